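# Independent oracles and small fixture builders used across the suite.

# Step-up FDR adjustment written independently of the package (and of
# p.adjust): sort ascending, take running minima of p*(n/rank) from the
# largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Brute-force enumeration of non-empty containment-closed interval sets
# over n ordered stages, with explicit nested loops (a code path
# independent of the package's vectorised enumeration). Returns a
# character vector of canonical set keys.
closed_sets_oracle <- function(n_stages) {
  pr <- list()
  for (i in seq_len(n_stages - 1)) {
    for (j in (i + 1):n_stages) pr[[length(pr) + 1]] <- c(i, j)
  }
  np <- length(pr)
  keys <- character(0)
  for (mask in seq_len(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    ok <- TRUE
    for (s in sel) {
      for (q in seq_len(np)) {
        encloses <- pr[[q]][1] <= pr[[s]][1] && pr[[q]][2] >= pr[[s]][2]
        if (encloses && !(q %in% sel)) ok <- FALSE
      }
    }
    if (ok) {
      lab <- sort(vapply(sel, function(s) paste(pr[[s]], collapse = "-"),
        character(1)
      ))
      keys <- c(keys, paste(lab, collapse = ","))
    }
  }
  sort(keys)
}

# One BLAST-style hit row with only the fields that matter filled in.
hit <- function(query, subject, evalue = 1e-50, bits = 100, qlen = NA_real_) {
  data.frame(
    query_id = query, subject_id = subject,
    percent_identity = 90, alignment_length = 100, mismatches = 5,
    gap_opens = 0, qstart = 1, qend = 300, sstart = 1, send = 100,
    evalue = evalue, bit_score = bits, query_length = qlen,
    stringsAsFactors = FALSE
  )
}

hits <- function(...) do.call(rbind, list(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonicalise a homology/interval key for set comparison.
sorted_key <- function(x) paste(sort(strsplit(x, ",")[[1]]), collapse = ",")

# Random homology map for roundtrip properties.
random_homology_map <- function(n, seed) {
  set.seed(seed)
  data.frame(
    transcript_id = sprintf("t%03d", sample.int(999, n)),
    gene_id = sprintf("G%d", sample.int(50, n, replace = TRUE)),
    method = sample(c("rbb", "conditional"), n, replace = TRUE),
    evalue = 10^-runif(n, 5, 180),
    bit_score = round(runif(n, 40, 900), 1),
    stringsAsFactors = FALSE
  )
}
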