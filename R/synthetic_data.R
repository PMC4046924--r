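# Generators producing every pipeline input with planted ground truth:
# simulated BLAST hit tables with a planted threshold curve, replicated
# stage-count matrices with planted behaviour patterns, and a linked
# two-species design with optional planted transcription-factor
# enrichment. All generators are pure functions of their parameters and
# seed.

default_planted_curve <- c(a = -5e-6, b = -0.04, c = -10)

eval_quadratic <- function(coefs, L) {
  coefs[["a"]] * L^2 + coefs[["b"]] * L + coefs[["c"]]
}

#' Simulate BLAST searches of assembled transcripts with known homology
#'
#' Emulates the structure of a de novo assembled transcriptome searched
#' against a reference gene set: each reference gene is represented by
#' one to several assembled transcript variants of varying length. True
#' transcript/gene hits get log10 e-values at `curve(length) -
#' |N(0, noise_sd)|` (always at least as stringent as the planted
#' curve); per gene, the variant with the most significant hit is the
#' reciprocal best pair. Decoy cross-gene hits sit a positive margin
#' above (less significant than) the curve. Bit scores are
#' anti-monotone in the e-value. A transcript abundance table is
#' generated alongside so that assignment quality can be scored by rank
#' concordance with the true gene-level abundance.
#'
#' @param n_genes Number of reference genes.
#' @param variants_per_gene Integer range (length 2) of assembled
#'   transcript variants per gene.
#' @param length_range Transcript length range (uniform).
#' @param curve Planted quadratic coefficients, named `a`, `b`, `c`, in
#'   (length, log10 e-value) space.
#' @param noise_sd Standard deviation of the half-normal log10 e-value
#'   noise below the curve.
#' @param decoy_rate Per-transcript probability of an additional decoy
#'   hit to a wrong gene.
#' @param decoy_margin How far above the curve (log10 units) decoy
#'   e-values sit, before their own half-normal jitter.
#' @param n_samples Number of abundance samples to simulate.
#' @param seed Integer seed; identical inputs give identical outputs.
#' @return List with `forward` and `reverse` hit tables (the format of
#'   [read_blast_tab()]), `lengths` (named transcript length vector),
#'   `abundance` (transcripts x samples matrix) and `truth` (list:
#'   `map` named transcript-to-gene vector, `rbb` the designated
#'   reciprocal variant per gene, `gene_abundance`, `curve`, `seed`).
#' @export
simulate_homology_truth <- function(n_genes = 500,
                                    variants_per_gene = c(1, 4),
                                    length_range = c(200, 3000),
                                    curve = default_planted_curve,
                                    noise_sd = 0.1, decoy_rate = 0.1,
                                    decoy_margin = 2, n_samples = 2,
                                    seed = 1) {
  stopifnot(
    n_genes >= 1, decoy_rate >= 0, decoy_rate < 1, noise_sd >= 0,
    length(variants_per_gene) == 2, variants_per_gene[1] >= 1
  )
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    k <- sample(variants_per_gene[1]:variants_per_gene[2], n_genes,
      replace = TRUE
    )
    gene_of <- rep(genes, k)
    tx <- paste0(gene_of, ".t", unlist(lapply(k, seq_len)))
    n_tx <- length(tx)
    len <- round(stats::runif(n_tx, length_range[1], length_range[2]))
    y_true <- eval_quadratic(curve, len) - abs(stats::rnorm(n_tx, 0, noise_sd))
    fwd <- blast_row(
      tx, gene_of, len,
      evalue = 10^y_true, bit_score = 30 - 2 * y_true
    )
    n_decoy <- stats::rbinom(1, n_tx, decoy_rate)
    if (n_decoy > 0 && n_genes > 1) {
      di <- sample.int(n_tx, n_decoy)
      wrong <- vapply(gene_of[di], function(g) sample(setdiff(genes, g), 1),
        character(1)
      )
      y_decoy <- pmin(
        eval_quadratic(curve, len[di]) + decoy_margin +
          abs(stats::rnorm(n_decoy, 0, 0.5)),
        2
      )
      fwd <- rbind(fwd, blast_row(
        tx[di], wrong, len[di],
        evalue = 10^y_decoy, bit_score = 30 - 2 * y_decoy
      ))
    }
    rev <- blast_row(
      fwd$subject_id[seq_len(n_tx)], fwd$query_id[seq_len(n_tx)],
      qlen = NA_real_,
      evalue = fwd$evalue[seq_len(n_tx)],
      bit_score = fwd$bit_score[seq_len(n_tx)]
    )
    # reciprocal variant = the gene's most significant reverse hit
    rb <- best_hit_per_query(rev)
    rbb <- stats::setNames(rb$subject_id, rb$query_id)
    gene_expr <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
    w <- stats::rgamma(n_tx, shape = 1)
    w_gene_total <- rep(
      unname(tapply(w, factor(gene_of, levels = genes), sum)), k
    )
    base <- gene_expr[match(gene_of, genes)] * w / w_gene_total
    abundance <- vapply(seq_len(n_samples), function(s) {
      base * exp(stats::rnorm(n_tx, 0, 0.2))
    }, numeric(n_tx))
    dimnames(abundance) <- list(tx, sprintf("s%d", seq_len(n_samples)))
    gene_abundance <- rowsum(abundance, group = gene_of, reorder = TRUE)
    list(
      forward = fwd, reverse = rev,
      lengths = stats::setNames(len, tx),
      abundance = abundance,
      truth = list(
        map = stats::setNames(gene_of, tx),
        rbb = rbb,
        gene_abundance = gene_abundance,
        curve = curve, noise_sd = noise_sd, decoy_rate = decoy_rate,
        seed = seed
      )
    )
  })
}

# Assemble a plausible 13-column hit table around the fields that
# matter (ids, e-value, bit score, query length).
blast_row <- function(query, subject, qlen, evalue, bit_score) {
  n <- length(query)
  aln <- pmax(30, round(ifelse(is.na(qlen), 300, qlen) / 3))
  data.frame(
    query_id = query, subject_id = subject,
    percent_identity = round(stats::runif(n, 70, 99), 2),
    alignment_length = aln,
    mismatches = pmax(0, round(aln * 0.1)),
    gap_opens = 0L,
    qstart = 1L, qend = ifelse(is.na(qlen), aln * 3, qlen),
    sstart = 1L, send = aln,
    evalue = evalue, bit_score = round(bit_score, 1),
    query_length = qlen,
    stringsAsFactors = FALSE
  )
}

parse_intervals <- function(key) {
  if (!nzchar(key)) return(matrix(integer(0), ncol = 2))
  parts <- strsplit(strsplit(key, ",")[[1]], "-")
  matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("i", "j"))
  )
}

# Log2 stage levels realising one catalogue pattern: a step of
# log2(fold_change) spread uniformly over each minimal interval,
# descending patterns mirrored so expression starts high.
pattern_stage_levels <- function(pattern_row, n_stages, log2_fc) {
  mins <- parse_intervals(pattern_row$minimal_intervals)
  d <- numeric(n_stages - 1)
  for (r in seq_len(nrow(mins))) {
    span <- mins[r, "i"]:(mins[r, "j"] - 1)
    d[span] <- d[span] + log2_fc / length(span)
  }
  lev <- cumsum(c(0, d))
  if (pattern_row$direction == "descending") lev <- max(lev) - lev
  lev
}

# Patterns whose minimal intervals are all adjacent stage pairs; these
# are exactly the patterns realisable with zero expression drift on
# their non-significant pairs.
jump_realizable <- function(catalogue) {
  vapply(seq_len(nrow(catalogue)), function(r) {
    mins <- parse_intervals(catalogue$minimal_intervals[r])
    all(mins[, "j"] - mins[, "i"] == 1)
  }, logical(1))
}

nb_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
  } else {
    round(mu)
  }
}

#' Simulate a replicated stage-count matrix with planted behaviours
#'
#' For every pattern of the behaviour catalogue, `genes_per_pattern`
#' genes are planted whose stage means follow a monotone step function:
#' a step of `log2(fold_change)` spread uniformly over each of the
#' pattern's minimal significant intervals. An equal number of flat
#' (null) genes is added by default so that median-of-ratios
#' normalisation has a non-differential majority to anchor on. Counts
#' are negative binomial with the given dispersion, scaled by planted
#' per-sample size factors.
#'
#' @param genes_per_pattern Genes planted per catalogue pattern.
#' @param n_stages Number of ordered stages.
#' @param n_replicates Replicates per stage.
#' @param base_mean Baseline expression mean (counts).
#' @param fold_change Total fold change across each minimal significant
#'   interval (> 1).
#' @param dispersion Negative binomial dispersion (0 gives rounded
#'   means).
#' @param size_factors Optional per-sample size factors; drawn
#'   log-normally and normalised to geometric mean 1 when `NULL`.
#' @param n_null_genes Number of flat genes; defaults to the number of
#'   planted pattern genes.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples), `stages` (factor per
#'   sample) and `truth` (list: `pattern` named gene-to-pattern vector
#'   (`NA` for null genes), `direction`, `size_factors`, `catalogue`,
#'   `seed`).
#' @export
simulate_count_matrix <- function(genes_per_pattern = 40, n_stages = 4,
                                  n_replicates = 4, base_mean = 100,
                                  fold_change = 8, dispersion = 0.05,
                                  size_factors = NULL,
                                  n_null_genes = NULL, seed = 1) {
  stopifnot(fold_change > 1, dispersion >= 0, n_replicates >= 2)
  catalogue <- enumerate_behavior_patterns(n_stages)
  n_pat <- nrow(catalogue)
  if (is.null(n_null_genes)) n_null_genes <- n_pat * genes_per_pattern
  with_seed(seed, {
    n_samples <- n_stages * n_replicates
    stages <- factor(
      rep(sprintf("S%d", seq_len(n_stages)), each = n_replicates),
      levels = sprintf("S%d", seq_len(n_stages))
    )
    sample_ids <- paste0(as.character(stages), "_R", rep(seq_len(n_replicates), n_stages))
    if (is.null(size_factors)) {
      sf <- exp(stats::rnorm(n_samples, 0, 0.3))
      sf <- sf / exp(mean(log(sf)))
    } else {
      sf <- rep_len(size_factors, n_samples)
    }
    names(sf) <- sample_ids
    gene_ids <- c(
      unlist(lapply(seq_len(n_pat), function(r) {
        sprintf("gene_%s_%03d", catalogue$pattern_id[r], seq_len(genes_per_pattern))
      })),
      if (n_null_genes > 0) sprintf("gene_null_%04d", seq_len(n_null_genes))
    )
    pattern <- c(
      rep(catalogue$pattern_id, each = genes_per_pattern),
      rep(NA_character_, n_null_genes)
    )
    levels_mat <- rbind(
      do.call(rbind, lapply(seq_len(n_pat), function(r) {
        matrix(
          rep(pattern_stage_levels(catalogue[r, ], n_stages, log2(fold_change)),
            each = genes_per_pattern
          ),
          nrow = genes_per_pattern
        )
      })),
      if (n_null_genes > 0) {
        matrix(
          rep(stats::runif(n_null_genes, -1, 2), n_stages),
          nrow = n_null_genes
        )
      }
    )
    mu_stage <- base_mean * 2^levels_mat
    mu <- mu_stage[, as.integer(stages), drop = FALSE] *
      rep(sf, each = length(gene_ids))
    dimnames(mu) <- list(gene_ids, sample_ids)
    counts <- nb_counts(mu, dispersion)
    dir_of <- stats::setNames(catalogue$direction, catalogue$pattern_id)
    list(
      counts = counts, stages = stages,
      truth = list(
        pattern = stats::setNames(pattern, gene_ids),
        direction = stats::setNames(unname(dir_of[pattern]), gene_ids),
        size_factors = sf, catalogue = catalogue, seed = seed
      )
    )
  })
}

#' Simulate two linked species with planted shared expression behaviour
#'
#' Builds two species whose genes map one-to-one onto a shared
#' intermediary reference gene set. A `shared_fraction` of intermediary
#' genes get the same planted direction in both species, the rest
#' opposite directions. Planted patterns are drawn from the
#' jump-realisable subset of the catalogue (minimal intervals all
#' adjacent), so supervised classification can recover them reliably.
#' Flat genes are added per species for normalisation. A designated
#' subset of intermediaries is labelled transcription factor (TF); with
#' `tf_enriched = TRUE`, a focal set of concordant ascending genes and
#' all TFs are planted together in a small set of ascending patterns
#' that the rest of the universe avoids, creating genuine co-occupancy
#' enrichment.
#'
#' @param n_genes Number of intermediary-linked expressed genes.
#' @param shared_fraction Fraction of genes with concordant planted
#'   direction in the two species.
#' @param n_tf Number of TF-labelled intermediary genes.
#' @param n_focal Size of the planted focal gene set.
#' @param tf_enriched Plant TF co-occupancy enrichment with the focal
#'   set?
#' @param n_focal_patterns Number of ascending patterns reserved for
#'   the focal set in enriched mode.
#' @param n_flat Flat (null) genes per species.
#' @param n_stages,n_replicates,base_mean,fold_change,dispersion Count
#'   model parameters, as in [simulate_count_matrix()].
#' @param seed Integer seed.
#' @return List with `species_a`, `species_b` (each: `counts`,
#'   `stages`), `map_a`, `map_b` (named gene-to-intermediary vectors),
#'   `tf`, `focal` (intermediary identifier vectors) and `truth`
#'   (planted directions, patterns, shared flags, seed).
#' @export
simulate_two_species <- function(n_genes = 1000, shared_fraction = 0.7,
                                 n_tf = 120, n_focal = 29,
                                 tf_enriched = FALSE,
                                 n_focal_patterns = 4, n_flat = 300,
                                 n_stages = 4, n_replicates = 4,
                                 base_mean = 100, fold_change = 8,
                                 dispersion = 0.05, seed = 1) {
  stopifnot(
    shared_fraction >= 0, shared_fraction <= 1,
    n_focal + n_tf <= n_genes
  )
  catalogue <- enumerate_behavior_patterns(n_stages)
  realizable <- catalogue[jump_realizable(catalogue), , drop = FALSE]
  asc <- realizable$pattern_id[realizable$direction == "ascending"]
  desc <- realizable$pattern_id[realizable$direction == "descending"]
  if (tf_enriched) stopifnot(n_focal_patterns < length(asc))
  with_seed(seed, {
    inter <- sprintf("i%05d", seq_len(n_genes))
    shared <- stats::runif(n_genes) < shared_fraction
    dir_a <- sample(c("ascending", "descending"), n_genes, replace = TRUE)
    dir_b <- ifelse(shared, dir_a,
      ifelse(dir_a == "ascending", "descending", "ascending")
    )
    focal <- tf <- character(0)
    focal_patterns <- character(0)
    if (tf_enriched) {
      focal_patterns <- asc[seq_len(n_focal_patterns)]
      open_asc <- setdiff(asc, focal_patterns)
      pick <- sample.int(n_genes, n_focal + n_tf)
      focal <- inter[pick[seq_len(n_focal)]]
      tf <- inter[pick[n_focal + seq_len(n_tf)]]
      special <- inter %in% c(focal, tf)
      shared[special] <- TRUE
      dir_a[special] <- dir_b[special] <- "ascending"
      pat_a <- ifelse(dir_a == "ascending",
        sample(open_asc, n_genes, replace = TRUE),
        sample(desc, n_genes, replace = TRUE)
      )
      pat_a[special] <- sample(focal_patterns, sum(special), replace = TRUE)
      pat_b <- ifelse(shared, pat_a, ifelse(dir_b == "ascending",
        sample(open_asc, n_genes, replace = TRUE),
        sample(desc, n_genes, replace = TRUE)
      ))
    } else {
      pick <- sample.int(n_genes, n_focal + n_tf)
      focal <- inter[pick[seq_len(n_focal)]]
      tf <- inter[pick[n_focal + seq_len(n_tf)]]
      pat_a <- ifelse(dir_a == "ascending",
        sample(asc, n_genes, replace = TRUE),
        sample(desc, n_genes, replace = TRUE)
      )
      pat_b <- ifelse(shared, pat_a, ifelse(dir_b == "ascending",
        sample(asc, n_genes, replace = TRUE),
        sample(desc, n_genes, replace = TRUE)
      ))
    }
    species <- function(prefix, patterns) {
      genes <- paste0(prefix, sub("^i", "", inter))
      flat_inter <- sprintf("iF%05d", seq_len(n_flat))
      flat_genes <- paste0(prefix, "F", sub("^iF", "", flat_inter))
      cm <- planted_counts(
        c(genes, flat_genes),
        c(patterns, rep(NA_character_, n_flat)),
        catalogue, n_stages, n_replicates, base_mean, fold_change,
        dispersion
      )
      list(
        counts = cm$counts, stages = cm$stages,
        map = stats::setNames(c(inter, flat_inter), c(genes, flat_genes))
      )
    }
    sa <- species("a", pat_a)
    sb <- species("b", pat_b)
    list(
      species_a = list(counts = sa$counts, stages = sa$stages),
      species_b = list(counts = sb$counts, stages = sb$stages),
      map_a = sa$map, map_b = sb$map,
      tf = tf, focal = focal,
      truth = list(
        direction_a = stats::setNames(dir_a, inter),
        direction_b = stats::setNames(dir_b, inter),
        pattern_a = stats::setNames(pat_a, inter),
        pattern_b = stats::setNames(pat_b, inter),
        shared = stats::setNames(shared, inter),
        focal_patterns = focal_patterns, seed = seed
      )
    )
  })
}

# Counts for an explicit gene -> pattern assignment (NA = flat gene).
# Uses the current RNG stream.
planted_counts <- function(gene_ids, patterns, catalogue, n_stages,
                           n_replicates, base_mean, fold_change,
                           dispersion) {
  n_samples <- n_stages * n_replicates
  stages <- factor(
    rep(sprintf("S%d", seq_len(n_stages)), each = n_replicates),
    levels = sprintf("S%d", seq_len(n_stages))
  )
  sample_ids <- paste0(as.character(stages), "_R", rep(seq_len(n_replicates), n_stages))
  sf <- exp(stats::rnorm(n_samples, 0, 0.3))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- sample_ids
  lev <- t(vapply(seq_along(gene_ids), function(g) {
    if (is.na(patterns[g])) {
      rep(stats::runif(1, -1, 2), n_stages)
    } else {
      r <- which(catalogue$pattern_id == patterns[g])
      pattern_stage_levels(catalogue[r, ], n_stages, log2(fold_change))
    }
  }, numeric(n_stages)))
  mu <- (base_mean * 2^lev)[, as.integer(stages), drop = FALSE] *
    rep(sf, each = length(gene_ids))
  dimnames(mu) <- list(gene_ids, sample_ids)
  list(counts = nb_counts(mu, dispersion), stages = stages,
    size_factors = sf
  )
}
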