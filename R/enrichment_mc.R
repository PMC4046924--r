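# Monte Carlo co-occupancy enrichment: is the number of transcription
# factor homologue pairs sharing behaviour groups with a focal gene set
# in both species larger than expected by chance?

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Behaviour patterns occupied by a gene set
#'
#' @param genes Character vector of gene identifiers.
#' @param assignment Named character vector, gene identifier to pattern
#'   identifier (one species' classification; see
#'   [behavior_assignment()]). Genes absent from the assignment
#'   contribute nothing.
#' @return Sorted character vector of occupied pattern identifiers.
#' @export
occupied_behaviors <- function(genes, assignment) {
  pat <- assignment[intersect(genes, names(assignment))]
  sort(unique(unname(pat)))
}

pair_key <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "\r")

#' Restrict a cross-species link to doubly classified pairs
#'
#' The natural sampling universe for the co-occupancy test: linked gene
#' pairs that carry a behaviour classification in both species.
#'
#' @param link Link table from [link_via_intermediary()].
#' @param assign_a,assign_b Named gene-to-pattern vectors (see
#'   [behavior_assignment()]).
#' @return The subset of `link` rows whose `gene_a` and `gene_b` are
#'   both classified.
#' @export
linked_classified_pairs <- function(link, assign_a, assign_b) {
  out <- link[
    link$gene_a %in% names(assign_a) & link$gene_b %in% names(assign_b), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

#' Monte Carlo co-occupancy enrichment test
#'
#' The observed statistic is the number of linked transcription factor
#' pairs whose behaviour pattern lies, in each species, within the set
#' of patterns occupied by the focal gene pairs. Each null iteration
#' redraws `n_select` linked pairs from the universe without
#' replacement and recomputes the statistic; the empirical p-value is
#' the plug-in estimator `(n_ge + 1) / (n_iter + 1)` where `n_ge`
#' counts simulated values at least as large as the observed one.
#'
#' @param focal_pairs Data frame of linked focal gene pairs (columns
#'   `gene_a`, `gene_b`), a subset of `universe`.
#' @param tf_pairs Data frame of linked transcription factor pairs
#'   (columns `gene_a`, `gene_b`).
#' @param assign_a,assign_b Named character vectors, gene to pattern
#'   identifier, for species A and B.
#' @param universe Data frame of all linked gene pairs eligible for
#'   resampling (typically the doubly classified linked set).
#' @param n_select Number of pairs drawn per iteration; defaults to the
#'   focal set size.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Optional integer seed; identical seed and inputs give an
#'   identical result, and the caller's RNG state is left untouched.
#' @return An object of class `enrichment_result`: list with
#'   `observed`, `n_iter`, `n_ge`, `p_empirical`, `seed`.
#' @export
monte_carlo_cooccupancy_test <- function(focal_pairs, tf_pairs,
                                         assign_a, assign_b, universe,
                                         n_select = nrow(focal_pairs),
                                         n_iter = 1e6, seed = NULL) {
  stopifnot(n_iter >= 1)
  if (n_select > nrow(universe)) {
    stop("n_select exceeds the size of the sampling universe")
  }
  if (!all(pair_key(focal_pairs) %in% pair_key(universe))) {
    stop("focal pairs must be a subset of the universe")
  }
  pat_a <- unname(assign_a[universe$gene_a])
  pat_b <- unname(assign_b[universe$gene_b])
  tfa <- unname(assign_a[tf_pairs$gene_a])
  tfb <- unname(assign_b[tf_pairs$gene_b])
  occ_a <- occupied_behaviors(focal_pairs$gene_a, assign_a)
  occ_b <- occupied_behaviors(focal_pairs$gene_b, assign_b)
  observed <- sum(tfa %in% occ_a & tfb %in% occ_b)
  n_univ <- nrow(universe)
  n_ge <- with_seed(seed, {
    hits <- 0L
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n_univ, n_select)
      s <- sum(tfa %in% pat_a[idx] & tfb %in% pat_b[idx])
      if (s >= observed) hits <- hits + 1L
    }
    hits
  })
  structure(
    list(
      observed = observed, n_iter = as.integer(n_iter), n_ge = n_ge,
      p_empirical = (n_ge + 1) / (n_iter + 1),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo co-occupancy test: observed = %d, %d/%d null draws >= observed\n",
    x$observed, x$n_ge, x$n_iter
  ))
  cat(sprintf("  empirical p = %.6g (seed %s)\n", x$p_empirical, x$seed))
  invisible(x)
}

#' Write an enrichment result as JSON
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_result <- function(result, path) {
  jsonlite::write_json(
    list(
      observed = result$observed, n_iter = result$n_iter,
      n_ge = result$n_ge, p_empirical = result$p_empirical,
      seed = result$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
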