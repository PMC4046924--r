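# Supervised classification of genes over an ordered developmental
# gradient into behaviourally discrete ascending/descending pattern
# groups. A behaviour is a direction plus a containment-closed set of
# significant stage-pair intervals; for four stages there are exactly
# thirteen behaviours per direction (twenty-six in total).

#' All ordered stage pairs for an n-stage gradient
#'
#' @param n_stages Number of ordered stages (>= 2).
#' @return Data frame with columns `i`, `j` (1-based stage indices,
#'   i < j) and `label` (`"i-j"`), in lexicographic order.
#' @export
stage_pairs <- function(n_stages) {
  stopifnot(n_stages >= 2)
  idx <- which(upper.tri(matrix(0, n_stages, n_stages)), arr.ind = TRUE)
  out <- data.frame(i = idx[, "row"], j = idx[, "col"])
  out <- out[order(out$i, out$j), , drop = FALSE]
  out$label <- paste0(out$i, "-", out$j)
  rownames(out) <- NULL
  out
}

# Containment closure: (i,j) in S implies every enclosing interval
# (k,l), k <= i, l >= j, is in S. `sel` is a logical vector over the
# rows of `pairs`.
interval_closure <- function(sel, pairs) {
  out <- logical(nrow(pairs))
  for (p in which(sel)) {
    out <- out | (pairs$i <= pairs$i[p] & pairs$j >= pairs$j[p])
  }
  out
}

interval_set_key <- function(sel, pairs) {
  paste(pairs$label[sel], collapse = ",")
}

# Minimal intervals of a closed set: members containing no other member.
minimal_intervals <- function(sel, pairs) {
  keep <- logical(nrow(pairs))
  for (p in which(sel)) {
    contains_other <- any(
      sel & seq_len(nrow(pairs)) != p &
        pairs$i >= pairs$i[p] & pairs$j <= pairs$j[p]
    )
    keep[p] <- !contains_other
  }
  keep
}

#' Enumerate the behaviour-pattern catalogue
#'
#' All non-empty containment-closed sets of stage-pair intervals, each
#' in both directions. For four stages this yields thirteen ascending
#' plus thirteen descending behaviours. Patterns are ordered by the
#' lexicographically earliest minimal interval, then by set size, then
#' by the full interval list (a deterministic tertiary tie-break), and
#' labelled `A01..` / `D01..` in that order.
#'
#' @param n_stages Number of ordered stages (2..8).
#' @return Data frame with one row per pattern: `pattern_id`,
#'   `direction`, `intervals` (comma-separated `"i-j"` labels in
#'   lexicographic order), `minimal_intervals`, `n_intervals`.
#' @export
enumerate_behavior_patterns <- function(n_stages) {
  stopifnot(n_stages >= 2, n_stages <= 8)
  pairs <- stage_pairs(n_stages)
  np <- nrow(pairs)
  closed <- list()
  for (mask in seq_len(2^np - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(np) - 1)))
    if (identical(sel, interval_closure(sel, pairs))) {
      closed[[length(closed) + 1]] <- sel
    }
  }
  meta <- do.call(rbind, lapply(closed, function(sel) {
    mins <- minimal_intervals(sel, pairs)
    first <- which(mins)[1]
    data.frame(
      intervals = interval_set_key(sel, pairs),
      minimal_intervals = interval_set_key(mins, pairs),
      n_intervals = sum(sel),
      first_i = pairs$i[first], first_j = pairs$j[first],
      stringsAsFactors = FALSE
    )
  }))
  meta <- meta[order(meta$first_i, meta$first_j, meta$n_intervals,
    meta$intervals,
    method = "radix"
  ), , drop = FALSE]
  n_pat <- nrow(meta)
  out <- rbind(
    data.frame(
      pattern_id = sprintf("A%02d", seq_len(n_pat)),
      direction = "ascending", meta[, 1:3],
      stringsAsFactors = FALSE
    ),
    data.frame(
      pattern_id = sprintf("D%02d", seq_len(n_pat)),
      direction = "descending", meta[, 1:3],
      stringsAsFactors = FALSE
    )
  )
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment (sort ascending,
#' `adj_(k) = min_(m>=k) p_(m) * n / m`, capped at 1, returned in input
#' order), with input validation.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Row-wise Welch two-sample test on two matrices with equal row count.
# Same statistic as stats::t.test(var.equal = FALSE), vectorised over
# rows. Zero-variance rows: p = 1 when the means are equal, else 0.
row_welch_p <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero & my == mx] <- 1
  p[zero & my != mx] <- 0
  p
}

#' Pairwise differential-expression p-values across ordered stages
#'
#' Plumbing stand-in for an external count-based test: per gene and per
#' ordered stage pair, a Welch two-sample test on
#' `log2(count / size_factor + 1)`, followed by Benjamini-Hochberg
#' adjustment within each stage pair's family across genes. Users
#' reproducing published analyses should supply externally computed
#' p-values instead.
#'
#' @param counts Numeric matrix, genes x samples.
#' @param stages Factor (or vector) of stage labels per sample; the
#'   order of `levels(stages)` (or of first appearance) defines the
#'   gradient.
#' @param size_factors Optional named per-sample size factors; computed
#'   with [median_ratio_size_factors()] when `NULL`.
#' @return An object of class `stage_de`: list with `adj_pvalues`
#'   (genes x pairs matrix of adjusted p-values), `direction` (genes x
#'   pairs sign matrix of stage-mean differences), `stage_means` (genes
#'   x stages, normalised and replicate-averaged), `pairs` (the
#'   [stage_pairs()] table) and `stage_levels`.
#' @export
pairwise_de_pvalues <- function(counts, stages, size_factors = NULL) {
  stages <- if (is.factor(stages)) stages else factor(stages, levels = unique(stages))
  stopifnot(length(stages) == ncol(counts))
  reps <- table(stages)
  if (any(reps < 2)) {
    stop(
      "every stage needs at least 2 replicates; offending stage(s): ",
      paste(names(reps)[reps < 2], collapse = ", ")
    )
  }
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(counts)
  lg <- log2(sweep(counts, 2, size_factors, "/") + 1)
  lev <- levels(stages)
  pairs <- stage_pairs(length(lev))
  stage_means <- vapply(lev, function(s) {
    rowMeans(lg[, stages == s, drop = FALSE])
  }, numeric(nrow(counts)))
  adj <- dir <- matrix(NA_real_, nrow(counts), nrow(pairs),
    dimnames = list(rownames(counts), pairs$label)
  )
  for (k in seq_len(nrow(pairs))) {
    x <- lg[, stages == lev[pairs$i[k]], drop = FALSE]
    y <- lg[, stages == lev[pairs$j[k]], drop = FALSE]
    adj[, k] <- bh_adjust(row_welch_p(x, y))
    dir[, k] <- sign(stage_means[, pairs$j[k]] - stage_means[, pairs$i[k]])
  }
  structure(
    list(
      adj_pvalues = adj, direction = dir, stage_means = stage_means,
      pairs = pairs, stage_levels = lev
    ),
    class = "stage_de"
  )
}

#' Classify a single gene's profile into a behaviour pattern
#'
#' The significant set S holds the stage pairs with adjusted p below
#' `alpha`. An empty S is `"unclassified"`; mixed directions (or a zero
#' difference) among significant pairs is `"inconsistent"`. In
#' `"strict"` mode the gene is assigned the pattern whose interval set
#' equals S, or `"inconsistent"` when S is not containment-closed; in
#' `"closure"` mode S is first replaced by its containment closure.
#'
#' @param pvalues Numeric vector of adjusted p-values, one per stage
#'   pair, named by pair label (`"i-j"`) or ordered as [stage_pairs()].
#' @param direction Numeric vector of signs of the stage-mean
#'   differences, aligned with `pvalues`.
#' @param n_stages Number of stages.
#' @param alpha Significance threshold on adjusted p-values.
#' @param mode `"strict"` or `"closure"`.
#' @param catalogue Optional pre-computed
#'   [enumerate_behavior_patterns()] table for `n_stages`.
#' @return A single string: a pattern identifier, `"unclassified"` or
#'   `"inconsistent"`.
#' @export
classify_gene_profile <- function(pvalues, direction, n_stages,
                                  alpha = 0.05,
                                  mode = c("strict", "closure"),
                                  catalogue = NULL) {
  mode <- match.arg(mode)
  pairs <- stage_pairs(n_stages)
  if (!is.null(names(pvalues))) pvalues <- pvalues[pairs$label]
  if (!is.null(names(direction))) direction <- direction[pairs$label]
  stopifnot(length(pvalues) == nrow(pairs), length(direction) == nrow(pairs))
  if (is.null(catalogue)) catalogue <- enumerate_behavior_patterns(n_stages)
  sel <- pvalues < alpha
  if (!any(sel)) return("unclassified")
  dirs <- direction[sel]
  if (any(dirs == 0) || length(unique(dirs)) > 1) return("inconsistent")
  if (mode == "strict") {
    if (!identical(unname(sel), unname(interval_closure(sel, pairs)))) {
      return("inconsistent")
    }
  } else {
    sel <- interval_closure(sel, pairs)
  }
  key <- interval_set_key(sel, pairs)
  dir_label <- if (dirs[1] > 0) "ascending" else "descending"
  hit <- catalogue$pattern_id[
    catalogue$intervals == key & catalogue$direction == dir_label
  ]
  if (length(hit) != 1) return("inconsistent")
  hit
}

#' Classify every gene of a differential-expression result
#'
#' Applies [classify_gene_profile()] to each gene of a
#' [pairwise_de_pvalues()] result and tallies genes per pattern.
#'
#' @param de A `stage_de` object (or any list with `adj_pvalues`,
#'   `direction` matrices and `stage_levels`).
#' @param alpha Significance threshold on adjusted p-values.
#' @param mode `"strict"` or `"closure"`; see
#'   [classify_gene_profile()].
#' @return List with `classification` (data frame: `gene_id`, `class`,
#'   `direction`) and `counts` (the pattern catalogue with an `n_genes`
#'   column; classified genes partition across patterns).
#' @export
classify_profiles <- function(de, alpha = 0.05,
                              mode = c("strict", "closure")) {
  mode <- match.arg(mode)
  n_stages <- length(de$stage_levels)
  catalogue <- enumerate_behavior_patterns(n_stages)
  genes <- rownames(de$adj_pvalues)
  cls <- vapply(seq_along(genes), function(g) {
    classify_gene_profile(
      de$adj_pvalues[g, ], de$direction[g, ], n_stages,
      alpha = alpha, mode = mode, catalogue = catalogue
    )
  }, character(1))
  dir_of <- stats::setNames(catalogue$direction, catalogue$pattern_id)
  classification <- data.frame(
    gene_id = genes, class = cls,
    direction = ifelse(cls %in% names(dir_of), unname(dir_of[cls]), NA),
    stringsAsFactors = FALSE
  )
  counts <- catalogue
  tab <- table(factor(cls, levels = catalogue$pattern_id))
  counts$n_genes <- as.integer(tab[counts$pattern_id])
  list(classification = classification, counts = counts)
}

#' Extract a gene-to-pattern assignment vector
#'
#' Convenience accessor: named character vector restricted to genes
#' classified into a catalogue pattern (drops `"unclassified"` and
#' `"inconsistent"`).
#'
#' @param classified Output of [classify_profiles()].
#' @return Named character vector, gene identifier to pattern
#'   identifier.
#' @export
behavior_assignment <- function(classified) {
  cl <- classified$classification
  keep <- !(cl$class %in% c("unclassified", "inconsistent"))
  stats::setNames(cl$class[keep], cl$gene_id[keep])
}
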