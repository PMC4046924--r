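# Conditional orthology assignment: reciprocal best-BLAST (RBB)
# identification, self-training of a length-conditioned e-value
# threshold curve, classification of non-reciprocating hits against the
# curve, and assembly of the transcript-to-gene homology map.

#' Best hit per query
#'
#' Reduces a hit table to the single best hit for each query: maximal
#' bit score, ties broken by smaller e-value, then by lexicographically
#' smallest subject identifier (C collation), so the result is fully
#' deterministic.
#'
#' @param hits Data frame of hits as returned by [read_blast_tab()].
#' @return Data frame with one row per query.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, -hits$bit_score, hits$evalue, hits$subject_id,
    method = "radix"
  )
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two search directions
#'
#' A transcript/gene pair is reciprocal iff the transcript's best
#' forward hit is that gene and the gene's best reverse hit is that
#' transcript (after the deterministic tie-breaking of
#' [best_hit_per_query()]). Each transcript and each gene occurs in at
#' most one pair.
#'
#' @param forward Hit table of transcripts searched against genes.
#' @param reverse Hit table of genes searched against transcripts.
#' @return Data frame with columns `transcript_id`, `gene_id`,
#'   `fwd_evalue`, `fwd_bit_score`, `rev_evalue`, `rev_bit_score`,
#'   `query_length` (forward query length, `NA` when absent).
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  fb <- best_hit_per_query(forward)
  rb <- best_hit_per_query(reverse)
  rb_best <- stats::setNames(rb$subject_id, rb$query_id)
  keep <- !is.na(rb_best[fb$subject_id]) &
    rb_best[fb$subject_id] == fb$query_id
  keep[is.na(keep)] <- FALSE
  fb <- fb[keep, , drop = FALSE]
  ri <- match(fb$subject_id, rb$query_id)
  out <- data.frame(
    transcript_id = fb$query_id,
    gene_id = fb$subject_id,
    fwd_evalue = fb$evalue,
    fwd_bit_score = fb$bit_score,
    rev_evalue = rb$evalue[ri],
    rev_bit_score = rb$bit_score[ri],
    query_length = fb$query_length,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Bin RBB pairs by transcript length and record a percentile e-value
#'
#' Self-training step: RBB pairs are split into equal-count (quantile)
#' bins on transcript length; within each bin the forward-hit e-values
#' are sorted ascending and the nearest-rank percentile (rank =
#' `ceiling(percentile/100 * n)`) is recorded. E-values of exactly zero
#' are replaced by `evalue_floor` before taking log10.
#'
#' @param pairs RBB pairs from [reciprocal_best_hits()].
#' @param lengths Named vector of transcript lengths. May be omitted if
#'   `pairs$query_length` is populated.
#' @param n_bins Requested number of equal-count bins.
#' @param percentile Percentile in (0, 100] of the ascending-sorted
#'   e-values to record per bin. The default, 99, places the curve at
#'   the permissive envelope below which 99 percent of self-training
#'   hits fall; small values give the stringent orientation.
#' @param evalue_floor Positive floor applied before log10.
#' @param min_per_bin Minimum pairs per bin; the bin count is reduced
#'   (with a warning) when there are fewer than `min_per_bin * n_bins`
#'   pairs.
#' @return Data frame with columns `bin_index`, `length_min`,
#'   `length_max`, `representative_length` (median length in bin),
#'   `n_hits`, `percentile_evalue`, `log10_percentile`.
#' @export
bin_rbb_by_length <- function(pairs, lengths = NULL, n_bins = 50,
                              percentile = 99, evalue_floor = 1e-180,
                              min_per_bin = 20) {
  stopifnot(n_bins >= 1, percentile > 0, percentile <= 100, evalue_floor > 0)
  n <- nrow(pairs)
  if (n == 0) stop("no reciprocal best hits: cannot self-train")
  len <- pairs$query_length
  if (!is.null(lengths)) {
    fill <- if (is.null(len)) rep(TRUE, n) else is.na(len)
    if (is.null(len)) len <- rep(NA_real_, n)
    len[fill] <- unname(lengths[pairs$transcript_id[fill]])
  }
  if (anyNA(len)) {
    stop(
      "missing transcript length for: ",
      paste(utils::head(pairs$transcript_id[is.na(len)], 5), collapse = ", ")
    )
  }
  eff_bins <- max(1L, min(as.integer(n_bins), n %/% as.integer(min_per_bin)))
  if (eff_bins < n_bins) {
    warning(sprintf(
      "reducing bin count from %d to %d (%d RBB pairs, min %d per bin)",
      as.integer(n_bins), eff_bins, n, as.integer(min_per_bin)
    ))
  }
  o <- order(len, pairs$transcript_id, method = "radix")
  len_s <- len[o]
  ev_s <- pairs$fwd_evalue[o]
  bin <- ceiling(seq_len(n) * eff_bins / n)
  out <- do.call(rbind, lapply(seq_len(eff_bins), function(b) {
    sel <- bin == b
    ev <- sort(ev_s[sel])
    k <- max(1L, ceiling(percentile / 100 * length(ev)))
    pe <- ev[k]
    data.frame(
      bin_index = b,
      length_min = min(len_s[sel]),
      length_max = max(len_s[sel]),
      representative_length = stats::median(len_s[sel]),
      n_hits = sum(sel),
      percentile_evalue = pe,
      log10_percentile = log10(max(pe, evalue_floor))
    )
  }))
  attr(out, "percentile") <- percentile
  attr(out, "evalue_floor") <- evalue_floor
  out
}

#' Fit the quadratic threshold curve to per-bin percentile points
#'
#' Ordinary least-squares fit of `log10(e-value) = a*L^2 + b*L + c`
#' through the per-bin points (`representative_length`,
#' `log10_percentile`). With fewer than three bins the fit falls back to
#' a constant curve (`a = b = 0`) at the hit-count-weighted mean of the
#' bins' log10 percentile values.
#'
#' @param bins Output of [bin_rbb_by_length()].
#' @param percentile Percentile the bins were computed at (recorded in
#'   the curve object; defaults to the attribute carried by `bins`).
#' @param evalue_floor Floor used when evaluating hits against the
#'   curve.
#' @details The curve's evaluation domain is the full self-training
#'   length range (smallest `length_min` to largest `length_max` of the
#'   bins), so transcripts at the short and long ends of the training
#'   data are judged by mild extrapolation of the fitted quadratic
#'   rather than clamped to the outermost bin medians, which would
#'   over-penalise them.
#' @return An object of class `threshold_curve`: a list with elements
#'   `a`, `b`, `c`, `percentile`, `evalue_floor`, `domain_min`,
#'   `domain_max`.
#' @export
fit_threshold_curve <- function(bins,
                                percentile = attr(bins, "percentile"),
                                evalue_floor = attr(bins, "evalue_floor")) {
  if (is.null(bins) || nrow(bins) < 1) stop("no bins: cannot fit threshold curve")
  if (is.null(percentile)) percentile <- 99
  if (is.null(evalue_floor)) evalue_floor <- 1e-180
  if (nrow(bins) < 3) {
    cc <- stats::weighted.mean(bins$log10_percentile, bins$n_hits)
    co <- c(a = 0, b = 0, c = cc)
  } else {
    L <- bins$representative_length
    fit <- stats::lm(bins$log10_percentile ~ L + I(L^2))
    beta <- stats::coef(fit)
    co <- c(a = unname(beta[3]), b = unname(beta[2]), c = unname(beta[1]))
    co[is.na(co)] <- 0
  }
  structure(
    list(
      a = unname(co["a"]), b = unname(co["b"]), c = unname(co["c"]),
      percentile = percentile, evalue_floor = evalue_floor,
      domain_min = min(bins$length_min),
      domain_max = max(bins$length_max)
    ),
    class = "threshold_curve"
  )
}

#' Construct a threshold curve from explicit coefficients
#'
#' Mainly useful for tests and for planting curves in simulations.
#'
#' @param a,b,c Quadratic coefficients of log10(e-value) in length.
#' @param domain_min,domain_max Length domain the curve is valid on;
#'   evaluation clamps to this range.
#' @param percentile,evalue_floor Metadata carried on the object.
#' @return A `threshold_curve` object.
#' @export
threshold_curve <- function(a, b, c, domain_min, domain_max,
                            percentile = 99, evalue_floor = 1e-180) {
  stopifnot(domain_min <= domain_max, evalue_floor > 0)
  structure(
    list(
      a = a, b = b, c = c, percentile = percentile,
      evalue_floor = evalue_floor,
      domain_min = domain_min, domain_max = domain_max
    ),
    class = "threshold_curve"
  )
}

#' Evaluate a threshold curve at given transcript lengths
#'
#' Lengths are clamped to the fitted domain before evaluation (a
#' quadratic extrapolated outside its training range is meaningless).
#'
#' @param object A `threshold_curve`.
#' @param lengths Numeric vector of transcript lengths.
#' @param ... Unused.
#' @return Numeric vector of log10 e-value thresholds.
#' @export
predict.threshold_curve <- function(object, lengths, ...) {
  L <- pmin(pmax(lengths, object$domain_min), object$domain_max)
  object$a * L^2 + object$b * L + object$c
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf(
    "threshold_curve: log10(e) = %.4g*L^2 + %.4g*L + %.4g\n", x$a, x$b, x$c
  ))
  cat(sprintf(
    "  percentile %.4g, e-value floor %g, length domain [%g, %g]\n",
    x$percentile, x$evalue_floor, x$domain_min, x$domain_max
  ))
  invisible(x)
}

#' Classify non-reciprocating hits against the threshold curve
#'
#' A hit is accepted when its e-value is at least as significant as the
#' length-conditioned threshold:
#' `log10(max(evalue, floor)) <= curve(query_length)`. Hits whose query
#' is already an RBB transcript are excluded (those transcripts are
#' accepted unconditionally).
#'
#' @param hits Hit table (forward direction); every remaining hit must
#'   carry a `query_length`.
#' @param rbb RBB pairs from [reciprocal_best_hits()].
#' @param curve A `threshold_curve`.
#' @return The accepted subset of `hits`.
#' @export
classify_nonrbb_hits <- function(hits, rbb, curve) {
  hits <- hits[!(hits$query_id %in% rbb$transcript_id), , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  if (anyNA(hits$query_length)) {
    stop(
      "missing query_length for transcript(s): ",
      paste(utils::head(unique(hits$query_id[is.na(hits$query_length)]), 5),
        collapse = ", "
      )
    )
  }
  thr <- predict(curve, hits$query_length)
  lg <- log10(pmax(hits$evalue, curve$evalue_floor))
  out <- hits[lg <= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a transcript-to-gene homology map
#'
#' Runs the full conditional orthology assignment: identify RBB pairs,
#' self-train the length-conditioned threshold curve on them, classify
#' all remaining hits against the curve, and assign each non-RBB
#' transcript with at least one accepted hit to its best accepted gene
#' (bit score, then e-value, then subject identifier). Transcripts with
#' no accepted hit are absent from the map.
#'
#' @param forward Hit table of transcripts searched against genes.
#' @param reverse Hit table of genes searched against transcripts.
#' @param lengths Optional named vector of transcript lengths, used to
#'   fill missing `query_length` values.
#' @param n_bins,percentile,evalue_floor,min_per_bin Self-training
#'   parameters; see [bin_rbb_by_length()].
#' @return A homology map data frame (columns `transcript_id`,
#'   `gene_id`, `method`, `evalue`, `bit_score`) with the fitted
#'   `threshold_curve` in attribute `"curve"` and the bin diagnostics in
#'   attribute `"bins"`.
#' @export
build_homology_map <- function(forward, reverse, lengths = NULL,
                               n_bins = 50, percentile = 99,
                               evalue_floor = 1e-180, min_per_bin = 20) {
  if (!is.null(lengths)) {
    fill <- is.na(forward$query_length)
    forward$query_length[fill] <- unname(lengths[forward$query_id[fill]])
  }
  rbb <- reciprocal_best_hits(forward, reverse)
  bins <- bin_rbb_by_length(rbb,
    lengths = lengths, n_bins = n_bins,
    percentile = percentile, evalue_floor = evalue_floor,
    min_per_bin = min_per_bin
  )
  curve <- fit_threshold_curve(bins)
  accepted <- classify_nonrbb_hits(forward, rbb, curve)
  cond <- best_hit_per_query(accepted)
  map <- rbind(
    data.frame(
      transcript_id = rbb$transcript_id, gene_id = rbb$gene_id,
      method = "rbb", evalue = rbb$fwd_evalue,
      bit_score = rbb$fwd_bit_score, stringsAsFactors = FALSE
    ),
    if (nrow(cond) > 0) {
      data.frame(
        transcript_id = cond$query_id, gene_id = cond$subject_id,
        method = "conditional", evalue = cond$evalue,
        bit_score = cond$bit_score, stringsAsFactors = FALSE
      )
    }
  )
  map <- map[order(map$transcript_id, method = "radix"), , drop = FALSE]
  rownames(map) <- NULL
  validate_homology_map(map)
  attr(map, "curve") <- curve
  attr(map, "bins") <- bins
  map
}

#' Evaluate a homology map against a known truth
#'
#' @param map Homology map data frame.
#' @param truth Named character vector, transcript identifier to true
#'   gene identifier, covering all transcripts that have a true gene.
#' @return Named numeric vector with `precision` (correct / assignments
#'   made, 0 when no assignments), `recall` (correct / |truth|) and `f1`
#'   (harmonic mean, 0 when both are 0).
#' @export
evaluate_assignment <- function(map, truth) {
  n_assigned <- nrow(map)
  correct <- sum(!is.na(truth[map$transcript_id]) &
    truth[map$transcript_id] == map$gene_id)
  precision <- if (n_assigned > 0) correct / n_assigned else 0
  recall <- if (length(truth) > 0) correct / length(truth) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  c(precision = precision, recall = recall, f1 = f1)
}
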