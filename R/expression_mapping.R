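# From transcript-level abundance to reference-gene-level, normalised
# expression, plus the cross-species linking machinery.

#' Aggregate transcript abundances to reference genes
#'
#' Sums each gene's assigned transcripts per sample (all transcript
#' variants of one reference gene locus contribute to that locus).
#' Abundance features absent from the map are dropped; their number and
#' total abundance are reported in attributes.
#'
#' @param ab Numeric matrix of abundances, transcripts x samples.
#' @param map Homology map data frame (transcript_id, gene_id, ...).
#' @return Numeric matrix, genes x samples, with attributes
#'   `n_excluded` (count of dropped abundance features) and
#'   `excluded_abundance` (their per-sample totals).
#' @export
aggregate_to_reference_genes <- function(ab, map) {
  validate_homology_map(map)
  tx <- intersect(rownames(ab), map$transcript_id)
  excluded <- setdiff(rownames(ab), tx)
  gene <- stats::setNames(map$gene_id, map$transcript_id)[tx]
  if (length(tx) == 0) {
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(ab),
      dimnames = list(NULL, colnames(ab))
    )
  } else {
    out <- rowsum(ab[tx, , drop = FALSE], group = unname(gene), reorder = TRUE)
  }
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_abundance") <-
    colSums(ab[excluded, , drop = FALSE])
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample library size factor: the median, over genes with strictly
#' positive counts in every sample, of the ratio of the gene's count to
#' its geometric mean across samples. Genes containing any zero are
#' excluded from the median (no pseudo-count).
#'
#' @param counts Numeric matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per
#'   sample.
#' @export
median_ratio_size_factors <- function(counts) {
  if (nrow(counts) == 0) stop("no genes in count matrix")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop(
      "no gene has all-positive counts across samples; ",
      "consider adding a pseudo-count before normalisation"
    )
  }
  geo <- exp(log_geo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cc) {
    stats::median(cc / geo)
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("degenerate size factor(s); check the count matrix")
  }
  sf
}

#' Spearman rank concordance between two abundance vectors
#'
#' Features are matched by name; the correlation (average ranks for
#' ties) is computed over the intersection.
#'
#' @param x,y Named numeric vectors of per-feature abundances.
#' @return List with `rho` (Spearman correlation) and `n` (size of the
#'   feature intersection).
#' @export
spearman_concordance <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) {
    stop("fewer than 3 shared features between the two vectors")
  }
  list(
    rho = stats::cor(x[shared], y[shared], method = "spearman"),
    n = length(shared)
  )
}

#' Link two species' genes through an intermediary reference genome
#'
#' Given many-to-one maps from each species' genes into a shared
#' intermediary gene space, returns every (geneA, geneB, intermediary)
#' triple with a common intermediary. The relation may be many-to-many
#' across species.
#'
#' @param map_a,map_b Named character vectors: species gene identifier
#'   to intermediary gene identifier.
#' @return Data frame with columns `gene_a`, `gene_b`, `intermediary`.
#' @export
link_via_intermediary <- function(map_a, map_b) {
  a <- data.frame(
    gene_a = names(map_a), intermediary = unname(map_a),
    stringsAsFactors = FALSE
  )
  b <- data.frame(
    gene_b = names(map_b), intermediary = unname(map_b),
    stringsAsFactors = FALSE
  )
  out <- merge(a, b, by = "intermediary", sort = TRUE)
  out <- out[order(out$intermediary, out$gene_a, out$gene_b,
    method = "radix"
  ), c("gene_a", "gene_b", "intermediary")]
  rownames(out) <- NULL
  out
}

#' Directional overlap of two species' expression behaviours
#'
#' Counts, at the intermediary-gene level with any-link semantics, the
#' intermediary genes whose linked genes ascend in both species, descend
#' in both species, or (having classified links on both sides) match in
#' neither direction.
#'
#' @param class_a,class_b Named character vectors mapping species genes
#'   to `"ascending"` or `"descending"`.
#' @param link Cross-species link table from [link_via_intermediary()].
#' @return List of counts: `ascending_shared`, `descending_shared`,
#'   `discordant`.
#' @export
directional_overlap <- function(class_a, class_b, link) {
  stopifnot(all(class_a %in% c("ascending", "descending")),
    all(class_b %in% c("ascending", "descending"))
  )
  da <- unname(class_a[link$gene_a])
  db <- unname(class_b[link$gene_b])
  ids <- unique(link$intermediary)
  asc <- desc <- disc <- 0L
  for (i in ids) {
    sel <- link$intermediary == i
    a_dirs <- da[sel][!is.na(da[sel])]
    b_dirs <- db[sel][!is.na(db[sel])]
    a_up <- "ascending" %in% a_dirs
    a_dn <- "descending" %in% a_dirs
    b_up <- "ascending" %in% b_dirs
    b_dn <- "descending" %in% b_dirs
    if (a_up && b_up) asc <- asc + 1L
    if (a_dn && b_dn) desc <- desc + 1L
    if (!(a_up && b_up) && !(a_dn && b_dn) &&
      length(a_dirs) > 0 && length(b_dirs) > 0) {
      disc <- disc + 1L
    }
  }
  list(
    ascending_shared = asc, descending_shared = desc, discordant = disc
  )
}
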