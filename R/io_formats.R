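# Readers/writers for the on-disk formats the pipeline touches: BLAST
# tabular hit files, FASTA (lengths only), abundance tables, and the
# homology-map interchange TSV.

#' Column names of the standard 12-column BLAST tabular format
#'
#' The classic `-outfmt 6` ordering. An optional 13th column is
#' interpreted as the query sequence length (`qlen`).
#'
#' @keywords internal
blast_columns <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
  "evalue", "bit_score"
)

#' Read a BLAST tabular hit file
#'
#' Parses a tab-separated BLAST hit file in the standard 12-column
#' `-outfmt 6` ordering. An optional 13th column, when present, is taken
#' to be the query sequence length; otherwise `query_length` is filled
#' from `length_index` where available and left `NA` elsewhere.
#'
#' @param path Path to a tab-separated hit file.
#' @param length_index Optional named integer/numeric vector mapping
#'   query identifiers to sequence lengths (e.g. from
#'   [read_fasta_lengths()]).
#' @return A data frame with one row per hit, in file order, with columns
#'   `query_id`, `subject_id`, `percent_identity`, `alignment_length`,
#'   `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bit_score`, `query_length`.
#' @details Malformed lines (wrong column count, non-numeric e-value)
#'   raise a parse error naming the offending line number; negative
#'   e-values raise a validation error. `qstart <= qend` is enforced;
#'   `send < sstart` is allowed (reverse-orientation subject coordinates).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("t1\tg1\t98.5\t300\t4\t0\t1\t300\t10\t309\t1e-150\t550", f)
#' read_blast_tab(f)
read_blast_tab <- function(path, length_index = NULL) {
  if (!file.exists(path)) stop("BLAST hit file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  empty <- data.frame(matrix(nrow = 0, ncol = 13))
  names(empty) <- c(blast_columns, "query_length")
  if (length(nf) == 0) return(empty)
  bad <- which(!(nf %in% c(12L, 13L)))
  if (length(bad) > 0) {
    stop(sprintf(
      "parse error at line %d of %s: expected 12 or 13 tab-separated columns, found %d",
      bad[1], path, nf[bad[1]]
    ))
  }
  has_qlen <- any(nf == 13L)
  hits <- utils::read.table(
    path, sep = "\t", quote = "", comment.char = "",
    stringsAsFactors = FALSE, fill = TRUE,
    col.names = c(blast_columns, if (has_qlen) "query_length"),
    colClasses = c(
      "character", "character", rep("character", 10),
      if (has_qlen) "character"
    )
  )
  num_cols <- setdiff(names(hits), c("query_id", "subject_id"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(hits[[cc]]))
    bad <- which(is.na(v) & !is.na(hits[[cc]]) & nzchar(hits[[cc]]))
    if (length(bad) > 0) {
      stop(sprintf(
        "parse error at line %d of %s: non-numeric value '%s' in column %s",
        bad[1], path, hits[[cc]][bad[1]], cc
      ))
    }
    hits[[cc]] <- v
  }
  if (!has_qlen) hits$query_length <- NA_real_
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stop("validation error: negative e-value in ", path)
  }
  if (any(hits$alignment_length < 1, na.rm = TRUE)) {
    stop("validation error: alignment_length < 1 in ", path)
  }
  if (any(hits$qstart > hits$qend, na.rm = TRUE)) {
    stop("validation error: qstart > qend in ", path)
  }
  if (!is.null(length_index)) {
    fill <- is.na(hits$query_length)
    hits$query_length[fill] <- unname(length_index[hits$query_id[fill]])
  }
  hits
}

#' Read sequence lengths from a FASTA file
#'
#' Returns the number of sequence characters per record, keyed by the
#' record identifier truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named integer vector of sequence lengths.
#' @details Duplicate identifiers (after truncation) raise an error
#'   listing the identifier; an empty file yields an empty map with a
#'   warning.
#' @export
read_fasta_lengths <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(startsWith(trimws(lines), ">"))) {
    warning("no FASTA records in ", path)
    return(stats::setNames(integer(0), character(0)))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate FASTA identifier(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  stats::setNames(Biostrings::width(seqs), ids)
}

#' Read a transcript/gene abundance table
#'
#' Reads a tab-separated abundance table whose first row holds sample
#' identifiers and whose first column holds feature identifiers
#' (RSEM-style estimated counts or TPM).
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (features x samples) with feature identifiers
#'   as row names and sample identifiers as column names.
#' @details Negative values and missing cells raise a validation error;
#'   ragged rows raise a parse error. A header-only file yields a
#'   zero-row matrix.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) stop("parse error: empty abundance table ", path)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf(
      "parse error at line %d of %s: ragged row (%d fields, expected %d)",
      bad, path, nf[bad], nf[1]
    ))
  }
  tab <- utils::read.table(
    path, sep = "\t", header = TRUE, quote = "", comment.char = "",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (nrow(tab) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(tab) - 1)
    colnames(m) <- names(tab)[-1]
    return(m)
  }
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop(
      "validation error: duplicate feature identifier(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (anyDuplicated(names(tab)[-1])) {
    stop("validation error: duplicate sample identifiers in ", path)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("parse error: non-numeric abundance values in ", path)
  if (anyNA(m)) stop("validation error: missing abundance values in ", path)
  if (any(m < 0)) stop("validation error: negative abundance values in ", path)
  rownames(m) <- ids
  m
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()].
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(values, path) {
  df <- data.frame(
    feature_id = rownames(values), values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hit table in BLAST tabular format
#'
#' Writes the 12 standard columns plus the query length as a 13th
#' column when present. Inverse of [read_blast_tab()].
#'
#' @param hits Hit data frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- blast_columns
  if ("query_length" %in% names(hits) && !anyNA(hits$query_length)) {
    cols <- c(cols, "query_length")
  }
  utils::write.table(
    hits[, cols, drop = FALSE], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

homology_map_columns <- c(
  "transcript_id", "gene_id", "method", "evalue", "bit_score"
)

#' Validate a homology map
#'
#' A homology map is a data frame with columns `transcript_id`,
#' `gene_id`, `method` (one of `"rbb"`, `"conditional"`), `evalue` and
#' `bit_score`, in which every transcript appears at most once
#' (many-to-one transcripts to genes).
#'
#' @param map Data frame to validate.
#' @return `map`, invisibly, or an error.
#' @export
validate_homology_map <- function(map) {
  missing_cols <- setdiff(homology_map_columns, names(map))
  if (length(missing_cols) > 0) {
    stop(
      "validation error: homology map lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (anyDuplicated(map$transcript_id)) {
    stop(
      "validation error: transcript(s) assigned more than once: ",
      paste(unique(map$transcript_id[duplicated(map$transcript_id)]),
        collapse = ", "
      )
    )
  }
  if (!all(map$method %in% c("rbb", "conditional"))) {
    stop("validation error: method must be 'rbb' or 'conditional'")
  }
  invisible(map)
}

#' Write a homology map as TSV
#'
#' Writes the fixed five-column tab-separated interchange format with
#' header `transcript_id`, `gene_id`, `method`, `evalue`, `bit_score`.
#'
#' @param map A homology map (see [validate_homology_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_map <- function(map, path) {
  validate_homology_map(map)
  utils::write.table(
    map[, homology_map_columns, drop = FALSE], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a homology map from TSV
#'
#' @param path Path to a file written by [write_homology_map()].
#' @return A validated homology map data frame.
#' @export
read_homology_map <- function(path) {
  if (!file.exists(path)) stop("homology map file not found: ", path)
  map <- utils::read.table(
    path, sep = "\t", header = TRUE, quote = "", comment.char = "",
    stringsAsFactors = FALSE,
    colClasses = c(
      transcript_id = "character", gene_id = "character",
      method = "character", evalue = "numeric", bit_score = "numeric"
    )
  )
  validate_homology_map(map)
  map
}
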