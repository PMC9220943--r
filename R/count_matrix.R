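#' Construct a count matrix with sample metadata
#'
#' The basic container for feature-by-sample integer counts plus per-sample
#' metadata. Metadata must provide `condition` (two-group label, e.g.
#' `tumor`/`normal`) and `batch`; optional columns such as `tumor_type`,
#' `met_site` or `patient` are carried along and used by grouping variants
#' (primary-vs-normal, matched pairs).
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with one row per sample; must contain columns
#'   `sample`, `condition`, `batch` and cover every column of `counts`.
#' @return an object of class `CountMatrix` (a list with elements `counts`
#'   and `meta`).
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_usage("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) abort_usage("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) abort_usage("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_usage("counts must be finite non-negative integers")
  }
  storage.mode(counts) <- "double"   # keeps > .Machine$integer.max safe
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  stopifnot_fields(meta, c("sample", "condition", "batch"), "meta")
  if (anyDuplicated(meta$sample)) abort_usage("duplicate sample ids in meta")
  missing_meta <- setdiff(colnames(counts), meta$sample)
  if (length(missing_meta)) {
    abort_usage(sprintf("samples without metadata: %s",
                        paste(missing_meta, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (anyNA(meta$condition) || anyNA(meta$batch)) {
    abort_usage("every sample needs a condition and a batch")
  }
  structure(list(counts = counts, meta = meta), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:",
      paste(sprintf("%s=%d", names(table(x$meta$condition)),
                    table(x$meta$condition)), collapse = ", "), "\n")
  cat("batches:", paste(unique(x$meta$batch), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by samples
#'
#' @param x a `CountMatrix`.
#' @param samples character vector of sample ids to keep.
#' @return a `CountMatrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "CountMatrix"))
  bad <- setdiff(samples, colnames(x$counts))
  if (length(bad)) {
    abort_usage(sprintf("unknown sample(s): %s", paste(bad, collapse = ", ")))
  }
  count_matrix(x$counts[, samples, drop = FALSE],
               x$meta[match(samples, x$meta$sample), , drop = FALSE])
}

#' Write a CountMatrix to counts + metadata TSV files
#'
#' @param x a `CountMatrix`.
#' @param counts_path,meta_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_count_matrix <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "CountMatrix"))
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(x$meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read a CountMatrix from counts + metadata TSV files
#'
#' @param counts_path TSV with a `feature` id column then one column per
#'   sample.
#' @param meta_path TSV with `sample`, `condition`, `batch` columns.
#' @return a `CountMatrix`.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  df <- read_tsv(counts_path)
  if (!"feature" %in% names(df)) {
    abort_input(sprintf("%s: first column must be named 'feature'",
                        counts_path))
  }
  m <- as.matrix(df[, setdiff(names(df), "feature"), drop = FALSE])
  if (!is.numeric(m)) abort_input(sprintf("%s: non-numeric counts", counts_path))
  rownames(m) <- df$feature
  count_matrix(m, read_tsv(meta_path))
}
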