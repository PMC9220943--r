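#' @keywords internal
#' @import data.table
"_PACKAGE"

.datatable.aware <- TRUE

## Condition classes: usage errors (bad arguments / CLI misuse), input errors
## (missing or malformed files, invalid designs), and plain computation errors.
## The CLI maps these to distinct exit codes.

abort_usage <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("mirptr_usage_error", "error", "condition")))
}

abort_input <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("mirptr_input_error", "error", "condition")))
}

#' Derive a child RNG seed from a global seed and a stage tag
#'
#' One global seed drives a whole run; every sub-generator (miRNA counts,
#' paired PTR matrices, UTR sequences, signal tracks, permutation draws)
#' derives its own deterministic child seed so stages can be re-run
#' independently and still reproduce the full-run stream.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return an integer in `[0, 2^31)`.
#' @export
child_seed <- function(seed, tag) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_usage("seed must be a single non-missing integer")
  }
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(tag)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

## TSV dialect used everywhere: tab separated, UTF-8, '.' decimal, NA for
## absent values, header row always present.

write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    comment.char = "", quote = "")
}

write_lines <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(x), path)
  invisible(path)
}

read_gene_list <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("gene list not found: %s", path))
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x > 0
}

stopifnot_fields <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss)) {
    abort_usage(sprintf("%s is missing field(s): %s", what,
                        paste(miss, collapse = ", ")))
  }
}
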