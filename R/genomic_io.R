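## Genomic file dialects. On disk: BED and bedGraph are 0-based half-open,
## GFF3 is 1-based inclusive. In memory everything is a GRanges (1-based
## inclusive); rtracklayer readers do the conversion, writers here are
## deterministic plain-text emitters so that repeated runs are byte
## identical.

#' Write intervals as BED6
#'
#' @param gr a `GRanges`; interval names become the BED name column.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed6 <- function(gr, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  nm <- if (is.null(names(gr))) sprintf("iv_%d", seq_along(gr)) else names(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   nm, 0L, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (>= 4 columns expected for named intervals).
#' @return a `GRanges` with names taken from the BED name column.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("BED not found: %s", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write a miRNA annotation as GFF3
#'
#' @param gr named `GRanges` of mature miRNA intervals.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gff3_mirnas <- function(gr, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  nm <- if (is.null(names(gr))) sprintf("mir_%d", seq_along(gr)) else names(gr)
  lines <- c("##gff-version 3",
             sprintf("%s\tmirptr_sim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     BiocGenerics::start(gr), BiocGenerics::end(gr),
                     as.character(BiocGenerics::strand(gr)), nm, nm))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mature miRNA annotation (GFF3 or BED)
#'
#' @param path annotation path; format inferred from the extension.
#' @return a named `GRanges` of mature miRNA intervals.
#' @export
read_mirna_annotation <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("annotation not found: %s", path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) return(read_bed(path))
  gr <- rtracklayer::import(path, format = "GFF3")
  nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
  if (is.null(nm)) abort_input(sprintf("%s: GFF3 records need ID or Name", path))
  names(gr) <- nm
  gr
}

#' Write a signal track as bedGraph
#'
#' @param gr `GRanges` with a numeric `score` column (minus-strand nascent
#'   signal is conventionally negative).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(gr, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   sprintf("%.10g", gr$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path.
#' @param strand optional strand ("+"/"-") to assign to all intervals, for
#'   per-strand track files.
#' @return a `GRanges` with a `score` column.
#' @export
read_bedgraph <- function(path, strand = NULL) {
  if (!file.exists(path)) abort_input(sprintf("bedGraph not found: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(strand)) BiocGenerics::strand(gr) <- strand
  gr
}
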