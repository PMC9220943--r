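## A miRNA locus spans from the nearest upstream TRE (its promoter) to the
## end of the mature miRNA, in transcription orientation: on the minus
## strand "upstream" means greater genomic coordinates. Gaps are measured
## from the TRE edge closest to the mature 5' end; a TRE overlapping the
## mature 5' end qualifies with gap 0. Ties are broken by wider TRE, then
## lexicographic id.

#' Assign the promoter TRE and construct the miRNA locus
#'
#' @param mirna length-1 named `GRanges` of the mature miRNA (strand + or -).
#' @param tres named `GRanges` of TRE calls (strand ignored; TREs are
#'   divergent-transcription calls).
#' @param max_distance maximum upstream gap in bp (default 1e5).
#' @return a list of class `MirnaLocus`: `mirna_id`, `mature`, `strand`,
#'   `promoter_id`, `locus` (a `GRanges`, or NULL when absent) and `reason`
#'   ("" or "no_upstream_tre").
#' @export
assign_promoter <- function(mirna, tres, max_distance = 1e5) {
  stopifnot(length(mirna) == 1L, !is.null(names(tres)))
  if (max_distance <= 0) abort_usage("max_distance must be > 0")
  strand <- as.character(BiocGenerics::strand(mirna))
  if (!strand %in% c("+", "-")) abort_usage("miRNA strand must be + or -")
  chrom <- as.character(GenomicRanges::seqnames(mirna))
  m_start <- BiocGenerics::start(mirna)
  m_end <- BiocGenerics::end(mirna)
  same <- as.character(GenomicRanges::seqnames(tres)) == chrom
  cand <- tres[same]
  if (strand == "+") {
    qual <- BiocGenerics::start(cand) <= m_start
    cand <- cand[qual]
    gap <- pmax(0L, (m_start - 1L) - BiocGenerics::end(cand))
  } else {
    qual <- BiocGenerics::end(cand) >= m_end
    cand <- cand[qual]
    gap <- pmax(0L, (BiocGenerics::start(cand) - 1L) - m_end)
  }
  keep <- gap <= max_distance
  cand <- cand[keep]; gap <- gap[keep]
  out <- list(mirna_id = names(mirna), mature = mirna, strand = strand,
              promoter_id = NA_character_, locus = NULL, reason = "")
  class(out) <- "MirnaLocus"
  if (!length(cand)) {
    out$reason <- "no_upstream_tre"
    return(out)
  }
  o <- order(gap, -BiocGenerics::width(cand), names(cand))
  best <- cand[o[1L]]
  out$promoter_id <- names(best)
  locus <- if (strand == "+") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      BiocGenerics::start(best), m_end), strand = strand)
  } else {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      m_start, BiocGenerics::end(best)), strand = strand)
  }
  names(locus) <- names(mirna)
  out$locus <- locus
  out
}

#' Assign promoters for a whole miRNA annotation
#'
#' @param mirnas named `GRanges` of mature miRNAs.
#' @param tres named `GRanges` of TREs.
#' @param max_distance maximum upstream gap in bp.
#' @return data.frame (one row per miRNA): mirna, chrom, locus_start,
#'   locus_end (0-based half-open, BED convention), strand, promoter_id,
#'   reason ("" for assigned loci).
#' @export
assign_promoters <- function(mirnas, tres, max_distance = 1e5) {
  stopifnot(!is.null(names(mirnas)))
  rows <- lapply(seq_along(mirnas), function(i) {
    ml <- assign_promoter(mirnas[i], tres, max_distance)
    if (is.null(ml$locus)) {
      data.frame(mirna = ml$mirna_id, chrom = NA_character_,
                 locus_start = NA_integer_, locus_end = NA_integer_,
                 strand = ml$strand, promoter_id = NA_character_,
                 reason = ml$reason, stringsAsFactors = FALSE)
    } else {
      data.frame(mirna = ml$mirna_id,
                 chrom = as.character(GenomicRanges::seqnames(ml$locus)),
                 locus_start = BiocGenerics::start(ml$locus) - 1L,
                 locus_end = BiocGenerics::end(ml$locus),
                 strand = ml$strand, promoter_id = ml$promoter_id,
                 reason = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Sum nascent-transcription signal over a locus
#'
#' Total absolute signal over the locus interval. By default only track
#' intervals on the miRNA strand (or unstranded intervals) contribute;
#' `strand_mode = "both"` sums both strands. Minus-strand bedGraph values
#' are conventionally negative, hence the absolute values.
#'
#' @param locus a `MirnaLocus` from [assign_promoter()], or a length-1
#'   `GRanges`.
#' @param track a `GRanges` with a numeric `score` column (run-length
#'   encoded signal).
#' @param strand_mode "mirna" (default) or "both".
#' @return nonnegative total signal.
#' @export
sum_locus_signal <- function(locus, track, strand_mode = c("mirna", "both")) {
  strand_mode <- match.arg(strand_mode)
  gr <- if (inherits(locus, "MirnaLocus")) locus$locus else locus
  if (is.null(gr)) abort_usage("locus is absent (no promoter assigned)")
  stopifnot(length(gr) == 1L)
  if (any(!is.finite(track$score))) abort_input("track has non-finite signal values")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  tr_chrom <- as.character(GenomicRanges::seqnames(track))
  if (!chrom %in% tr_chrom) {
    abort_input(sprintf("chromosome %s missing from track", chrom))
  }
  keep <- tr_chrom == chrom
  if (strand_mode == "mirna") {
    st <- as.character(BiocGenerics::strand(gr))
    tr_st <- as.character(BiocGenerics::strand(track))
    keep <- keep & (tr_st == st | tr_st == "*")
  }
  tr <- track[keep]
  ov_start <- pmax(BiocGenerics::start(tr), BiocGenerics::start(gr))
  ov_end <- pmin(BiocGenerics::end(tr), BiocGenerics::end(gr))
  w <- pmax(0L, ov_end - ov_start + 1L)
  sum(abs(tr$score) * w)
}

#' Size factors from genome-wide signal totals
#'
#' @param totals named per-sample genome-wide signal totals.
#' @return named factors scaled to geometric mean 1.
#' @export
signal_size_factors <- function(totals) {
  if (any(totals <= 0)) abort_input("genome-wide signal totals must be positive")
  totals / exp(mean(log(totals)))
}

#' Differential transcription of miRNA loci
#'
#' Per-sample locus totals are rounded to integers and passed through the
#' negative-binomial Wald machinery ([nb_wald_de()]); size factors come from
#' genome-wide signal totals when supplied, else median-of-ratios on the
#' locus totals themselves.
#'
#' @param totals numeric matrix, loci x samples.
#' @param meta sample metadata (sample, condition, batch).
#' @param genome_totals optional named per-sample genome-wide signal totals.
#' @param ... passed to [nb_wald_de()].
#' @return a `DeTable` (see [nb_wald_de()]).
#' @export
locus_differential_transcription <- function(totals, meta,
                                             genome_totals = NULL, ...) {
  cm <- count_matrix(round(as.matrix(totals)), meta)
  sf <- if (!is.null(genome_totals)) signal_size_factors(genome_totals) else NULL
  nb_wald_de(cm, size_factors = sf, ...)
}

#' Transcription-vs-expression concordance of miRNA fold changes
#'
#' Joins the expression (small RNA-seq) and transcription (locus nascent
#' signal) differential tables, reports the sign-agreement fraction over
#' miRNAs significant in expression, and flags miRNAs whose expression
#' change exceeds their transcription change by more than `gap` log2 units —
#' candidates for posttranscriptional regulation.
#'
#' @param mirna_de expression `DeTable`.
#' @param locus_de transcription `DeTable`.
#' @param alpha significance cutoff on expression padj (default 0.05).
#' @param gap log2 gap |expression lfc| - |transcription lfc| above which a
#'   miRNA is flagged (default 2).
#' @return list with `table` (paired log2fc per miRNA with `ptr_candidate`
#'   flag) and `sign_agreement` (fraction over expression-significant
#'   miRNAs).
#' @export
concordance_report <- function(mirna_de, locus_de, alpha = 0.05, gap = 2) {
  shared <- intersect(mirna_de$feature, locus_de$feature)
  if (!length(shared)) abort_input("no shared miRNA ids between the two tables")
  e <- mirna_de[match(shared, mirna_de$feature), ]
  t <- locus_de[match(shared, locus_de$feature), ]
  tab <- data.frame(
    mirna = shared,
    log2fc_expression = e$log2fc, padj_expression = e$padj,
    log2fc_transcription = t$log2fc, padj_transcription = t$padj,
    sign_agree = sign(e$log2fc) == sign(t$log2fc),
    ptr_candidate = (abs(e$log2fc) - abs(t$log2fc)) > gap,
    stringsAsFactors = FALSE, row.names = NULL)
  sig <- !is.na(tab$padj_expression) & tab$padj_expression < alpha &
    !is.na(tab$sign_agree)
  list(table = tab,
       sign_agreement = if (any(sig)) mean(tab$sign_agree[sig]) else NA_real_)
}
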