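#' Parameters for posttranscriptional-regulation classification
#'
#' Defaults follow the published rule: transcriptionally unchanged means
#' ChRO-seq |log2FC| < 0.59 (0.59 as printed, ~log2 1.5) with ChRO-seq
#' FDR > 0.2; the expression arm requires normalized mean > 1000 in the
#' relevant group (normal for gain, tumor for loss), |RNA-seq log2FC| > 1
#' with the matching sign, and RNA-seq FDR < 0.05.
#'
#' @param chro_lfc_bound transcription log2fc bound (default 0.59).
#' @param chro_fdr_floor transcription FDR must exceed this (default 0.2).
#' @param rna_abs_lfc_min expression |log2fc| threshold (default 1).
#' @param rna_fdr_max expression FDR ceiling (default 0.05).
#' @param min_mean normalized-count floor on the qualifying group mean
#'   (default 1000).
#' @param strict_methods if TRUE, apply the one-sided transcription bounds
#'   as printed in the methods text (GPR: chro log2fc > -0.59; LPR: chro
#'   log2fc < 0.59) instead of the symmetric |log2fc| < 0.59 reading.
#' @return a list of class `PtrParams`.
#' @export
ptr_params <- function(chro_lfc_bound = 0.59, chro_fdr_floor = 0.2,
                       rna_abs_lfc_min = 1, rna_fdr_max = 0.05,
                       min_mean = 1000, strict_methods = FALSE) {
  for (f in c("chro_lfc_bound", "chro_fdr_floor", "rna_abs_lfc_min",
              "rna_fdr_max", "min_mean")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort_usage(sprintf("PtrParams field '%s' must be a positive number", f))
    }
  }
  structure(list(chro_lfc_bound = chro_lfc_bound,
                 chro_fdr_floor = chro_fdr_floor,
                 rna_abs_lfc_min = rna_abs_lfc_min,
                 rna_fdr_max = rna_fdr_max, min_mean = min_mean,
                 strict_methods = isTRUE(strict_methods)),
            class = "PtrParams")
}

#' Classify genes under gain or loss of posttranscriptional regulation
#'
#' Integrates a transcription (ChRO-seq) and an expression (RNA-seq)
#' differential table over a shared gene namespace. GPR (gain of PTR):
#' transcriptionally unchanged but significantly downregulated at steady
#' state with normal-group mean above the floor. LPR (loss of PTR): the
#' mirror image, qualified on the tumor-group mean. Everything else is
#' unclassified with the first failing condition as the reason code
#' (`missing_modality`, `transcriptional_change`, `low_expression`,
#' `expression_lfc`, `expression_fdr`); genes with absent statistics fail
#' the corresponding condition.
#'
#' @param chro transcription `DeTable` (needs feature, log2fc, padj).
#' @param rna expression `DeTable` (needs feature, log2fc, padj,
#'   mean_tumor, mean_normal).
#' @param params a [ptr_params()].
#' @return a `PtrLabelTable` data.frame: gene, class (GPR/LPR/unclassified),
#'   chro_log2fc, chro_fdr, rna_log2fc, rna_fdr, mean_tumor, mean_normal,
#'   reason.
#' @export
classify_ptr <- function(chro, rna, params = ptr_params()) {
  for (tab in list(chro = chro, rna = rna)) {
    if (!is.data.frame(tab) || !nrow(tab)) abort_input("empty DeTable")
    if (anyDuplicated(tab$feature)) abort_input("duplicated gene ids in DeTable")
  }
  genes <- sort(union(chro$feature, rna$feature))
  ic <- match(genes, chro$feature)
  ir <- match(genes, rna$feature)
  out <- data.frame(
    gene = genes,
    class = "unclassified",
    chro_log2fc = chro$log2fc[ic], chro_fdr = chro$padj[ic],
    rna_log2fc = rna$log2fc[ir], rna_fdr = rna$padj[ir],
    mean_tumor = rna$mean_tumor[ir], mean_normal = rna$mean_normal[ir],
    reason = "", stringsAsFactors = FALSE, row.names = NULL)

  missing <- is.na(ic) | is.na(ir)
  ok <- function(x) !is.na(x)

  txn_flat_gpr <- if (params$strict_methods) {
    ok(out$chro_log2fc) & out$chro_log2fc > -params$chro_lfc_bound
  } else {
    ok(out$chro_log2fc) & abs(out$chro_log2fc) < params$chro_lfc_bound
  }
  txn_flat_lpr <- if (params$strict_methods) {
    ok(out$chro_log2fc) & out$chro_log2fc < params$chro_lfc_bound
  } else {
    txn_flat_gpr
  }
  txn_quiet <- ok(out$chro_fdr) & out$chro_fdr > params$chro_fdr_floor

  gpr <- txn_flat_gpr & txn_quiet &
    ok(out$mean_normal) & out$mean_normal > params$min_mean &
    ok(out$rna_log2fc) & out$rna_log2fc < -params$rna_abs_lfc_min &
    ok(out$rna_fdr) & out$rna_fdr < params$rna_fdr_max
  lpr <- txn_flat_lpr & txn_quiet &
    ok(out$mean_tumor) & out$mean_tumor > params$min_mean &
    ok(out$rna_log2fc) & out$rna_log2fc > params$rna_abs_lfc_min &
    ok(out$rna_fdr) & out$rna_fdr < params$rna_fdr_max
  gpr[missing] <- FALSE
  lpr[missing] <- FALSE
  out$class[gpr] <- "GPR"
  out$class[lpr] <- "LPR"

  uncls <- which(out$class == "unclassified")
  for (i in uncls) {
    out$reason[i] <- if (missing[i]) {
      "missing_modality"
    } else if (!(txn_flat_gpr[i] || txn_flat_lpr[i]) || !txn_quiet[i]) {
      "transcriptional_change"
    } else {
      ## transcription passed at least one branch: pick the branch by the
      ## expression fold-change sign, conditions in printed order
      ## (mean floor, log2fc, FDR)
      neg <- ok(out$rna_log2fc[i]) && out$rna_log2fc[i] < 0
      mean_ok <- if (neg) {
        ok(out$mean_normal[i]) && out$mean_normal[i] > params$min_mean
      } else {
        ok(out$mean_tumor[i]) && out$mean_tumor[i] > params$min_mean
      }
      lfc_ok <- ok(out$rna_log2fc[i]) &&
        abs(out$rna_log2fc[i]) > params$rna_abs_lfc_min
      if (!mean_ok) "low_expression"
      else if (!lfc_ok) "expression_lfc"
      else "expression_fdr"
    }
  }
  out
}
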