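#' Configuration for the synthetic-data generators
#'
#' One config object drives every generator so that a single run produces
#' internally consistent inputs: the miRNA count experiment, the paired
#' transcription/expression gene matrices, 3'UTR and mature-miRNA sequences
#' with planted seed sites, and TRE/signal tracks. Defaults emulate the
#' structure of the deposited patient cohorts at desk scale: 33 tumor vs 10
#' normal samples in 2 sequencing batches, negative-binomial counts
#' (variance = mu + alpha * mu^2) with alpha = 0.05, abundances spanning
#' several orders of magnitude so that a 1000-normalized-count floor is
#' discriminative.
#'
#' @param n_mirnas number of simulated miRNAs.
#' @param n_genes number of simulated genes (the enrichment universe).
#' @param n_tumor,n_normal samples per condition.
#' @param n_batches number of sequencing batches (balanced across
#'   conditions).
#' @param batch_effect_sd std dev of the per-feature additive batch shift on
#'   the log2 scale.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param planted_up_mirnas,planted_down_mirnas named numeric vectors:
#'   names are miRNA ids (`mir_0001`...), values the planted tumor-vs-normal
#'   log2 fold changes (positive for up, negative for down).
#' @param planted_gpr,planted_lpr,planted_transcriptional named numeric
#'   vectors of gene ids (`gene_00001`...) with planted RNA-seq log2 fold
#'   changes; GPR genes are transcriptionally flat with RNA change <= -1,
#'   LPR the mirror image, transcriptional genes change concordantly in
#'   both modalities. The three sets must be disjoint.
#' @param master_mirna id of the miRNA whose seed sites are enriched in
#'   GPR-gene UTRs (NULL for none).
#' @param site_enrichment_odds multiplier (>= 1) on the master miRNA's
#'   per-UTR site rate inside GPR-gene UTRs relative to background.
#' @param utr_length_range integer length-2 vector, min/max simulated 3'UTR
#'   length in nt.
#' @param baseline_site_rate expected injected seed sites per kb of UTR for
#'   every miRNA (Poisson rate).
#' @param planted_log2_mean log2 baseline abundance assigned to planted
#'   miRNAs/genes (default 11, i.e. ~2000 normalized counts, safely above
#'   the 1000-count selection floor like the dysregulated miRNAs of
#'   interest).
#' @param library_size_sd std dev (log2 scale) of per-sample library-size
#'   factors; 0 gives equal library sizes.
#' @param rng_seed global integer seed; each generator derives a child
#'   stream via [child_seed()].
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(n_mirnas = 500L,
                       n_genes = 10000L,
                       n_tumor = 33L,
                       n_normal = 10L,
                       n_batches = 2L,
                       batch_effect_sd = 0.3,
                       dispersion = 0.05,
                       planted_up_mirnas = numeric(0),
                       planted_down_mirnas = numeric(0),
                       planted_gpr = numeric(0),
                       planted_lpr = numeric(0),
                       planted_transcriptional = numeric(0),
                       master_mirna = NULL,
                       site_enrichment_odds = 3,
                       utr_length_range = c(200L, 2000L),
                       baseline_site_rate = 0.5,
                       planted_log2_mean = 11,
                       library_size_sd = 0.35,
                       rng_seed = 1L) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes, n_tumor = n_tumor,
              n_normal = n_normal, n_batches = n_batches,
              batch_effect_sd = batch_effect_sd, dispersion = dispersion,
              planted_up_mirnas = planted_up_mirnas,
              planted_down_mirnas = planted_down_mirnas,
              planted_gpr = planted_gpr, planted_lpr = planted_lpr,
              planted_transcriptional = planted_transcriptional,
              master_mirna = master_mirna,
              site_enrichment_odds = site_enrichment_odds,
              utr_length_range = as.integer(utr_length_range),
              baseline_site_rate = baseline_site_rate,
              planted_log2_mean = planted_log2_mean,
              library_size_sd = library_size_sd,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_mirnas", "n_genes", "n_tumor", "n_normal", "n_batches")) {
    if (!is_count1(cfg[[f]])) {
      abort_usage(sprintf("SimConfig field '%s' must be a positive integer", f))
    }
  }
  if (!is.numeric(cfg$batch_effect_sd) || cfg$batch_effect_sd < 0) {
    abort_usage("SimConfig field 'batch_effect_sd' must be >= 0")
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0) {
    abort_usage("SimConfig field 'dispersion' must be >= 0")
  }
  for (f in c("planted_up_mirnas", "planted_down_mirnas", "planted_gpr",
              "planted_lpr", "planted_transcriptional")) {
    v <- cfg[[f]]
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v)))) {
        abort_usage(sprintf("SimConfig field '%s' must be a named numeric vector", f))
      }
      if (any(!is.finite(v))) {
        abort_usage(sprintf("SimConfig field '%s' has non-finite fold changes", f))
      }
    }
  }
  if (any(cfg$planted_up_mirnas <= 0)) {
    abort_usage("SimConfig field 'planted_up_mirnas' must have positive log2fc")
  }
  if (any(cfg$planted_down_mirnas >= 0)) {
    abort_usage("SimConfig field 'planted_down_mirnas' must have negative log2fc")
  }
  if (anyDuplicated(c(names(cfg$planted_up_mirnas),
                      names(cfg$planted_down_mirnas)))) {
    abort_usage("SimConfig: planted miRNA sets must be disjoint")
  }
  gene_sets <- c(names(cfg$planted_gpr), names(cfg$planted_lpr),
                 names(cfg$planted_transcriptional))
  if (anyDuplicated(gene_sets)) {
    abort_usage("SimConfig: planted gene sets must be disjoint")
  }
  if (!is.numeric(cfg$site_enrichment_odds) || cfg$site_enrichment_odds < 1) {
    abort_usage("SimConfig field 'site_enrichment_odds' must be >= 1")
  }
  if (length(cfg$utr_length_range) != 2L ||
      any(cfg$utr_length_range <= 0) ||
      cfg$utr_length_range[1] > cfg$utr_length_range[2]) {
    abort_usage("SimConfig field 'utr_length_range' must be an increasing positive pair")
  }
  if (!is.numeric(cfg$baseline_site_rate) || cfg$baseline_site_rate < 0) {
    abort_usage("SimConfig field 'baseline_site_rate' must be >= 0")
  }
  if (!is.numeric(cfg$library_size_sd) || cfg$library_size_sd < 0) {
    abort_usage("SimConfig field 'library_size_sd' must be >= 0")
  }
  if (!is.numeric(cfg$rng_seed) || length(cfg$rng_seed) != 1L ||
      is.na(cfg$rng_seed)) {
    abort_usage("SimConfig field 'rng_seed' must be a single integer")
  }
  invisible(cfg)
}

mirna_ids <- function(n) sprintf("mir_%04d", seq_len(n))
gene_ids <- function(n) sprintf("gene_%05d", seq_len(n))

check_planted_ids <- function(planted, ids, field) {
  bad <- setdiff(names(planted), ids)
  if (length(bad)) {
    abort_usage(sprintf("SimConfig field '%s' names unknown feature(s): %s",
                        field, paste(bad, collapse = ", ")))
  }
}
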