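## Negative-binomial count generators. Parameterization throughout:
## variance = mu + alpha * mu^2 (alpha = cfg$dispersion), i.e.
## rnbinom(mu = mu, size = 1/alpha); alpha = 0 degenerates to Poisson.

rnb <- function(n, mu, alpha) {
  if (alpha <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

sim_sample_meta <- function(cfg, prefix = "") {
  n <- cfg$n_tumor + cfg$n_normal
  cond <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  sample <- c(sprintf("%stumor_%02d", prefix, seq_len(cfg$n_tumor)),
              sprintf("%snormal_%02d", prefix, seq_len(cfg$n_normal)))
  ## batches balanced within each condition so batch and condition stay
  ## identifiable in the default design
  batch <- c(sprintf("b%d", rep_len(seq_len(cfg$n_batches), cfg$n_tumor)),
             sprintf("b%d", rep_len(seq_len(cfg$n_batches), cfg$n_normal)))
  patient <- c(sprintf("P%02d", seq_len(cfg$n_tumor)),
               sprintf("P%02d", seq_len(cfg$n_normal)))
  tumor_type <- c(rep_len(c("primary", "metastatic"), cfg$n_tumor),
                  rep("normal", cfg$n_normal))
  met_site <- ifelse(tumor_type == "metastatic",
                     rep_len(c("liver", "lung", "lymph_node", "peritoneal"),
                             n), NA_character_)
  data.frame(sample = sample, condition = cond, batch = batch,
             patient = patient, tumor_type = tumor_type,
             met_site = met_site, stringsAsFactors = FALSE)
}

## Draw an NB count matrix given per-feature baseline (normalized scale,
## = normal-condition mean), per-feature log2fc applied to tumor samples,
## per-feature-per-batch log2 shifts and per-sample depth factors.
sim_nb_matrix <- function(q, lfc, meta, cfg, feature_names) {
  n_f <- length(q)
  n_s <- nrow(meta)
  sf <- 2 ^ stats::rnorm(n_s, 0, cfg$library_size_sd)
  batch_levels <- sort(unique(meta$batch))
  delta <- matrix(0, n_f, length(batch_levels),
                  dimnames = list(NULL, batch_levels))
  if (length(batch_levels) > 1L && cfg$batch_effect_sd > 0) {
    delta[, -1L] <- stats::rnorm(n_f * (length(batch_levels) - 1L),
                                 0, cfg$batch_effect_sd)
  }
  is_tumor <- as.numeric(meta$condition == "tumor")
  log2mu <- outer(log2(q), rep(1, n_s)) +
    outer(lfc, is_tumor) +
    delta[, meta$batch, drop = FALSE] +
    outer(rep(1, n_f), log2(sf))
  mu <- 2 ^ log2mu
  counts <- matrix(rnb(length(mu), mu, cfg$dispersion), n_f, n_s,
                   dimnames = list(feature_names, meta$sample))
  counts
}

#' Simulate a two-condition miRNA count experiment with known truth
#'
#' Counts follow a negative-binomial model with per-sample library-size
#' factors, additive per-feature batch shifts on the log2 scale, and planted
#' condition fold changes. Baseline abundances are log-normal
#' (log2 mean 6, sd 2.5), spanning several orders of magnitude so that a
#' 1000-normalized-count floor separates abundant from rare miRNAs; planted
#' miRNAs get baseline log2 abundance `planted_log2_mean` (default 11) like
#' the high-abundance miRNAs the selection filters target.
#'
#' @param cfg a [sim_config()] object.
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data.frame: feature, class in up/down/null, true_log2fc,
#'   true_base_log2_mean — the normal-condition log2 abundance on the
#'   normalized scale).
#' @export
simulate_mirna_experiment <- function(cfg) {
  validate_sim_config(cfg)
  ids <- mirna_ids(cfg$n_mirnas)
  check_planted_ids(cfg$planted_up_mirnas, ids, "planted_up_mirnas")
  check_planted_ids(cfg$planted_down_mirnas, ids, "planted_down_mirnas")
  with_seed(child_seed(cfg$rng_seed, "mirna_counts"), {
    meta <- sim_sample_meta(cfg)
    base_log2 <- stats::rnorm(cfg$n_mirnas, 6, 2.5)
    planted <- c(cfg$planted_up_mirnas, cfg$planted_down_mirnas)
    if (length(planted)) {
      base_log2[match(names(planted), ids)] <-
        stats::rnorm(length(planted), cfg$planted_log2_mean, 0.5)
    }
    lfc <- stats::setNames(rep(0, cfg$n_mirnas), ids)
    lfc[names(planted)] <- planted
    counts <- sim_nb_matrix(2 ^ base_log2, lfc, meta, cfg, ids)
    truth <- data.frame(
      feature = ids,
      class = ifelse(ids %in% names(cfg$planted_up_mirnas), "up",
              ifelse(ids %in% names(cfg$planted_down_mirnas), "down", "null")),
      true_log2fc = unname(lfc),
      true_base_log2_mean = base_log2,
      stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate paired transcription (ChRO-seq) and expression (RNA-seq) matrices
#'
#' Gene-level matrices for the same two-condition design: genes planted as
#' transcriptional change concordantly in both modalities; gain-of-PTR (GPR)
#' genes are transcriptionally flat with RNA-seq log2fc <= -1; loss-of-PTR
#' (LPR) genes the mirror image; all other genes are unchanged. Planted
#' genes get high baseline abundance (`planted_log2_mean`) so the
#' 1000-normalized-count expression floor is satisfiable.
#'
#' @param cfg a [sim_config()] object; `planted_gpr` values must be <= -1
#'   and `planted_lpr` values >= 1.
#' @return list with elements `chro`, `rna` (both [count_matrix()]) and
#'   `truth` (gene, class in GPR/LPR/transcriptional/null, true_rna_log2fc,
#'   true_chro_log2fc).
#' @export
simulate_ptr_experiment <- function(cfg) {
  validate_sim_config(cfg)
  ids <- gene_ids(cfg$n_genes)
  check_planted_ids(cfg$planted_gpr, ids, "planted_gpr")
  check_planted_ids(cfg$planted_lpr, ids, "planted_lpr")
  check_planted_ids(cfg$planted_transcriptional, ids, "planted_transcriptional")
  if (any(cfg$planted_gpr > -1)) {
    abort_usage("SimConfig field 'planted_gpr' log2fc must be <= -1")
  }
  if (any(cfg$planted_lpr < 1)) {
    abort_usage("SimConfig field 'planted_lpr' log2fc must be >= 1")
  }
  with_seed(child_seed(cfg$rng_seed, "ptr_counts"), {
    rna_lfc <- stats::setNames(rep(0, cfg$n_genes), ids)
    chro_lfc <- rna_lfc
    rna_lfc[names(cfg$planted_gpr)] <- cfg$planted_gpr
    rna_lfc[names(cfg$planted_lpr)] <- cfg$planted_lpr
    rna_lfc[names(cfg$planted_transcriptional)] <- cfg$planted_transcriptional
    chro_lfc[names(cfg$planted_transcriptional)] <- cfg$planted_transcriptional

    base_log2_rna <- stats::rnorm(cfg$n_genes, 8, 2)
    planted_ids <- c(names(cfg$planted_gpr), names(cfg$planted_lpr),
                     names(cfg$planted_transcriptional))
    if (length(planted_ids)) {
      base_log2_rna[match(planted_ids, ids)] <-
        stats::rnorm(length(planted_ids), cfg$planted_log2_mean, 0.5)
    }
    ## nascent signal has its own dynamic range, narrower than steady state
    base_log2_chro <- 7 + 0.5 * (base_log2_rna - 8) +
      stats::rnorm(cfg$n_genes, 0, 1)

    meta_chro <- sim_sample_meta(cfg, prefix = "chro_")
    meta_rna <- sim_sample_meta(cfg, prefix = "rna_")
    chro <- sim_nb_matrix(2 ^ base_log2_chro, chro_lfc, meta_chro, cfg, ids)
    rna <- sim_nb_matrix(2 ^ base_log2_rna, rna_lfc, meta_rna, cfg, ids)
    truth <- data.frame(
      gene = ids,
      class = ifelse(ids %in% names(cfg$planted_gpr), "GPR",
              ifelse(ids %in% names(cfg$planted_lpr), "LPR",
              ifelse(ids %in% names(cfg$planted_transcriptional),
                     "transcriptional", "null"))),
      true_rna_log2fc = unname(rna_lfc),
      true_chro_log2fc = unname(chro_lfc),
      stringsAsFactors = FALSE)
    list(chro = count_matrix(chro, meta_chro),
         rna = count_matrix(rna, meta_rna),
         truth = truth)
  })
}
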