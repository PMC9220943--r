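#' Add-one empirical p-value
#'
#' `p = (n_exceed + 1) / (n_sim + 1)`: the add-one convention avoids p = 0,
#' so the minimum attainable p is `1/(n_sim + 1)` (e.g. 1/1001 at 1000
#' permutations) and 40 exceedances in 1000 give 41/1001.
#'
#' @param n_exceed number of null scores >= the observed score.
#' @param n_sim number of Monte-Carlo simulations.
#' @return empirical p in (0, 1].
#' @export
empirical_pvalue <- function(n_exceed, n_sim) {
  (n_exceed + 1) / (n_sim + 1)
}

#' Monte-Carlo seed-site enrichment test over a gene list
#'
#' For each miRNA family, the observed score is the cumulative number of
#' putative binding sites in the 3'UTRs of the input genes; the null
#' distribution is obtained by drawing `n_sim` random gene lists of the same
#' length uniformly without replacement from the universe. One shared
#' sequence of random lists is used for all families, so family scores are
#' comparable on identical draws. Empirical p uses the add-one convention
#' `p = (#{null >= observed} + 1) / (n_sim + 1)`, hence p is never 0 and its
#' minimum is `1/(n_sim + 1)`.
#'
#' @param genes character vector of unique gene ids, a subset of the
#'   universe.
#' @param map a `TargetSiteMap` from [build_site_map()] or [read_site_map()].
#' @param families family ids to test (default: all rows of the map).
#' @param universe background gene ids sampled from (default: all genes with
#'   an annotated UTR in the map).
#' @param n_sim number of random lists (default 1000).
#' @param rng_seed integer seed; results are exactly reproducible.
#' @param length_binned if TRUE, null genes are drawn within deciles of
#'   3'UTR length matched to the input list instead of uniformly.
#' @return an `EnrichmentResult` data.frame: mirna, observed, n_sim,
#'   null_mean, null_sd, n_exceed, p, neg_log10_p.
#' @export
empirical_enrichment <- function(genes, map, families = NULL, universe = NULL,
                                 n_sim = 1000L, rng_seed = 1L,
                                 length_binned = FALSE) {
  stopifnot(inherits(map, "TargetSiteMap"))
  if (!length(genes)) abort_usage("empty gene list")
  if (anyDuplicated(genes)) abort_usage("gene list must be unique")
  if (is.null(universe)) universe <- map$universe
  if (!all(genes %in% universe)) {
    abort_usage(sprintf("%d gene(s) outside the universe",
                        sum(!genes %in% universe)))
  }
  if (length(genes) >= length(universe)) {
    abort_usage("gene list must be smaller than the universe")
  }
  if (n_sim < 1L) abort_usage("n_sim must be >= 1")
  if (is.null(families)) families <- rownames(map$counts)
  miss <- setdiff(families, rownames(map$counts))
  if (length(miss)) {
    abort_usage(sprintf("families not in site map: %s",
                        paste(utils::head(miss, 5L), collapse = ", ")))
  }
  cts <- map$counts[families, universe, drop = FALSE]
  observed <- as.numeric(cts[, genes, drop = FALSE] %*%
                           rep(1, length(genes)))
  len <- length(genes)
  idx <- with_seed(child_seed(rng_seed, "enrichment_null"), {
    if (!length_binned) {
      vapply(seq_len(n_sim), function(i) sample.int(length(universe), len),
             integer(len))
    } else {
      bins <- findInterval(map$utr_len[universe],
                           stats::quantile(map$utr_len[universe],
                                           probs = seq(0.1, 0.9, 0.1)),
                           left.open = TRUE) + 1L
      need <- table(bins[match(genes, universe)])
      pool <- split(seq_along(universe), bins)
      vapply(seq_len(n_sim), function(i) {
        sort(unlist(lapply(names(need), function(b) {
          sample(pool[[b]], need[[b]])
        }), use.names = FALSE))
      }, integer(len))
    }
  })
  ind <- Matrix::sparseMatrix(i = as.vector(idx),
                              j = rep(seq_len(n_sim), each = len),
                              x = 1, dims = c(length(universe), n_sim))
  null_scores <- as.matrix(cts %*% ind)
  n_exceed <- rowSums(null_scores >= observed)
  p <- empirical_pvalue(n_exceed, n_sim)
  data.frame(mirna = families, observed = observed, n_sim = n_sim,
             null_mean = rowMeans(null_scores),
             null_sd = apply(null_scores, 1L, stats::sd),
             n_exceed = n_exceed, p = p, neg_log10_p = -log10(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank an enrichment table
#'
#' Orders by empirical p, breaking ties by observed score (descending) then
#' miRNA id, and appends a `rank` column.
#'
#' @param res an `EnrichmentResult` data.frame.
#' @return the ranked data.frame.
#' @export
rank_enrichment <- function(res) {
  res <- res[order(res$p, -res$observed, res$mirna), , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- seq_len(nrow(res))
  res
}

#' Master-regulator report: enrichment of miRNA sites in GPR and LPR genes
#'
#' Runs [empirical_enrichment()] twice — upregulated miRNA families against
#' gain-of-PTR genes, downregulated families against loss-of-PTR genes —
#' with the same seed, so both analyses share identical null draws for
#' equal-length lists. Families absent from the site map are excluded and
#' listed. Tables are ranked by -log10 p, ties broken by observed score
#' then id; the -log10 of the p = 0.05 reference line is attached.
#'
#' @param gpr_genes,lpr_genes character vectors of gene ids.
#' @param up_families,down_families family ids (e.g. selected up/down
#'   miRNAs).
#' @param map a `TargetSiteMap`.
#' @param n_sim,rng_seed,universe,length_binned passed to
#'   [empirical_enrichment()].
#' @return list with ranked `gpr` and `lpr` EnrichmentResult tables,
#'   `excluded_up`/`excluded_down` family ids, and `reference_line`
#'   (= -log10(0.05)).
#' @export
master_regulator_report <- function(gpr_genes, lpr_genes, up_families,
                                    down_families, map, n_sim = 1000L,
                                    rng_seed = 1L, universe = NULL,
                                    length_binned = FALSE) {
  if (!length(gpr_genes) || !length(lpr_genes)) {
    abort_usage("gene lists must be nonempty")
  }
  if (!length(up_families) || !length(down_families)) {
    abort_usage("family lists must be nonempty")
  }
  excluded_up <- setdiff(up_families, rownames(map$counts))
  excluded_down <- setdiff(down_families, rownames(map$counts))
  up_use <- setdiff(up_families, excluded_up)
  down_use <- setdiff(down_families, excluded_down)
  if (!length(up_use) || !length(down_use)) {
    abort_usage("no testable families remain after site-map exclusion")
  }
  gpr <- rank_enrichment(empirical_enrichment(
    gpr_genes, map, families = up_use, universe = universe, n_sim = n_sim,
    rng_seed = rng_seed, length_binned = length_binned))
  lpr <- rank_enrichment(empirical_enrichment(
    lpr_genes, map, families = down_use, universe = universe, n_sim = n_sim,
    rng_seed = rng_seed, length_binned = length_binned))
  list(gpr = gpr, lpr = lpr, excluded_up = excluded_up,
       excluded_down = excluded_down, reference_line = -log10(0.05))
}
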