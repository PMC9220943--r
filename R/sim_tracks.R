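#' Simulate TRE calls, a miRNA annotation and nascent-signal tracks
#'
#' Lays each simulated miRNA out in its own genomic block on one chromosome:
#' a designated true promoter TRE 0.5-5 kb upstream (strand-aware: greater
#' coordinates for minus-strand miRNAs), a 22-bp mature miRNA, plus decoy
#' TREs that are farther upstream or strictly downstream so the designated
#' TRE is always the nearest upstream one. Per-sample signal is piled
#' uniformly over [promoter, mature end] on the miRNA strand; planted up/
#' down miRNAs (`planted_up_mirnas` / `planted_down_mirnas`) scale their
#' tumor-condition signal by the planted fold change, making their
#' differential expression transcription-driven. Minus-strand signal is
#' emitted with negative values, as in stranded nascent-run-on bedGraphs.
#' The block layout is collision-free by construction and is validated; a
#' collision aborts.
#'
#' @param cfg a [sim_config()].
#' @return list with `tres` (named `GRanges`), `mirnas` (named `GRanges`),
#'   `tracks` (per-sample named list of `GRanges` with signed `score`),
#'   `meta` (sample metadata) and `truth` (list: `loci` layout table,
#'   `expected` loci x condition pre-noise totals, `realized` loci x sample
#'   totals equal to the emitted bedGraph sums).
#' @export
simulate_tracks <- function(cfg) {
  validate_sim_config(cfg)
  ids <- mirna_ids(cfg$n_mirnas)
  check_planted_ids(cfg$planted_up_mirnas, ids, "planted_up_mirnas")
  check_planted_ids(cfg$planted_down_mirnas, ids, "planted_down_mirnas")
  block <- 20000L
  mature_w <- 22L
  with_seed(child_seed(cfg$rng_seed, "tracks"), {
    meta <- sim_sample_meta(cfg, prefix = "trk_")
    n <- cfg$n_mirnas
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tre_w <- sample(200:600, n, replace = TRUE)
    gap <- sample(500:5000, n, replace = TRUE)
    decoy_w <- sample(200:600, n, replace = TRUE)
    decoy_gap <- sample(3000:6000, n, replace = TRUE)
    anchor <- (seq_len(n) - 1L) * block + 8000L   # 1-based block anchor

    ## plus strand: [promoter][gap][mature]; minus strand mirrored
    prom_start <- prom_end <- m_start <- m_end <- integer(n)
    dec_start <- dec_end <- integer(n)
    plus <- strand == "+"
    prom_start[plus] <- anchor[plus]
    prom_end[plus] <- anchor[plus] + tre_w[plus] - 1L
    m_start[plus] <- prom_end[plus] + gap[plus] + 1L
    m_end[plus] <- m_start[plus] + mature_w - 1L
    ## decoy farther upstream than the promoter
    dec_end[plus] <- prom_start[plus] - decoy_gap[plus]
    dec_start[plus] <- dec_end[plus] - decoy_w[plus] + 1L
    minus <- !plus
    prom_end[minus] <- anchor[minus] + 7000L
    prom_start[minus] <- prom_end[minus] - tre_w[minus] + 1L
    m_end[minus] <- prom_start[minus] - gap[minus] - 1L
    m_start[minus] <- m_end[minus] - mature_w + 1L
    dec_start[minus] <- prom_end[minus] + decoy_gap[minus]
    dec_end[minus] <- dec_start[minus] + decoy_w[minus] - 1L

    if (any(c(m_start, dec_start, prom_start) < 1L)) {
      abort_input("track layout collision: block too small for sampled gaps")
    }
    tres <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(prom_start, dec_start), c(prom_end, dec_end)), strand = "*")
    names(tres) <- c(sprintf("tre_%04d", seq_len(n)),
                     sprintf("dec_%04d", seq_len(n)))
    if (!IRanges::isDisjoint(c(
      tres, GenomicRanges::GRanges("chr1", IRanges::IRanges(m_start, m_end))))) {
      abort_input("track layout collision: overlapping intervals")
    }
    mirnas <- GenomicRanges::GRanges("chr1", IRanges::IRanges(m_start, m_end),
                                     strand = strand)
    names(mirnas) <- ids

    locus_start <- ifelse(plus, prom_start, m_start)
    locus_end <- ifelse(plus, m_end, prom_end)
    width <- locus_end - locus_start + 1L

    lfc <- stats::setNames(rep(0, n), ids)
    lfc[names(cfg$planted_up_mirnas)] <- cfg$planted_up_mirnas
    lfc[names(cfg$planted_down_mirnas)] <- cfg$planted_down_mirnas
    base_total <- 2 ^ stats::runif(n, 8, 12)
    expected <- cbind(normal = base_total, tumor = base_total * 2 ^ lfc)

    n_s <- nrow(meta)
    depth <- 2 ^ stats::rnorm(n_s, 0, cfg$library_size_sd)
    noise <- matrix(2 ^ stats::rnorm(n * n_s, 0, 0.25), n, n_s)
    cond_idx <- ifelse(meta$condition == "tumor", 2L, 1L)
    tot <- expected[, cond_idx, drop = FALSE] *
      matrix(depth, n, n_s, byrow = TRUE) * noise
    ## per-base value rounded as written to bedGraph; realized totals are
    ## defined from the rounded value so file sums match the truth exactly
    val <- round(tot / width, 6L)
    realized <- val * width
    dimnames(realized) <- list(ids, meta$sample)

    dec_val <- stats::runif(n, 0.1, 1)
    dec_strand <- sample(c("+", "-"), n, replace = TRUE)
    tracks <- lapply(seq_len(n_s), function(s) {
      gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(locus_start, dec_start), c(locus_end, dec_end)),
        strand = c(strand, dec_strand),
        score = c(val[, s], round(dec_val * depth[s], 6L)))
      neg <- as.character(BiocGenerics::strand(gr)) == "-"
      gr$score[neg] <- -abs(gr$score[neg])
      BiocGenerics::sort(gr, ignore.strand = TRUE)
    })
    names(tracks) <- meta$sample

    truth <- list(
      loci = data.frame(mirna = ids, chrom = "chr1",
                        locus_start = locus_start - 1L, locus_end = locus_end,
                        strand = strand,
                        promoter_id = sprintf("tre_%04d", seq_len(n)),
                        true_log2fc = unname(lfc), stringsAsFactors = FALSE),
      expected = expected, realized = realized)
    list(tres = tres, mirnas = mirnas, tracks = tracks, meta = meta,
         truth = truth)
  })
}
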