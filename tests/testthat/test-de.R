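make_cm <- function(counts, condition, batch = NULL) {
  if (is.null(batch)) batch <- rep("b1", ncol(counts))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  count_matrix(counts, data.frame(sample = colnames(counts),
                                  condition = condition, batch = batch))
}

test_that("size factors follow the median-of-ratios convention", {
  m1 <- matrix(c(5, 9, 12), dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(compute_size_factors(m1)), 1.0)
  m2 <- cbind(s1 = c(5, 9, 12), s2 = c(5, 9, 12))
  rownames(m2) <- c("a", "b", "c")
  expect_equal(unname(compute_size_factors(m2)), c(1, 1))
  # sample B = 2 x sample A featurewise: factors (2^-1/2, 2^1/2)
  set.seed(4)
  a <- rpois(50, 100) + 1
  m3 <- cbind(s1 = a, s2 = 2 * a)
  rownames(m3) <- sprintf("f%02d", 1:50)
  expect_equal(unname(compute_size_factors(m3)),
               c(2^-0.5, 2^0.5), tolerance = 1e-12)
  # brute-force oracle on a random matrix
  set.seed(9)
  m4 <- matrix(rpois(200, 50) + 1, 40, 5,
               dimnames = list(sprintf("f%02d", 1:40), sprintf("s%d", 1:5)))
  geo <- apply(m4, 1, function(x) exp(mean(log(x))))
  oracle <- apply(m4, 2, function(x) median(x / geo))
  expect_equal(unname(compute_size_factors(m4)), unname(oracle),
               tolerance = 1e-12)
  # scale equivariance: multiplying one sample by c multiplies its factor by
  # c relative to the others (median-of-ratios factors are defined up to a
  # common scale because the geometric-mean reference itself shifts, as the
  # (2^-1/2, 2^1/2) two-sample case above shows)
  m5 <- m4; m5[, 3] <- m5[, 3] * 5
  sf4 <- compute_size_factors(m4); sf5 <- compute_size_factors(m5)
  expect_equal(unname((sf5[3] / sf5[1]) / (sf4[3] / sf4[1])), 5,
               tolerance = 1e-12)
  # no all-nonzero feature
  m6 <- cbind(s1 = c(0, 3), s2 = c(3, 0))
  rownames(m6) <- c("a", "b")
  expect_error(compute_size_factors(m6), "nonzero")
})

test_that("coefficient of variation matches its definition", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(5, 15)), 0.7071068,
               tolerance = 1e-6)
  expect_true(is.na(coefficient_of_variation(c(0, 0, 0))))
  expect_true(is.na(coefficient_of_variation(7)))
})

test_that("geometric-mean log2 fold change handles pseudocounts", {
  expect_equal(as.numeric(geometric_mean_log2fc(c(4, 4, 4), c(1, 1, 1), 0)), 2)
  expect_equal(as.numeric(geometric_mean_log2fc(c(1, 16), c(2, 2), 0)), 1)
  expect_equal(as.numeric(geometric_mean_log2fc(c(0, 3), c(1, 1), 1)), 0)
  expect_error(geometric_mean_log2fc(c(0, 3), c(1, 1), 0), "pseudocount")
  # default pseudocount 1 when zeros occur, recorded in the output
  r <- geometric_mean_log2fc(c(0, 3), c(1, 1))
  expect_equal(attr(r, "pseudocount"), 1)
})

test_that("BH adjustment agrees with a brute-force implementation", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- runif(2500)^(seed)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("miRNA selection applies the published filters", {
  base <- data.frame(feature = "m1", baseMean = 700, mean_tumor = 1500,
                     mean_normal = 10, log2fc = 3, se = 0.2, p = 1e-4,
                     padj = 0.01, cov_tumor = 0.5, stringsAsFactors = FALSE)
  sel <- select_de_mirnas(base)
  expect_equal(sel$up$feature, "m1")
  expect_equal(nrow(sel$down), 0L)
  # CoV 2.5 exceeds the 2.0 maximum
  high_cov <- transform(base, cov_tumor = 2.5)
  expect_equal(nrow(select_de_mirnas(high_cov)$up), 0L)
  # padj 0.2 not significant
  ns <- transform(base, padj = 0.2)
  expect_equal(nrow(select_de_mirnas(ns)$up), 0L)
  # either-group mean floor: normal-high also qualifies
  nh <- transform(base, mean_tumor = 10, mean_normal = 1500, log2fc = -3)
  expect_equal(select_de_mirnas(nh)$down$feature, "m1")
  # optional |log2fc| floor is off by default
  small <- transform(base, log2fc = 0.5)
  expect_equal(nrow(select_de_mirnas(small)$up), 1L)
  expect_equal(nrow(select_de_mirnas(small,
                                     de_params(min_abs_log2fc = 2))$up), 0L)
})

test_that("selection matches the brute-force filter and ignores row order", {
  for (seed in c(11, 12)) {
    de <- random_de_table(400, seed)
    got <- select_de_mirnas(de)
    want <- oracle_select(de)
    expect_equal(got$up, want$up)
    expect_equal(got$down, want$down)
    shuffled <- de[sample.int(nrow(de)), ]
    got2 <- select_de_mirnas(shuffled)
    expect_equal(got2$up, got$up)
    expect_equal(got2$down, got$down)
  }
})

test_that("vst transform is monotone and removes an additive batch offset", {
  set.seed(2)
  counts <- matrix(rpois(100 * 12, 200), 100, 12)
  cond <- rep(c("tumor", "normal"), each = 6)
  # single batch: identity adjustment
  cm1 <- make_cm(counts, cond)
  v1 <- vst_batch_adjust(cm1)
  sf <- compute_size_factors(cm1)
  expect_equal(v1, log2(sweep(counts, 2, sf, "/") + 1),
               ignore_attr = TRUE)
  # monotone in counts for a fixed sample
  c2 <- counts; c2[1, 1] <- c2[1, 1] + 50
  v2 <- vst_batch_adjust(make_cm(c2, cond))
  expect_gt(v2[1, 1], v1[1, 1])
  # balanced two-batch design with an exact per-feature log2 offset on a
  # minority of features (so size factors stay at 1 and the offset must be
  # removed by the batch regression, not by normalization)
  batch <- rep(c("b1", "b2"), 6)
  offset_counts <- counts
  offset_counts[1:30, batch == "b2"] <- offset_counts[1:30, batch == "b2"] * 4
  cmb <- make_cm(offset_counts, cond, batch)
  vb <- vst_batch_adjust(cmb, pseudocount = 0)
  diffs <- rowMeans(vb[1:30, batch == "b2"]) - rowMeans(vb[1:30, batch == "b1"])
  expect_lt(max(abs(diffs)), 1e-6)
})

test_that("nb_wald_de handles flat features, bad designs and sign agreement", {
  counts <- matrix(50, 20, 8,
                   dimnames = list(sprintf("f%02d", 1:20),
                                   sprintf("s%d", 1:8)))
  set.seed(5)
  counts[2:20, ] <- matrix(rpois(19 * 8, 80), 19, 8)
  cm <- make_cm(counts, rep(c("tumor", "normal"), each = 4))
  # identical counts in all samples with equal size factors
  de <- nb_wald_de(cm, size_factors = setNames(rep(1, 8), colnames(counts)))
  expect_lt(abs(de$log2fc[1]), 1e-6)
  expect_gt(de$p[1], 0.9)
  # confounded design: batch identical to condition
  cmc <- make_cm(counts, rep(c("tumor", "normal"), each = 4),
                 batch = rep(c("b1", "b2"), each = 4))
  expect_error(nb_wald_de(cmc), "confounded")
  # single-replicate group
  cm1 <- make_cm(counts[, 1:5], c(rep("tumor", 4), "normal"))
  expect_error(nb_wald_de(cm1), "at least 2")
  # all-zero feature reported with absent p
  z <- counts; z[3, ] <- 0
  dez <- nb_wald_de(make_cm(z, rep(c("tumor", "normal"), each = 4)))
  expect_true(is.na(dez$p[3]))
  expect_true(is.na(dez$padj[3]))
  # sign agreement with group means (equal size factors, single batch)
  cfg <- sim_config(n_mirnas = 300L, n_tumor = 8L, n_normal = 8L,
                    n_batches = 1L, library_size_sd = 0, batch_effect_sd = 0,
                    planted_up_mirnas = c(mir_0001 = 2, mir_0002 = 1),
                    planted_down_mirnas = c(mir_0003 = -2), rng_seed = 8L)
  sim <- simulate_mirna_experiment(cfg)
  de2 <- nb_wald_de(sim$counts)
  both <- de2$mean_tumor > 0 & de2$mean_normal > 0 & !is.na(de2$log2fc) &
    abs(de2$log2fc) > 1e-8
  expect_gt(mean(sign(de2$log2fc[both]) ==
                   sign(log(de2$mean_tumor[both] / de2$mean_normal[both]))),
            0.99)
  # padj >= p wherever both exist
  ok <- !is.na(de2$p)
  expect_true(all(de2$padj[ok] >= de2$p[ok] - 1e-12))
})

test_that("nb_wald_de agrees with DESeq2 on a shared fixture", {
  cfg <- sim_config(n_mirnas = 400L, n_tumor = 8L, n_normal = 8L,
                    n_batches = 2L, dispersion = 0.05,
                    planted_up_mirnas = stats::setNames(
                      rep(2, 10), mirna_ids(400)[1:10]),
                    rng_seed = 77L)
  sim <- simulate_mirna_experiment(cfg)
  de <- nb_wald_de(sim$counts)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = round(sim$counts$counts),
    colData = data.frame(condition = factor(sim$counts$meta$condition,
                                            levels = c("normal", "tumor")),
                         batch = factor(sim$counts$meta$batch)),
    design = ~ condition + batch)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds, contrast = c("condition", "tumor", "normal"))
  keep <- !is.na(de$p) & !is.na(ref$pvalue) & de$baseMean > 10
  expect_lt(median(abs(de$log2fc[keep] - ref$log2FoldChange[keep])), 0.1)
  expect_gt(cor(de$p[keep], ref$pvalue[keep], method = "spearman"), 0.95)
})
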