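library(GenomicRanges)

gr <- function(start0, end0, strand = "*", chrom = "chr1", ids = NULL) {
  if (!length(start0)) {
    g <- GRanges()
    names(g) <- character(0)
    return(g)
  }
  g <- GRanges(rep(chrom, length(start0)),
               IRanges::IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(ids)) names(g) <- ids
  g
}

test_that("promoter assignment follows the nearest-upstream rule", {
  # + strand mature [1000,1022); TREs [100,200) [800,900) [1100,1200)
  m <- gr(1000, 1022, "+", ids = "m1")
  tres <- gr(c(100, 800, 1100), c(200, 900, 1200), ids = c("t1", "t2", "t3"))
  ml <- assign_promoter(m, tres)
  expect_equal(ml$promoter_id, "t2")
  expect_equal(BiocGenerics::start(ml$locus) - 1L, 800L)
  expect_equal(BiocGenerics::end(ml$locus), 1022L)
  # - strand mature [1000,1022); TREs [800,900) [1100,1200)
  m2 <- gr(1000, 1022, "-", ids = "m2")
  tres2 <- gr(c(800, 1100), c(900, 1200), ids = c("t1", "t3"))
  ml2 <- assign_promoter(m2, tres2)
  expect_equal(ml2$promoter_id, "t3")
  expect_equal(BiocGenerics::start(ml2$locus) - 1L, 1000L)
  expect_equal(BiocGenerics::end(ml2$locus), 1200L)
  # no upstream TRE within max_distance
  ml3 <- assign_promoter(m, gr(200000, 200100, ids = "far"),
                         max_distance = 50000)
  expect_null(ml3$locus)
  expect_equal(ml3$reason, "no_upstream_tre")
  # overlap of the mature 5' end qualifies with gap 0
  ml4 <- assign_promoter(m, gr(c(990, 100), c(1010, 900),
                               ids = c("ov", "up")))
  expect_equal(ml4$promoter_id, "ov")
})

test_that("ties break by wider TRE then lexicographic id", {
  m <- gr(5000, 5022, "+", ids = "m")
  # identical gap 99, widths 100 vs 300
  tres <- gr(c(4801, 4601), c(4901, 4901), ids = c("narrow", "wide"))
  expect_equal(assign_promoter(m, tres)$promoter_id, "wide")
  # identical gap and width: lexicographically smaller id on another chrom
  tres2 <- gr(c(4801, 4801), c(4901, 4901), ids = c("b_tre", "a_tre"))
  expect_equal(assign_promoter(m, tres2)$promoter_id, "a_tre")
})

test_that("promoter assignment equals exhaustive search on random instances", {
  set.seed(42)
  for (i in 1:300) {
    strand <- sample(c("+", "-"), 1)
    n_tre <- sample(0:8, 1)
    m_start <- sample(5000:50000, 1)
    mir <- list(start0 = m_start, end0 = m_start + 22L, strand = strand)
    tres <- data.frame(id = sprintf("t%02d", seq_len(n_tre)),
                       start0 = sample(0:60000, n_tre),
                       stringsAsFactors = FALSE)
    tres$end0 <- tres$start0 + sample(c(50, 100, 100, 200), n_tre,
                                      replace = TRUE)
    maxd <- sample(c(500, 5000, 1e5), 1)
    want <- oracle_promoter(mir, tres, maxd)
    got <- assign_promoter(
      gr(mir$start0, mir$end0, strand, ids = "m"),
      if (n_tre) gr(tres$start0, tres$end0, ids = tres$id) else
        gr(integer(0), integer(0), ids = character(0)),
      max_distance = maxd)
    if (is.null(want)) {
      expect_null(got$locus)
      expect_equal(got$reason, "no_upstream_tre")
    } else {
      expect_equal(got$promoter_id, want$id)
    }
  }
})

test_that("locus construction is idempotent and order-invariant", {
  m <- gr(9000, 9022, "-", ids = "m")
  tres <- gr(c(9100, 9500, 2000), c(9200, 9700, 2100),
             ids = c("x", "y", "z"))
  a <- assign_promoter(m, tres)
  b <- assign_promoter(m, rev(tres))
  c2 <- assign_promoter(m, tres)
  expect_equal(a$promoter_id, b$promoter_id)
  expect_identical(BiocGenerics::start(a$locus), BiocGenerics::start(b$locus))
  expect_identical(a$promoter_id, c2$promoter_id)
})

test_that("signal summation matches a per-base oracle and is additive", {
  # uniform 1.0 over locus [800,1022) -> 222
  locus <- gr(800, 1022, "+", ids = "m")
  track <- GRanges("chr1", IRanges::IRanges(1, 5000), strand = "+",
                   score = 1.0)
  expect_equal(sum_locus_signal(locus, track), 222)
  # empty region -> 0
  empty <- GRanges("chr1", IRanges::IRanges(4000, 5000), strand = "+",
                   score = 2.0)
  expect_equal(sum_locus_signal(locus, empty), 0)
  # randomized run-length track vs naive per-base summation
  set.seed(13)
  for (rep in 1:20) {
    brk <- sort(sample(1:3000, 40))
    starts <- c(1L, brk + 1L)
    ends <- c(brk, 3200L)
    sc <- round(rnorm(length(starts), 0, 2), 3)
    st <- sample(c("+", "-"), length(starts), replace = TRUE)
    tr <- GRanges("chr1", IRanges::IRanges(starts, ends), strand = st,
                  score = sc)
    l0 <- sample(1:2000, 1); l1 <- l0 + sample(50:900, 1)
    lg <- GRanges("chr1", IRanges::IRanges(l0, l1), strand = "+")
    per_base <- numeric(3200)
    for (k in seq_along(starts)) {
      if (st[k] == "+") per_base[starts[k]:ends[k]] <-
          per_base[starts[k]:ends[k]] + abs(sc[k])
    }
    expect_equal(sum_locus_signal(lg, tr), sum(per_base[l0:l1]),
                 tolerance = 1e-9)
    # both-strand mode adds the minus entries
    per_base2 <- numeric(3200)
    for (k in seq_along(starts)) {
      per_base2[starts[k]:ends[k]] <- per_base2[starts[k]:ends[k]] + abs(sc[k])
    }
    expect_equal(sum_locus_signal(lg, tr, strand_mode = "both"),
                 sum(per_base2[l0:l1]), tolerance = 1e-9)
    # additivity over a partition of the locus
    mid <- (l0 + l1) %/% 2
    left <- GRanges("chr1", IRanges::IRanges(l0, mid), strand = "+")
    right <- GRanges("chr1", IRanges::IRanges(mid + 1L, l1), strand = "+")
    expect_equal(sum_locus_signal(left, tr) + sum_locus_signal(right, tr),
                 sum_locus_signal(lg, tr), tolerance = 1e-9)
  }
  # chromosome missing from track
  other <- GRanges("chr9", IRanges::IRanges(1, 100), score = 1)
  expect_error(sum_locus_signal(locus, other), "chromosome")
})

test_that("track simulation satisfies its bookkeeping identities", {
  cfg <- sim_config(n_mirnas = 40L, n_tumor = 6L, n_normal = 6L,
                    planted_up_mirnas = c(mir_0002 = 2), rng_seed = 19L)
  tk <- simulate_tracks(cfg)
  # same seed twice: identical layout and signal
  tk2 <- simulate_tracks(cfg)
  expect_identical(tk$truth$realized, tk2$truth$realized)
  expect_identical(BiocGenerics::start(tk$tres), BiocGenerics::start(tk2$tres))
  # planted 4x activated locus: exact pre-noise ratio
  expect_equal(unname(tk$truth$expected[2, "tumor"] /
                        tk$truth$expected[2, "normal"]), 4)
  # minus-strand miRNAs have their promoter at greater coordinates
  loci <- assign_promoters(tk$mirnas, tk$tres)
  expect_true(all(loci$reason == ""))
  expect_identical(loci$promoter_id, tk$truth$loci$promoter_id)
  minus <- loci$strand == "-"
  tre_starts <- BiocGenerics::start(tk$tres)[match(loci$promoter_id,
                                                   names(tk$tres))]
  m_ends <- BiocGenerics::end(tk$mirnas)
  expect_true(all(tre_starts[minus] > m_ends[minus]))
  # realized totals equal the emitted bedGraph sums over each locus
  s <- tk$meta$sample[1]
  tot <- vapply(seq_len(40), function(i) {
    l <- GRanges(loci$chrom[i], IRanges::IRanges(loci$locus_start[i] + 1L,
                                                 loci$locus_end[i]),
                 strand = loci$strand[i])
    sum_locus_signal(l, tk$tracks[[s]])
  }, 0)
  expect_equal(tot, unname(tk$truth$realized[, s]), tolerance = 1e-9)
})

test_that("locus differential transcription recovers planted activation", {
  cfg <- sim_config(n_mirnas = 40L, n_tumor = 6L, n_normal = 6L,
                    planted_up_mirnas = c(mir_0002 = 2), rng_seed = 19L)
  tk <- simulate_tracks(cfg)
  loci <- assign_promoters(tk$mirnas, tk$tres)
  totals <- sapply(tk$meta$sample, function(s) {
    vapply(seq_len(40), function(i) {
      l <- GRanges(loci$chrom[i], IRanges::IRanges(loci$locus_start[i] + 1L,
                                                   loci$locus_end[i]),
                   strand = loci$strand[i])
      sum_locus_signal(l, tk$tracks[[s]])
    }, 0)
  })
  rownames(totals) <- loci$mirna
  gw <- vapply(tk$tracks, function(g) {
    sum(abs(g$score) * BiocGenerics::width(g))
  }, 0)
  lde <- locus_differential_transcription(totals, tk$meta, genome_totals = gw)
  expect_lt(abs(lde$log2fc[lde$feature == "mir_0002"] - 2), 0.4)
  null_lfc <- lde$log2fc[lde$feature != "mir_0002"]
  expect_gt(mean(abs(null_lfc) < 0.5), 0.9)
  expect_lt(median(abs(null_lfc)), 0.2)
  # identical totals in all samples -> log2fc 0
  flat <- matrix(500, 3, nrow(tk$meta),
                 dimnames = list(c("a", "b", "c"), tk$meta$sample))
  flat[2, ] <- 900; flat[3, ] <- 1400
  lflat <- locus_differential_transcription(flat, tk$meta)
  expect_true(all(abs(lflat$log2fc) < 1e-6))
})

test_that("concordance report joins tables and flags PTR candidates", {
  de <- data.frame(feature = c("m1", "m2", "m3"),
                   log2fc = c(4, -2, 1), padj = c(0.001, 0.001, 0.5),
                   stringsAsFactors = FALSE)
  expect_equal(concordance_report(de, de)$sign_agreement, 1.0)
  txn <- transform(de, log2fc = c(0.2, -1.8, 1.1))
  rep <- concordance_report(de, txn, gap = 2)
  expect_true(rep$table$ptr_candidate[rep$table$mirna == "m1"])
  expect_false(rep$table$ptr_candidate[rep$table$mirna == "m2"])
  other <- transform(de, feature = c("x1", "x2", "x3"))
  expect_error(concordance_report(de, other), "shared")
})
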