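test_that("seed families expose the three canonical site strings", {
  fam <- seed_family("mirX", "UACCCUGUAGAACCGAAUUUGUGU")
  expect_equal(unname(fam$sites["8mer"]), "ACAGGGTA")
  expect_equal(unname(fam$sites["7mer-m8"]), "ACAGGGT")
  expect_equal(unname(fam$sites["7mer-A1"]), "CAGGGTA")
  expect_equal(fam$seed7, "ACCCUGU")
  expect_error(seed_family("short", "UACCCUG"), "8 nt")
})

test_that("find_seed_sites resolves types and overlaps as specified", {
  fam <- seed_family("mirX", "UACCCUGUAGAACCGAAUUUGUGU")
  hit <- find_seed_sites("GGACAGGGUAGG", fam)
  expect_equal(hit$position, 3L)
  expect_equal(hit$type, "8mer")
  # greedy left-to-right, non-overlapping: two sites
  hit2 <- find_seed_sites("ACAGGGUACAGGGUA", fam)
  expect_equal(nrow(hit2), 2L)
  expect_equal(hit2$position, c(1L, 9L))
  # no complementarity
  expect_equal(nrow(find_seed_sites("GGGGGG", fam)), 0L)
  # N never matches
  expect_equal(nrow(find_seed_sites("GGACAGGGNAGG", fam)), 0L)
  # T and U are interchangeable on both sides
  expect_equal(find_seed_sites("GGACAGGGTAGG", fam)$type, "8mer")
  famT <- seed_family("mirX", "TACCCTGTAGAACCGAATTTGTGT")
  expect_equal(find_seed_sites("GGACAGGGUAGG", famT)$type, "8mer")
})

test_that("find_seed_sites equals the sliding-window oracle (small batch)", {
  set.seed(37)
  for (i in 1:100) {
    mature <- random_dna(22, c("A", "C", "G", "U"))
    fam <- seed_family("m", mature)
    # random background plus planted occurrences and N contamination
    utr <- random_dna(300)
    ins <- sample(c(fam$sites, "N"), 4, replace = TRUE)
    for (s in ins) {
      pos <- sample(seq_len(300 - nchar(s)), 1)
      substr(utr, pos, pos + nchar(s) - 1L) <- s
    }
    expect_identical(find_seed_sites(utr, fam), oracle_seed_scan(utr, mature))
  }
})

test_that("the bulk site map agrees with the single-UTR scanner", {
  cfg <- sim_config(n_mirnas = 15L, n_genes = 250L,
                    utr_length_range = c(100L, 600L),
                    baseline_site_rate = 2, rng_seed = 41L)
  s <- simulate_utrs_and_mirnas(cfg)
  map <- build_site_map(s$utrs, s$mirnas)
  expect_setequal(map$universe, names(s$utrs))
  set.seed(1)
  for (i in 1:150) {
    g <- sample(names(s$utrs), 1)
    m <- sample(names(s$mirnas), 1)
    expect_equal(unname(map$counts[m, g]),
                 nrow(find_seed_sites(s$utrs[[g]],
                                      seed_family(m, s$mirnas[[m]]))))
  }
})

test_that("gene-list scores sum counts and report missing annotations", {
  counts <- matrix(c(2, 0, 3), 1, 3,
                   dimnames = list("mirA", c("g1", "g2", "g3")))
  map <- structure(list(counts = counts, universe = c("g1", "g2", "g3"),
                        utr_len = c(g1 = 100L, g2 = 100L, g3 = 100L)),
                   class = "TargetSiteMap")
  s <- score_gene_list(c("g1", "g2", "g3"), map, "mirA")
  expect_equal(as.numeric(s), 5)
  expect_equal(attr(s, "n_missing"), 0L)
  expect_equal(as.numeric(score_gene_list(character(0), map, "mirA")), 0)
  s2 <- score_gene_list(c("g1", "g3", "unknown"), map, "mirA")
  expect_equal(as.numeric(s2), 5)
  expect_equal(attr(s2, "n_missing"), 1L)
  expect_error(score_gene_list(c("g1", "g1"), map, "mirA"), "unique")
  # partition additivity
  expect_equal(as.numeric(score_gene_list(c("g1", "g2"), map, "mirA")) +
                 as.numeric(score_gene_list("g3", map, "mirA")),
               as.numeric(s))
})

make_test_map <- function(n_genes = 400, n_fam = 8, seed = 3) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  fams <- sprintf("fam%02d", seq_len(n_fam))
  counts <- matrix(rpois(n_fam * n_genes, 0.6), n_fam, n_genes,
                   dimnames = list(fams, genes))
  structure(list(counts = counts, universe = genes,
                 utr_len = stats::setNames(
                   sample(200:2000, n_genes, TRUE), genes)),
            class = "TargetSiteMap")
}

test_that("empirical enrichment is deterministic and follows the add-one rule", {
  map <- make_test_map()
  genes <- map$universe[1:50]
  r1 <- empirical_enrichment(genes, map, n_sim = 300L, rng_seed = 11L)
  r2 <- empirical_enrichment(genes, map, n_sim = 300L, rng_seed = 11L)
  expect_identical(r1, r2)
  r3 <- empirical_enrichment(genes, map, n_sim = 300L, rng_seed = 12L)
  expect_false(identical(r1$n_exceed, r3$n_exceed))
  expect_equal(r1$p, (r1$n_exceed + 1) / 301)
  expect_true(all(r1$p >= 1 / 301 & r1$p <= 1))
  # dominant observed score: exact minimum p
  map2 <- make_test_map()
  map2$counts["fam01", genes] <- map2$counts["fam01", genes] + 100
  r4 <- empirical_enrichment(genes, map2, n_sim = 300L, rng_seed = 11L)
  expect_equal(r4$p[r4$mirna == "fam01"], 1 / 301)
  # p is non-increasing in the observed score under fixed null draws:
  # raising one family's counts on the list genes can only lower its p
  expect_lte(r4$p[r4$mirna == "fam01"], r1$p[r1$mirna == "fam01"])
})

test_that("empirical enrichment validates its preconditions", {
  map <- make_test_map()
  expect_error(empirical_enrichment(character(0), map), "empty")
  expect_error(empirical_enrichment(c("g0001", "g0001"), map), "unique")
  expect_error(empirical_enrichment("nope", map), "universe")
  expect_error(empirical_enrichment(map$universe, map), "smaller")
})

test_that("master regulator report excludes unmapped families and is paired", {
  map <- make_test_map()
  genes <- map$universe[1:40]
  rep <- master_regulator_report(
    gpr_genes = genes, lpr_genes = genes,
    up_families = c("fam01", "fam02", "ghost"),
    down_families = c("fam03", "phantom"),
    map = map, n_sim = 200L, rng_seed = 5L)
  expect_equal(rep$excluded_up, "ghost")
  expect_equal(rep$excluded_down, "phantom")
  expect_equal(rep$reference_line, -log10(0.05))
  expect_equal(rep$gpr$rank, seq_len(nrow(rep$gpr)))
  # identical gene list in both arms: identical null draws under one seed,
  # so a family tested in both arms gets identical statistics
  rep2 <- master_regulator_report(genes, genes, c("fam01", "fam02"),
                                  c("fam01", "fam02"), map,
                                  n_sim = 200L, rng_seed = 5L)
  expect_identical(rep2$gpr, rep2$lpr)
})

test_that("length-binned null sampling preserves the list length", {
  map <- make_test_map()
  genes <- map$universe[order(map$utr_len)][1:30]   # short-UTR heavy list
  r <- empirical_enrichment(genes, map, n_sim = 50L, rng_seed = 2L,
                            length_binned = TRUE)
  expect_true(all(r$n_sim == 50L))
  expect_true(all(r$p > 0 & r$p <= 1))
})

test_that("precomputed site-count tables load as a site map", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(mirna = c("mA", "mA", "mB"),
                         gene = c("g1", "g2", "g1"),
                         count = c(2L, 1L, 4L)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- read_site_map(path)
  expect_equal(unname(map$counts["mA", "g2"]), 1)
  expect_equal(unname(map$counts["mB", "g2"]), 0)
  expect_equal(as.numeric(score_gene_list(c("g1", "g2"), map, "mA")), 3)
})
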