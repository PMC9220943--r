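# Independent oracle implementations. These deliberately share no code with
# the package: plain loops, direct substring comparison, literal transcription
# of the published rules.

# -- exhaustive sliding-window seed-site scan ---------------------------------
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_seed_scan <- function(utr, mature) {
  utr <- toupper(chartr("u", "t", chartr("U", "T", utr)))
  mature <- toupper(chartr("u", "t", chartr("U", "T", mature)))
  s8 <- paste0(oracle_revcomp(substr(mature, 2, 8)), "A")
  s7m8 <- oracle_revcomp(substr(mature, 2, 8))
  s7a1 <- paste0(oracle_revcomp(substr(mature, 2, 7)), "A")
  n <- nchar(utr)
  best <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i + 7 <= n && substr(utr, i, i + 7) == s8) best[i] <- "8mer"
    else if (i + 6 <= n && substr(utr, i, i + 6) == s7m8) best[i] <- "7mer-m8"
    else if (i + 6 <= n && substr(utr, i, i + 6) == s7a1) best[i] <- "7mer-A1"
  }
  pos <- integer(0); typ <- character(0)
  last_end <- 0L
  for (i in seq_len(n)) {
    if (is.na(best[i]) || i <= last_end) next
    pos <- c(pos, i); typ <- c(typ, best[i])
    last_end <- i + ifelse(best[i] == "8mer", 8L, 7L) - 1L
  }
  data.frame(position = pos, type = typ, stringsAsFactors = FALSE)
}

# -- literal brute-force PTR predicate ----------------------------------------
oracle_ptr_class <- function(rec, chro_bound = 0.59, chro_floor = 0.2,
                             rna_lfc = 1, rna_fdr = 0.05, min_mean = 1000) {
  ok <- function(x) !is.na(x)
  gpr <- ok(rec$chro_log2fc) && abs(rec$chro_log2fc) < chro_bound &&
    ok(rec$chro_fdr) && rec$chro_fdr > chro_floor &&
    ok(rec$mean_normal) && rec$mean_normal > min_mean &&
    ok(rec$rna_log2fc) && rec$rna_log2fc < -rna_lfc &&
    ok(rec$rna_fdr) && rec$rna_fdr < rna_fdr
  lpr <- ok(rec$chro_log2fc) && abs(rec$chro_log2fc) < chro_bound &&
    ok(rec$chro_fdr) && rec$chro_fdr > chro_floor &&
    ok(rec$mean_tumor) && rec$mean_tumor > min_mean &&
    ok(rec$rna_log2fc) && rec$rna_log2fc > rna_lfc &&
    ok(rec$rna_fdr) && rec$rna_fdr < rna_fdr
  if (gpr) "GPR" else if (lpr) "LPR" else "unclassified"
}

# -- exhaustive promoter search on 0-based half-open tuples -------------------
# mir: list(start0, end0, strand); tres: data.frame(id, start0, end0)
oracle_promoter <- function(mir, tres, max_distance) {
  best_id <- NA_character_; best_gap <- Inf; best_w <- -Inf
  for (i in seq_len(nrow(tres))) {
    s <- tres$start0[i]; e <- tres$end0[i]; w <- e - s
    if (mir$strand == "+") {
      five <- mir$start0
      if (s > five) next                      # begins downstream of 5' end
      gap <- max(0L, five - e)
    } else {
      five <- mir$end0 - 1L                   # 0-based coordinate of 5' base
      if (e - 1L < five) next                 # ends downstream of 5' end
      gap <- max(0L, s - five - 1L)
    }
    if (gap > max_distance) next
    better <- gap < best_gap ||
      (gap == best_gap && w > best_w) ||
      (gap == best_gap && w == best_w && (is.na(best_id) || tres$id[i] < best_id))
    if (better) { best_id <- tres$id[i]; best_gap <- gap; best_w <- w }
  }
  if (is.na(best_id)) return(NULL)
  list(id = best_id, gap = best_gap)
}

# -- brute-force BH adjustment ------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# -- brute-force miRNA selection filter ---------------------------------------
oracle_select <- function(de, alpha = 0.05, min_mean = 1000, max_cov = 2) {
  keep <- logical(nrow(de))
  for (i in seq_len(nrow(de))) {
    r <- de[i, ]
    keep[i] <- !is.na(r$padj) && r$padj < alpha &&
      (r$mean_tumor > min_mean || r$mean_normal > min_mean) &&
      !is.na(r$cov_tumor) && r$cov_tumor < max_cov && !is.na(r$log2fc)
  }
  sel <- de[keep, ]
  sel <- sel[order(sel$padj, sel$feature), ]
  rownames(sel) <- NULL
  list(up = sel[sel$log2fc > 0, ], down = sel[sel$log2fc < 0, ])
}

# -- shared fixtures ----------------------------------------------------------
random_de_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    feature = sprintf("f%05d", sample.int(9e4, n)),
    baseMean = exp(runif(n, 0, 10)),
    mean_tumor = ifelse(runif(n) < 0.1, 0, exp(runif(n, 0, 12))),
    mean_normal = ifelse(runif(n) < 0.1, 0, exp(runif(n, 0, 12))),
    log2fc = ifelse(runif(n) < 0.05, NA, rnorm(n, 0, 2)),
    se = runif(n, 0.05, 1),
    p = runif(n)^2,
    padj = ifelse(runif(n) < 0.1, NA, runif(n)^1.5),
    cov_tumor = ifelse(runif(n) < 0.1, NA, runif(n, 0, 4)),
    stringsAsFactors = FALSE)
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
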