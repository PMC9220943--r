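## Non-overlapping placement of k length-w sites in a length-L sequence,
## uniform over valid configurations: draw k distinct integers from
## 1..(L - k*(w-1) - (w-1)) and shift the i-th order statistic by (i-1)*(w-1).
place_sites <- function(L, k, w) {
  if (k == 0L) return(integer(0))
  m <- L - w + 1L - (k - 1L) * (w - 1L)
  stopifnot(m >= k)
  t <- sort(sample.int(m, k))
  t + (w - 1L) * (seq_len(k) - 1L)
}

random_mature_set <- function(n, length = 22L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "U"), k * length, replace = TRUE),
                k, length)
    apply(m, 1L, paste, collapse = "")
  }
  seqs <- draw(n)
  ## distinct seed regions so family truths never collide
  for (i in 1:50) {
    dup <- duplicated(substr(seqs, 2L, 8L))
    if (!any(dup)) break
    seqs[dup] <- draw(sum(dup))
  }
  seqs
}

#' Simulate 3'UTRs and mature miRNAs with planted seed-site enrichment
#'
#' Generates uniform-composition UTRs (lengths uniform over
#' `utr_length_range`) and random 22-nt mature miRNA sequences with distinct
#' seeds, then injects 8mer seed-complementary sites: for every miRNA the
#' per-UTR injection count is Poisson with rate
#' `baseline_site_rate * length/1000`, multiplied by `site_enrichment_odds`
#' for the master miRNA within GPR-gene UTRs. Sites are written in place
#' (UTR length preserved) at positions drawn uniformly over non-overlapping
#' configurations, so no injected site destroys another and every injected
#' site is rediscoverable by a string scan; when a UTR cannot host all
#' requested sites the surplus (chosen at random) is dropped and counted.
#'
#' @param cfg a [sim_config()]; `utr_length_range` must admit at least one
#'   8-nt site.
#' @return list with `utrs` (named character, DNA alphabet), `mirnas` (named
#'   character, RNA alphabet), and `truth`: a list with `mirna_flags`
#'   (mirna, enriched), `injections` (gene, mirna, position, type) and
#'   `n_dropped`.
#' @export
simulate_utrs_and_mirnas <- function(cfg) {
  validate_sim_config(cfg)
  w <- 8L
  if (cfg$utr_length_range[1] < w) {
    abort_usage("SimConfig field 'utr_length_range' is too short to host a seed site (min 8 nt)")
  }
  ids_g <- gene_ids(cfg$n_genes)
  ids_m <- mirna_ids(cfg$n_mirnas)
  check_planted_ids(cfg$planted_gpr, ids_g, "planted_gpr")
  if (!is.null(cfg$master_mirna) && !cfg$master_mirna %in% ids_m) {
    abort_usage("SimConfig field 'master_mirna' is not a simulated miRNA id")
  }
  with_seed(child_seed(cfg$rng_seed, "utr_seq"), {
    len <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                  cfg$n_genes, replace = TRUE)
    bases <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
    offset <- cumsum(c(1L, len))[seq_len(cfg$n_genes)]

    mirnas <- stats::setNames(random_mature_set(cfg$n_mirnas), ids_m)
    fams <- Map(seed_family, ids_m, mirnas)
    site8 <- vapply(fams, function(f) f$sites[["8mer"]], "")
    site8_chars <- strsplit(site8, "", fixed = TRUE)

    lam <- outer(len / 1000 * cfg$baseline_site_rate,
                 rep(1, cfg$n_mirnas))
    if (!is.null(cfg$master_mirna) && length(cfg$planted_gpr)) {
      lam[match(names(cfg$planted_gpr), ids_g),
          match(cfg$master_mirna, ids_m)] <-
        lam[match(names(cfg$planted_gpr), ids_g),
            match(cfg$master_mirna, ids_m)] * cfg$site_enrichment_odds
    }
    n_inj <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))

    inj_gene <- integer(0); inj_mirna <- integer(0); inj_pos <- integer(0)
    n_dropped <- 0L
    for (g in seq_len(cfg$n_genes)) {
      kv <- n_inj[g, ]
      k <- sum(kv)
      if (k == 0L) next
      mir_idx <- rep(seq_len(cfg$n_mirnas), kv)
      k_max <- (len[g] - w + 1L + (w - 1L)) %/% w   # floor(L / w)
      if (k > k_max) {
        n_dropped <- n_dropped + (k - k_max)
        mir_idx <- sample(mir_idx, k_max)
        k <- k_max
      }
      if (k == 0L) next
      pos <- place_sites(len[g], k, w)
      mir_idx <- sample(mir_idx, k)   # random site-to-miRNA assignment
      inj_gene <- c(inj_gene, rep.int(g, k))
      inj_mirna <- c(inj_mirna, mir_idx)
      inj_pos <- c(inj_pos, pos)
    }
    if (length(inj_pos)) {
      abs_idx <- rep(offset[inj_gene] + inj_pos - 1L, each = w) +
        rep.int(0:(w - 1L), length(inj_pos))
      bases[abs_idx] <- unlist(site8_chars[inj_mirna], use.names = FALSE)
    }
    corpus <- paste(bases, collapse = "")
    utrs <- stats::setNames(substring(corpus, offset, offset + len - 1L),
                            ids_g)
    truth <- list(
      mirna_flags = data.frame(
        mirna = ids_m,
        enriched = if (is.null(cfg$master_mirna)) {
          rep(FALSE, cfg$n_mirnas)
        } else {
          ids_m == cfg$master_mirna & cfg$site_enrichment_odds > 1 &
            length(cfg$planted_gpr) > 0
        },
        stringsAsFactors = FALSE),
      injections = data.frame(gene = ids_g[inj_gene], mirna = ids_m[inj_mirna],
                              position = inj_pos, type = "8mer",
                              stringsAsFactors = FALSE),
      n_dropped = n_dropped)
    list(utrs = utrs, mirnas = mirnas, truth = truth)
  })
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param alphabet "dna" or "rna".
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  set <- if (alphabet == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::RNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path (DNA or RNA alphabet; T/U handled downstream).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("FASTA not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
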