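## Canonical seed-match site types. For a mature miRNA sequence m (5'->3',
## RNA alphabet), seed7 = m[2..8]:
##   8mer    = reverse complement of seed7, followed by A   (8 nt)
##   7mer-m8 = reverse complement of seed7                  (7 nt)
##   7mer-A1 = reverse complement of m[2..7], followed by A (7 nt)
## Matching is on the DNA alphabet (T == U); N never matches. Each UTR
## position carries at most one site of the best (longest) type, and
## overlapping occurrences are resolved greedily left to right.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

rna_to_dna <- function(x) chartr("uU", "tT", x)

revcomp_dna <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(toupper(x), "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), ""))
}

#' Seed family of a mature miRNA
#'
#' @param mirna_id identifier.
#' @param mature mature sequence, 5' to 3', RNA or DNA alphabet, length >= 8.
#' @return a list of class `SeedFamily` with the mature sequence, `seed7`
#'   (nucleotides 2-8) and the three DNA-alphabet site strings scanned for
#'   in 3'UTRs.
#' @export
seed_family <- function(mirna_id, mature) {
  mature <- toupper(rna_to_dna(as.character(mature)))
  if (nchar(mature) < 8L) {
    abort_usage(sprintf("%s: mature sequence must be >= 8 nt", mirna_id))
  }
  if (grepl("[^ACGTN]", mature)) {
    abort_usage(sprintf("%s: mature sequence has invalid characters", mirna_id))
  }
  seed7 <- substr(mature, 2L, 8L)
  sites <- c("8mer" = paste0(revcomp_dna(seed7), "A"),
             "7mer-m8" = revcomp_dna(seed7),
             "7mer-A1" = paste0(revcomp_dna(substr(mature, 2L, 7L)), "A"))
  structure(list(mirna_id = mirna_id, mature = mature,
                 seed7 = chartr("T", "U", seed7), sites = sites),
            class = "SeedFamily")
}

## Greedy resolution shared by the single-UTR scanner and the bulk site map:
## candidates sorted by start, best (longest) type first at equal starts,
## then accepted left to right without overlap.
resolve_sites <- function(start, width, prio) {
  o <- order(start, prio)
  start <- start[o]; width <- width[o]; prio <- prio[o]
  dup <- duplicated(start)
  start <- start[!dup]; width <- width[!dup]; prio <- prio[!dup]
  keep <- logical(length(start))
  last_end <- 0L
  for (i in seq_along(start)) {
    if (start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- start[i] + width[i] - 1L
    }
  }
  list(start = start[keep], width = width[keep], prio = prio[keep])
}

#' Find canonical miRNA seed-match sites in one 3'UTR
#'
#' @param utr UTR sequence (character or `DNAString`), RNA or DNA alphabet;
#'   N never matches.
#' @param family a [seed_family()].
#' @return data.frame with `position` (1-based start) and `type`
#'   (8mer / 7mer-m8 / 7mer-A1), ordered by position.
#' @export
find_seed_sites <- function(utr, family) {
  stopifnot(inherits(family, "SeedFamily"))
  utr <- toupper(rna_to_dna(as.character(utr)))
  starts <- integer(0); widths <- integer(0); prios <- integer(0)
  for (k in seq_along(SITE_TYPES)) {
    pat <- family$sites[[SITE_TYPES[k]]]
    hit <- gregexpr(pat, utr, fixed = TRUE)[[1L]]
    if (hit[1L] != -1L) {
      starts <- c(starts, as.integer(hit))
      widths <- c(widths, rep(nchar(pat), length(hit)))
      prios <- c(prios, rep(k, length(hit)))
    }
  }
  if (!length(starts)) {
    return(data.frame(position = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- resolve_sites(starts, widths, prios)
  data.frame(position = r$start, type = SITE_TYPES[r$prio],
             stringsAsFactors = FALSE)
}

#' Build a miRNA-by-gene target-site count map from sequences
#'
#' Scans every 3'UTR for every family's canonical sites (same rules as
#' [find_seed_sites()], implemented with an Aho-Corasick dictionary scan
#' over the concatenated UTRs for speed) and tabulates site counts.
#'
#' @param utrs named character vector or `DNAStringSet` of 3'UTR sequences;
#'   names are gene ids.
#' @param families list of [seed_family()] objects, or a named character
#'   vector of mature sequences.
#' @return a `TargetSiteMap`: list with `counts` (families x genes numeric
#'   matrix), `universe` (gene ids with an annotated UTR) and `utr_len`.
#' @export
build_site_map <- function(utrs, families) {
  if (inherits(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  if (is.null(names(utrs)) || anyDuplicated(names(utrs))) {
    abort_usage("utrs must be uniquely named by gene id")
  }
  if (!is.list(families)) {
    families <- Map(seed_family, names(families), families)
  }
  fam_ids <- vapply(families, function(f) f$mirna_id, "")
  if (anyDuplicated(fam_ids)) abort_usage("duplicate miRNA ids in families")
  utrs <- toupper(rna_to_dna(utrs))
  genes <- names(utrs)
  utr_len <- stats::setNames(nchar(utrs), genes)

  ## pattern table: one row per (family, site type)
  pat <- data.table::data.table(
    family = rep(fam_ids, each = 3L),
    prio = rep(seq_len(3L), length(families)),
    seq = unlist(lapply(families, function(f) unname(f$sites))))
  pat[, width := nchar(seq)]

  ## concatenate UTRs with N runs so no window spans two genes
  sep <- strrep("N", 10L)
  subject <- Biostrings::DNAString(paste(utrs, collapse = sep))
  offsets <- cumsum(c(1L, nchar(utrs) + 10L))[seq_along(utrs)]

  hit_list <- list()
  for (w in unique(pat$width)) {
    rows <- which(pat$width == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pat$seq[rows]))
    m <- Biostrings::matchPDict(pd, subject)
    st <- BiocGenerics::start(m)
    n_per <- S4Vectors::elementNROWS(m)
    if (sum(n_per) == 0) next
    hit_list[[as.character(w)]] <- data.table::data.table(
      pat_row = rep(rows, n_per),
      abs_start = unlist(st, use.names = FALSE))
  }
  counts <- matrix(0, length(fam_ids), length(genes),
                   dimnames = list(fam_ids, genes))
  if (length(hit_list)) {
    hits <- data.table::rbindlist(hit_list)
    hits[, gene_idx := findInterval(abs_start, offsets)]
    hits[, `:=`(family = pat$family[pat_row],
                prio = pat$prio[pat_row],
                width = pat$width[pat_row],
                start = abs_start - offsets[gene_idx] + 1L)]
    resolved <- hits[, {
      r <- resolve_sites(start, width, prio)
      list(n = length(r$start))
    }, by = .(family, gene_idx)]
    counts[cbind(match(resolved$family, fam_ids), resolved$gene_idx)] <-
      resolved$n
  }
  structure(list(counts = counts, universe = genes, utr_len = utr_len),
            class = "TargetSiteMap")
}

#' Load a precomputed target-site count table
#'
#' Accepts a user-supplied `(mirna, gene, count)` TSV — e.g. counts derived
#' from TargetScan predictions — as a drop-in replacement for the de novo
#' seed scan.
#'
#' @param path TSV with columns `mirna`, `gene`, `count`.
#' @param universe optional gene universe; defaults to the genes present in
#'   the table.
#' @return a `TargetSiteMap`.
#' @export
read_site_map <- function(path, universe = NULL) {
  df <- read_tsv(path)
  stopifnot_fields(df, c("mirna", "gene", "count"), basename(path))
  if (is.null(universe)) universe <- sort(unique(df$gene))
  bad <- setdiff(df$gene, universe)
  if (length(bad)) {
    abort_input(sprintf("site map genes outside the universe: %s",
                        paste(utils::head(bad, 5L), collapse = ", ")))
  }
  fams <- sort(unique(df$mirna))
  counts <- matrix(0, length(fams), length(universe),
                   dimnames = list(fams, universe))
  counts[cbind(match(df$mirna, fams), match(df$gene, universe))] <- df$count
  structure(list(counts = counts, universe = universe,
                 utr_len = stats::setNames(rep(NA_integer_, length(universe)),
                                           universe)),
            class = "TargetSiteMap")
}

#' Cumulative site score of a gene list for one miRNA
#'
#' Sum of 3'UTR site counts over the listed genes; genes without a UTR
#' annotation contribute 0 and are reported in the `n_missing` attribute.
#'
#' @param genes unique gene ids.
#' @param map a `TargetSiteMap`.
#' @param mirna family id (row of the map).
#' @return nonnegative integer score with attribute `n_missing`.
#' @export
score_gene_list <- function(genes, map, mirna) {
  stopifnot(inherits(map, "TargetSiteMap"))
  if (anyDuplicated(genes)) abort_usage("gene list must be unique")
  if (!mirna %in% rownames(map$counts)) {
    abort_usage(sprintf("miRNA '%s' not in site map", mirna))
  }
  present <- genes %in% colnames(map$counts)
  score <- sum(map$counts[mirna, genes[present]])
  attr(score, "n_missing") <- sum(!present)
  score
}
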