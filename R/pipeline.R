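## Pipeline orchestration. Every stage reads its inputs from files under the
## output directory (or user-supplied paths) and writes its outputs before
## the next stage starts, so re-running one stage from cached upstream
## outputs reproduces the full run. All randomness is derived from the
## single config seed via child streams; manifests record seeds and
## checksums. Wall-clock timings go to a sidecar (timings.tsv) so the
## result bundle proper is byte-identical across reruns.

## call-time aliases: the pipeline_config arguments shadow the constructors
mirptr_de_params <- function(...) de_params(...)
mirptr_ptr_params <- function(...) ptr_params(...)

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory for the result bundle.
#' @param seed global integer seed.
#' @param stages character vector of stages to run, among
#'   `simulate`, `de`, `locus`, `ptr`, `enrich`.
#' @param sim named list of [sim_config()] overrides (used by `simulate`).
#' @param de_params,ptr_params parameter objects (or named lists).
#' @param n_sim,universe,length_binned enrichment settings (`universe` is
#'   "utr" for all UTR-annotated genes or "expressed" for genes tested in
#'   the RNA-seq table).
#' @param grouping one of "tumor_vs_normal", "primary_vs_normal",
#'   "metastatic_vs_normal" (the latter two need a `tumor_type` metadata
#'   column).
#' @param max_distance,strand_mode locus-stage settings.
#' @param inputs named list of external input paths used when `simulate` is
#'   not among the stages: `mirna_counts`, `mirna_meta`, `chro_counts`,
#'   `chro_meta`, `rna_counts`, `rna_meta`, `utr_fasta`, `mirna_fasta`,
#'   `tre_bed`, `mirna_annotation`, `tracks_manifest`.
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "de", "locus", "ptr",
                                       "enrich"),
                            sim = list(), de_params = NULL,
                            ptr_params = NULL,
                            n_sim = 1000L, universe = c("utr", "expressed"),
                            length_binned = FALSE,
                            grouping = "tumor_vs_normal",
                            max_distance = 1e5,
                            strand_mode = c("mirna", "both"),
                            inputs = list()) {
  universe <- match.arg(universe)
  strand_mode <- match.arg(strand_mode)
  bad <- setdiff(stages, c("simulate", "de", "locus", "ptr", "enrich"))
  if (length(bad)) {
    abort_usage(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  if (!grouping %in% c("tumor_vs_normal", "primary_vs_normal",
                       "metastatic_vs_normal")) {
    abort_usage(sprintf("unknown grouping: %s", grouping))
  }
  if (is.null(de_params)) de_params <- list()
  if (is.null(ptr_params)) ptr_params <- list()
  if (!inherits(de_params, "DeParams")) {
    de_params <- do.call(mirptr_de_params, as.list(de_params))
  }
  if (!inherits(ptr_params, "PtrParams")) {
    ptr_params <- do.call(mirptr_ptr_params, as.list(ptr_params))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim = sim, de_params = de_params, ptr_params = ptr_params,
                 n_sim = as.integer(n_sim), universe = universe,
                 length_binned = isTRUE(length_binned), grouping = grouping,
                 max_distance = max_distance, strand_mode = strand_mode,
                 inputs = inputs),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; keys mirror the arguments of [pipeline_config()].
#'   Planted sets in `sim` are JSON objects mapping feature id to log2fc,
#'   or the compact block form `{"n": 120, "start": 1, "log2fc": -2}`
#'   denoting `n` consecutive simulated features from index `start`.
#' @param out_dir optional override of the configured output directory.
#' @param seed optional override of the configured seed.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(js$sim)) {
    for (f in c("planted_up_mirnas", "planted_down_mirnas", "planted_gpr",
                "planted_lpr", "planted_transcriptional")) {
      v <- js$sim[[f]]
      if (is.null(v)) next
      if (all(c("n", "start", "log2fc") %in% names(v))) {
        ids_fn <- if (grepl("mirnas$", f)) mirna_ids else gene_ids
        ids <- ids_fn(v$start + v$n - 1L)[seq(v$start, v$start + v$n - 1L)]
        js$sim[[f]] <- stats::setNames(rep(v$log2fc, v$n), ids)
      } else {
        js$sim[[f]] <- unlist(v)
      }
    }
  }
  args <- js[intersect(names(js), names(formals(pipeline_config)))]
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  if (is.null(args$out_dir)) abort_usage("config needs an out_dir (or --out)")
  do.call(pipeline_config, args)
}

in_path <- function(config, key, default_rel) {
  p <- config$inputs[[key]]
  if (is.null(p)) p <- file.path(config$out_dir, default_rel)
  p
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      list(message = sprintf("stage '%s' failed: %s", stage,
                             conditionMessage(e)),
           call = NULL),
      class = unique(c(class(e)[1L], "error", "condition"))))
  })
}

stage_simulate <- function(config) {
  cfg <- do.call(sim_config, c(config$sim, list(rng_seed = config$seed)))
  dir <- file.path(config$out_dir, "inputs")
  mir <- simulate_mirna_experiment(cfg)
  write_count_matrix(mir$counts, file.path(dir, "mirna_counts.tsv"),
                     file.path(dir, "mirna_meta.tsv"))
  ptr <- simulate_ptr_experiment(cfg)
  write_count_matrix(ptr$chro, file.path(dir, "chro_counts.tsv"),
                     file.path(dir, "chro_meta.tsv"))
  write_count_matrix(ptr$rna, file.path(dir, "rna_counts.tsv"),
                     file.path(dir, "rna_meta.tsv"))
  seqs <- simulate_utrs_and_mirnas(cfg)
  write_fasta(seqs$utrs, file.path(dir, "utrs.fa"), "dna")
  write_fasta(seqs$mirnas, file.path(dir, "mirnas.fa"), "rna")
  tk <- simulate_tracks(cfg)
  write_bed6(tk$tres, file.path(dir, "tres.bed"))
  write_gff3_mirnas(tk$mirnas, file.path(dir, "mirnas.gff3"))
  tman <- tk$meta
  tman$plus_path <- file.path("inputs", "tracks",
                              paste0(tman$sample, "_plus.bedGraph"))
  tman$minus_path <- file.path("inputs", "tracks",
                               paste0(tman$sample, "_minus.bedGraph"))
  for (i in seq_len(nrow(tman))) {
    gr <- tk$tracks[[tman$sample[i]]]
    st <- as.character(BiocGenerics::strand(gr))
    write_bedgraph(gr[st == "+"], file.path(config$out_dir, tman$plus_path[i]))
    write_bedgraph(gr[st == "-"], file.path(config$out_dir, tman$minus_path[i]))
  }
  write_tsv(tman, file.path(dir, "tracks_manifest.tsv"))
  write_tsv(seqs$truth$injections, file.path(dir, "truth_injections.tsv"))
  truth <- list(mirna = mir$truth, ptr = ptr$truth,
                mirna_flags = seqs$truth$mirna_flags,
                utr_sites_dropped = seqs$truth$n_dropped,
                loci = tk$truth$loci,
                sim_config = cfg[setdiff(names(cfg), character(0))])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

grouping_subset <- function(cm, grouping) {
  if (grouping == "tumor_vs_normal") return(cm)
  type <- sub("_vs_normal", "", grouping)
  if (is.null(cm$meta$tumor_type)) {
    abort_input(sprintf("grouping '%s' needs a tumor_type metadata column",
                        grouping))
  }
  keep <- cm$meta$condition == "normal" |
    (cm$meta$condition == "tumor" & cm$meta$tumor_type == type)
  subset_samples(cm, cm$meta$sample[keep])
}

stage_de <- function(config) {
  dir <- file.path(config$out_dir, "de")
  cm <- read_count_matrix(in_path(config, "mirna_counts", "inputs/mirna_counts.tsv"),
                          in_path(config, "mirna_meta", "inputs/mirna_meta.tsv"))
  cm_g <- grouping_subset(cm, config$grouping)
  de <- nb_wald_de(cm_g)
  write_tsv(de, file.path(dir, "mirna_de.tsv"))
  sel <- select_de_mirnas(de, config$de_params)
  write_lines(sel$up$feature, file.path(dir, "selected_up.txt"))
  write_lines(sel$down$feature, file.path(dir, "selected_down.txt"))
  vst <- vst_batch_adjust(cm_g)
  write_tsv(data.frame(feature = rownames(vst), vst, check.names = FALSE),
            file.path(dir, "vst_matrix.tsv"))
  if (!is.null(cm$meta$patient)) {
    feats <- c(sel$up$feature, sel$down$feature)
    mp <- matched_pair_report(cm, features = if (length(feats)) feats)
    write_tsv(mp$pairs, file.path(dir, "matched_pairs.tsv"))
    write_tsv(mp$summary, file.path(dir, "matched_pair_summary.tsv"))
  }
  invisible(NULL)
}

read_tracks <- function(config) {
  man_path <- in_path(config, "tracks_manifest", "inputs/tracks_manifest.tsv")
  man <- read_tsv(man_path)
  stopifnot_fields(man, c("sample", "condition", "plus_path", "minus_path"),
                   basename(man_path))
  tracks <- lapply(seq_len(nrow(man)), function(i) {
    plus <- read_bedgraph(file.path(config$out_dir, man$plus_path[i]),
                          strand = "+")
    minus <- read_bedgraph(file.path(config$out_dir, man$minus_path[i]),
                           strand = "-")
    c(plus, minus)
  })
  names(tracks) <- man$sample
  list(meta = man, tracks = tracks)
}

stage_locus <- function(config) {
  dir <- file.path(config$out_dir, "locus")
  tres <- read_bed(in_path(config, "tre_bed", "inputs/tres.bed"))
  mirnas <- read_mirna_annotation(
    in_path(config, "mirna_annotation", "inputs/mirnas.gff3"))
  loci <- assign_promoters(mirnas, tres, max_distance = config$max_distance)
  tk <- read_tracks(config)
  present <- loci$reason == ""
  totals <- matrix(0, sum(present), length(tk$tracks),
                   dimnames = list(loci$mirna[present], names(tk$tracks)))
  for (s in names(tk$tracks)) {
    for (i in which(present)) {
      l <- GenomicRanges::GRanges(loci$chrom[i], IRanges::IRanges(
        loci$locus_start[i] + 1L, loci$locus_end[i]), strand = loci$strand[i])
      totals[loci$mirna[i], s] <-
        sum_locus_signal(l, tk$tracks[[s]], strand_mode = config$strand_mode)
    }
  }
  gw <- vapply(tk$tracks, function(gr) {
    sum(abs(gr$score) * BiocGenerics::width(gr))
  }, 0)
  write_tsv(cbind(loci[present, ], as.data.frame(totals, check.names = FALSE)),
            file.path(dir, "loci.tsv"))
  write_lines(loci$mirna[!present], file.path(dir, "absent_loci.txt"))
  lde <- locus_differential_transcription(totals, tk$meta, genome_totals = gw)
  write_tsv(lde, file.path(dir, "locus_de.tsv"))
  de_path <- file.path(config$out_dir, "de", "mirna_de.tsv")
  if (file.exists(de_path)) {
    conc <- concordance_report(read_tsv(de_path), lde)
    tab <- conc$table
    attr(tab, "sign_agreement") <- NULL
    write_tsv(tab, file.path(dir, "concordance.tsv"))
    write_tsv(data.frame(sign_agreement = conc$sign_agreement),
              file.path(dir, "sign_agreement.tsv"))
  }
  invisible(NULL)
}

stage_ptr <- function(config) {
  dir <- file.path(config$out_dir, "ptr")
  chro <- read_count_matrix(in_path(config, "chro_counts", "inputs/chro_counts.tsv"),
                            in_path(config, "chro_meta", "inputs/chro_meta.tsv"))
  rna <- read_count_matrix(in_path(config, "rna_counts", "inputs/rna_counts.tsv"),
                           in_path(config, "rna_meta", "inputs/rna_meta.tsv"))
  chro_de <- nb_wald_de(chro)
  rna_de <- nb_wald_de(rna)
  write_tsv(chro_de, file.path(dir, "chro_de.tsv"))
  write_tsv(rna_de, file.path(dir, "rna_de.tsv"))
  labels <- classify_ptr(chro_de, rna_de, config$ptr_params)
  write_tsv(labels, file.path(dir, "ptr_labels.tsv"))
  write_lines(labels$gene[labels$class == "GPR"],
              file.path(dir, "gpr_genes.txt"))
  write_lines(labels$gene[labels$class == "LPR"],
              file.path(dir, "lpr_genes.txt"))
  write_tsv(labels[, c("gene", "rna_log2fc", "chro_log2fc", "class")],
            file.path(dir, "ptr_scatter.tsv"))
  invisible(NULL)
}

stage_enrich <- function(config) {
  dir <- file.path(config$out_dir, "enrich")
  utr_path <- in_path(config, "utr_fasta", "inputs/utrs.fa")
  utrs <- read_fasta(utr_path)
  matures <- read_fasta(in_path(config, "mirna_fasta", "inputs/mirnas.fa"))
  gpr <- read_gene_list(file.path(config$out_dir, "ptr", "gpr_genes.txt"))
  lpr <- read_gene_list(file.path(config$out_dir, "ptr", "lpr_genes.txt"))
  up <- read_gene_list(file.path(config$out_dir, "de", "selected_up.txt"))
  down <- read_gene_list(file.path(config$out_dir, "de", "selected_down.txt"))
  with_seq <- intersect(c(up, down), names(matures))
  map <- build_site_map(utrs, matures[with_seq])
  universe <- map$universe
  if (config$universe == "expressed") {
    rna_de <- read_tsv(file.path(config$out_dir, "ptr", "rna_de.tsv"))
    universe <- intersect(universe, rna_de$feature[!is.na(rna_de$p)])
  }
  gpr <- intersect(gpr, universe)
  lpr <- intersect(lpr, universe)
  rep <- master_regulator_report(
    gpr, lpr, up_families = up, down_families = down, map = map,
    n_sim = config$n_sim, rng_seed = child_seed(config$seed, "enrich"),
    universe = universe, length_binned = config$length_binned)
  write_tsv(rep$gpr, file.path(dir, "gpr_enrichment.tsv"))
  write_tsv(rep$lpr, file.path(dir, "lpr_enrichment.tsv"))
  write_lines(c(sprintf("up\t%s", rep$excluded_up),
                sprintf("down\t%s", rep$excluded_down)),
              file.path(dir, "excluded_families.txt"))
  invisible(NULL)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate, de, locus,
#' ptr, enrich), writing each stage's outputs before the next starts, then
#' a `manifest.json` (config echo, package version, per-stage seeds, md5
#' checksum per output file) and a `timings.tsv` sidecar. Reruns with the
#' same config and seed yield byte-identical bundles apart from the timing
#' sidecar.
#'
#' @param config a `PipelineConfig` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  order <- c("simulate", "de", "locus", "ptr", "enrich")
  stages <- order[order %in% config$stages]
  fns <- list(simulate = stage_simulate, de = stage_de, locus = stage_locus,
              ptr = stage_ptr, enrich = stage_enrich)
  timings <- data.frame(stage = character(0), seconds = numeric(0))
  for (s in stages) {
    t0 <- proc.time()[["elapsed"]]
    stage_wrap(s, fns[[s]](config))
    timings <- rbind(timings,
                     data.frame(stage = s,
                                seconds = proc.time()[["elapsed"]] - t0))
  }
  files <- sort(setdiff(
    list.files(config$out_dir, recursive = TRUE),
    c("manifest.json", "timings.tsv")))
  sums <- unname(tools::md5sum(file.path(config$out_dir, files)))
  manifest <- list(
    package = "mirptr",
    version = as.character(utils::packageVersion("mirptr")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) child_seed(config$seed, s)), stages),
    grouping = config$grouping,
    stages = stages,
    de_params = unclass(config$de_params),
    ptr_params = unclass(config$ptr_params),
    n_sim = config$n_sim,
    universe = config$universe,
    checksums = stats::setNames(as.list(sums), files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(timings, file.path(config$out_dir, "timings.tsv"))
  invisible(manifest)
}

#' Matched tumor/normal pair report
#'
#' For patients with exactly one tumor and one normal sample, reports each
#' miRNA's normalized expression in both tissues and a per-miRNA paired
#' sign summary. No statistics beyond the normalization of the DE stage.
#' Patients without a complete pair (e.g. a tumor without matched normal)
#' are excluded and listed.
#'
#' @param counts a [count_matrix()] whose metadata has a `patient` column
#'   (or supply `pairing`).
#' @param features optional feature subset (default all).
#' @param pairing optional named vector sample -> patient overriding the
#'   metadata column.
#' @return list with `pairs` (mirna, patient, normal, tumor, higher_in
#'   tumor flag), `summary` (per miRNA: n_pairs, n_tumor_higher,
#'   frac_tumor_higher) and `excluded_patients`.
#' @export
matched_pair_report <- function(counts, features = NULL, pairing = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  meta <- counts$meta
  if (is.null(pairing)) {
    if (is.null(meta$patient)) abort_input("no pairing map: metadata lacks a patient column")
    pairing <- stats::setNames(meta$patient, meta$sample)
  }
  if (!length(pairing)) abort_input("empty pairing map")
  meta$patient <- pairing[meta$sample]
  sf <- compute_size_factors(counts)
  norm <- sweep(counts$counts, 2L, sf, "/")
  if (is.null(features)) features <- rownames(norm)
  split_p <- split(meta, meta$patient)
  complete <- vapply(split_p, function(d) {
    sum(d$condition == "tumor") == 1L && sum(d$condition == "normal") == 1L
  }, TRUE)
  excluded <- names(split_p)[!complete]
  split_p <- split_p[complete]
  if (length(split_p) < 2L) abort_input("need >= 2 complete tumor/normal pairs")
  pairs <- do.call(rbind, lapply(split_p, function(d) {
    t_s <- d$sample[d$condition == "tumor"]
    n_s <- d$sample[d$condition == "normal"]
    data.frame(mirna = features, patient = d$patient[1L],
               normal = norm[features, n_s], tumor = norm[features, t_s],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  pairs$tumor_higher <- pairs$tumor > pairs$normal
  pairs <- pairs[order(pairs$mirna, pairs$patient), ]
  rownames(pairs) <- NULL
  agg <- stats::aggregate(tumor_higher ~ mirna, data = pairs,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  summary <- data.frame(mirna = agg$mirna,
                        n_pairs = agg$tumor_higher[, "n"],
                        n_tumor_higher = agg$tumor_higher[, "k"],
                        frac_tumor_higher = agg$tumor_higher[, "k"] /
                          agg$tumor_higher[, "n"],
                        stringsAsFactors = FALSE)
  list(pairs = pairs, summary = summary, excluded_patients = excluded)
}
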