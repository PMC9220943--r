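# mirptr

Master microRNA regulator inference from paired transcription and expression
data.

## The problem

In tumors driven by a single lesion — fibrolamellar carcinoma (FLC), a rare
liver cancer of adolescents and young adults, is the motivating case — broad
gene-expression changes can arise without matching changes in transcription.
When a gene's steady-state RNA falls while its transcription rate is flat,
something posttranscriptional is degrading or repressing it; microRNAs are
prime suspects. `mirptr` is for computational biologists who have (or want to
simulate) three data modalities for a tumor/normal cohort:

* small RNA-seq miRNA counts,
* RNA-seq gene counts (steady-state expression),
* nascent transcription (ChRO-seq/PRO-seq): gene-level counts, TRE calls
  (BED) and per-sample signal tracks (bedGraph),

and want to answer: **which miRNAs are candidate master regulators of the
posttranscriptionally dysregulated genes?**

## The method

1. **Differential miRNA abundance** — per-feature negative-binomial GLM
   (variance μ + αμ²) on `~ condition + batch` with median-of-ratios size
   factors, method-of-moments dispersions shrunk toward a mean–dispersion
   trend, Wald test on a t reference, BH adjustment. Selection keeps miRNAs
   with padj < 0.05, mean normalized counts > 1000 in either group, and
   coefficient of variation < 2 across tumor samples.
2. **miRNA locus transcription** — each miRNA's locus spans from the nearest
   upstream TRE (strand-aware) to the end of the mature miRNA; absolute
   nascent signal is summed over the locus per sample and tested for
   differential transcription, giving a transcription-vs-expression
   concordance report.
3. **PTR classification** — a gene *gains* posttranscriptional regulation
   (GPR) iff |ChRO-seq log2FC| < 0.59 and ChRO-seq FDR > 0.2 while RNA-seq
   normal-group mean > 1000, log2FC < −1 and FDR < 0.05; *loss* (LPR) is the
   mirror image on the tumor-group mean.
4. **Seed-site enrichment** — canonical target sites (8mer, 7mer-m8,
   7mer-A1) are counted in 3'UTRs; the cumulative site count over the
   GPR gene list is compared against 1000 random same-length gene lists
   (shared across miRNA families), with add-one empirical p-values
   p = (#{null ≥ observed} + 1)/(n_sim + 1). Upregulated miRNAs are tested
   against GPR genes, downregulated against LPR genes; the top-ranked family
   is the master-regulator nominee.

A first-class synthetic-data module (`sim_config()`, `simulate_*()`)
generates all inputs with planted ground truth. See
`vignettes/mirptr-methods.Rmd` for models, defaults, numerical choices and
limitations.

## Worked example

Simulate a cohort with two planted upregulated miRNAs (`mir_0001`, the
designated master, has 3-fold enriched seed sites in the 120 planted
gain-of-PTR genes), then run the chain:

```r
library(mirptr)

cfg <- sim_config(
  n_mirnas = 200L, n_genes = 2000L, n_tumor = 12L, n_normal = 8L,
  dispersion = 0.05,
  planted_up_mirnas = c(mir_0001 = 2.5, mir_0002 = 2),
  planted_down_mirnas = c(mir_0003 = -2),
  planted_gpr = setNames(rep(-2, 120), sprintf("gene_%05d", 1:120)),
  planted_lpr = setNames(rep(2, 60), sprintf("gene_%05d", 121:180)),
  master_mirna = "mir_0001", site_enrichment_odds = 3, rng_seed = 1L)

sim <- simulate_mirna_experiment(cfg)
de  <- nb_wald_de(sim$counts)
sel <- select_de_mirnas(de, de_params())
sel$up[, c("feature", "baseMean", "log2fc", "padj", "cov_tumor")]
#>    feature baseMean log2fc     padj cov_tumor
#> 1 mir_0001     7147   2.47 9.48e-11     0.207
#> 2 mir_0002     7289   1.89 4.77e-09     0.212
```

Both planted up-miRNAs pass the abundance/consistency filters with fold
changes near truth (2.5 and 2). Classify genes from the paired matrices:

```r
ptr <- simulate_ptr_experiment(cfg)
labels <- classify_ptr(nb_wald_de(ptr$chro), nb_wald_de(ptr$rna))
table(labels$class)
#>          GPR          LPR unclassified
#>          114           60         1826
```

114 of the 120 planted GPR genes and all 60 LPR genes are recovered. Test
the upregulated miRNAs' seed sites in the GPR genes:

```r
seqs <- simulate_utrs_and_mirnas(cfg)
map  <- build_site_map(seqs$utrs, seqs$mirnas[sel$up$feature])
res  <- rank_enrichment(empirical_enrichment(
  labels$gene[labels$class == "GPR"], map, n_sim = 1000L, rng_seed = 1L))
res[, c("mirna", "observed", "null_mean", "p", "neg_log10_p", "rank")]
#>      mirna observed null_mean        p neg_log10_p rank
#> 1 mir_0001      170     69.88 0.000999      3.0004    1
#> 2 mir_0002       68     67.94 0.523477      0.2811    2
```

The planted master carries 170 sites in the GPR UTRs against a null mean of
~70 and attains the minimum possible p (1/1001); the non-master miRNA sits
at its null expectation. `run_pipeline()` / the `inst/cli/mirptr` script
(`simulate`, `de`, `locus`, `ptr`, `enrich`, `run-all`, `report`,
`enrich-files`) chain the same stages from a JSON config with a checksummed,
byte-reproducible result bundle; `inst/extdata/fixture_config.json` is a
complete example.

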