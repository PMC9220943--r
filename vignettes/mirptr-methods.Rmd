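---
title: "mirptr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirptr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`mirptr` implements an integrative strategy for nominating *master microRNA
regulators* in a two-condition design (tumor vs adjacent normal tissue), of
the kind used to study fibrolamellar carcinoma. The reasoning chain is:

1. **Differential miRNA abundance** (small RNA-seq counts): which miRNAs are
   up or down in tumors, restricted to abundant, consistently expressed ones?
2. **Transcription at miRNA loci** (nascent-transcription signal such as
   ChRO-seq/PRO-seq): is a miRNA's expression change driven by transcription
   of its locus, or does it arise post-transcriptionally?
3. **Genes under posttranscriptional regulation (PTR)**: which genes change
   at steady state (RNA-seq) while their transcription (ChRO-seq) does not?
   Down at steady state = *gain* of PTR (GPR); up = *loss* of PTR (LPR).
4. **Seed-site enrichment**: are the 3'UTRs of GPR genes enriched for binding
   sites of the tumor-upregulated miRNAs (and LPR genes for sites of the
   downregulated ones)? A miRNA whose sites are over-represented is a
   candidate master regulator.

A synthetic-data module generates every input with known ground truth, so
each stage — and the full pipeline — is testable offline.

## Differential expression model

Counts are modeled as negative binomial with variance
$\mathrm{Var}(K) = \mu + \alpha\,\mu^2$. Normalization uses median-of-ratios
size factors: $s_j = \mathrm{median}_i\, K_{ij} / (\prod_j K_{ij})^{1/n}$
over features with no zero counts. Note these factors are defined only up to
a common scale: multiplying one sample's counts by $c$ multiplies its factor
by $c$ *relative to the others* (the geometric-mean reference itself moves).

Per feature, a NB GLM with log link is fit on `~ condition + batch` with
$\log s_j$ offsets. Dispersion is estimated by method of moments within
design cells (condition × batch), pooled with $(n_c - 1)$ weights, then
shrunk on the log scale toward a parametric trend
$\alpha(\mu) = a_0 + a_1/\mu$ fit by trimmed least squares; the shrinkage
weight is $d/(d + d_0)$ with $d$ the residual degrees of freedom and prior
strength $d_0 = 15$. The condition coefficient is tested with a Wald
statistic referred to a **t distribution on the residual degrees of
freedom** rather than a normal: with ~20 samples the plug-in dispersion makes
the normal reference anticonservative (empirical type-I error ≈ 0.06 at
nominal 0.05 in our null simulations; the t reference restores ≈ 0.045–0.05).
P-values are Benjamini–Hochberg adjusted over tested features; all-zero
features are reported with absent statistics. The implementation is
intentionally from scratch (the test suite checks agreement with DESeq2 on a
shared fixture: median |Δlog2FC| < 0.1, Spearman correlation of p > 0.95),
because downstream stages — not the DE engine — are the substance here.

### Selection filters

`select_de_mirnas()` keeps features with adjusted p below `alpha` (0.05),
average normalized counts above `min_group_mean` (1000) **in either group**,
and coefficient of variation below `max_cov` (2.0). Choices on points the
underlying analysis leaves open:

* CoV is computed on size-factor-normalized counts across **tumor** samples
  only, with the sample (n−1) standard deviation. Whether the original
  analysis used normalized counts or reads-per-million is not documented;
  normalized counts keep the filter consistent with the DE model.
* No |log2FC| ≥ 2 filter is applied by default: the ±2 volcano-plot guides
  are treated as visualization, not selection. A `min_abs_log2fc` knob exists
  for users who read them as a rule.

### Ordination matrix and the pan-cancer statistic

`vst_batch_adjust()` returns `log2(normalized + 1)` (a monotone, variance
stabilizing transform adequate for PCA/Euclidean clustering at these depths)
with the fitted batch term removed per feature by linear regression on
centered batch indicators, preserving each feature's grand mean; a single
batch is the identity. `geometric_mean_log2fc()` computes
$\log_2(\mathrm{geomean}(T + c)/\mathrm{geomean}(N + c))$ for ranking tumor
types; the pseudocount defaults to 1 exactly when zeros are present and is
recorded on the result.

## miRNA loci and transcription

A miRNA locus runs from the **nearest upstream TRE** (transcriptional
regulatory element, the promoter call) to the **end of the mature miRNA**.
Upstream is strand-aware — greater genomic coordinates for minus-strand
miRNAs — and distance is measured from the TRE edge closest to the mature 5'
end; a TRE overlapping the 5' end qualifies with gap 0. Ties (identical gap)
break toward the wider TRE, then lexicographic id; the source analysis does
not address ties. Loci without a TRE within `max_distance` (default 100 kb)
are excluded from testing and listed with reason `no_upstream_tre`.

Signal over a locus is the sum of absolute per-base values (minus-strand
nascent bedGraphs conventionally store negative values), restricted to the
miRNA strand by default; whether the original quantification used one or
both strands is not stated, and `strand_mode = "both"` is available.
Cross-sample normalization for differential transcription uses genome-wide
signal totals as size factors (scaled to geometric mean 1), another
convention the source leaves open. Locus totals are rounded to integers and
reuse the NB machinery. `concordance_report()` joins expression and
transcription fold changes, reports sign agreement over
expression-significant miRNAs, and flags miRNAs whose expression change
exceeds the transcription change by more than `gap` (default 2) log2 units
as PTR candidates.

## PTR classification

With defaults, a gene is **GPR** iff |ChRO log2FC| < 0.59 and ChRO FDR > 0.2
(transcriptionally quiet) and RNA normal-group mean > 1000, RNA log2FC < −1,
RNA FDR < 0.05; **LPR** mirrors it on the tumor-group mean and positive fold
change. 0.59 is used exactly as printed (≈ log2 1.5). The transcription
bound is symmetric by default, following the figure-caption reading
("< ±0.59"); the methods text prints one-sided bounds
(GPR: > −0.59; LPR: < 0.59), available via `strict_methods = TRUE`. Where
the two sources disagree on the GPR expression sign (caption "< 1" vs
methods "< −1"), the methods sign is used. All comparisons are strict;
absent statistics fail their condition; genes missing from either table are
`unclassified` with reason `missing_modality`, and other unclassified genes
carry the first failing condition in printed order.

## Seed sites and Monte-Carlo enrichment

Sites are counted de novo by seed matching rather than imported from
TargetScan predictions (the original tool consumed those, which require
multi-species conservation data); `read_site_map()` accepts a precomputed
`(mirna, gene, count)` table when real predictions are available. For mature
sequence $m$, seed7 = $m_{2..8}$:

| type | pattern | length |
|---|---|---|
| 8mer | revcomp(seed7) + A | 8 |
| 7mer-m8 | revcomp(seed7) | 7 |
| 7mer-A1 | revcomp($m_{2..7}$) + A | 7 |

T and U are equivalent; N never matches; 6mer-only sites are not counted.
Each position hosts at most one site of the best (longest) type, and
overlapping occurrences resolve greedily left to right. IsomiRs with shifted
5' ends share the canonical family unless the caller builds a family from
the shifted sequence explicitly.

The gene-list score for a miRNA is the cumulative site count over the list.
`empirical_enrichment()` draws `n_sim` (default 1000) random lists of the
same length, uniformly without replacement from the universe (default: all
UTR-annotated genes; "expressed genes" is a pipeline option), **sharing one
sequence of null draws across all families**, and reports the add-one
empirical p-value $(\#\{S_{null} \ge S_{obs}\} + 1)/(n_{sim} + 1)$, never 0,
minimum $1/(n_{sim}+1)$.

**A caveat that matters for calibration studies:** because every family is
scored against the same observed list and the same null draws, family-wise
p-values are positively correlated — a list whose total UTR length happens
to sit above the universe average lifts all families' scores at once. Each
p-value is marginally calibrated, but the *set* of p-values from one run is
not an i.i.d. uniform sample, and one-run uniformity diagnostics (e.g. a KS
distance over the 200 families of a null run) will fluctuate far beyond
i.i.d. expectations. The `length_binned` option, which draws null genes
within UTR-length deciles, removes most of this shared component; it is off
by default to match the published procedure ("random gene lists of the same
length").

## The synthetic-data module

The generators state a world resembling the deposited cohorts at desk scale;
defaults are chosen once and documented here:

* **miRNA counts**: 33 tumor / 10 normal samples (the small RNA-seq cohort
  sizes), 2 sequencing batches balanced within condition, NB dispersion
  α = 0.05 (typical for bulk counts), per-sample depth factors
  $2^{N(0, 0.35)}$, per-feature batch shifts $2^{N(0, 0.3)}$, baseline
  abundances $2^{N(6, 2.5)}$ so the 1000-count floor is discriminative.
  Planted miRNAs take baseline $2^{N(11, 0.5)}$ — abundant, like the
  dysregulated miRNAs the filters target.
* **Paired PTR matrices**: GPR genes transcriptionally flat with RNA
  log2FC ≤ −1, LPR mirrored, transcriptional genes concordant in both
  modalities; planted genes are given high baselines so the expression floor
  is satisfiable. Nascent-signal baselines are compressed relative to RNA
  (half the dynamic range plus noise), as in real ChRO-seq.
* **UTRs and miRNAs**: uniform-composition UTRs 200–2000 nt; mature 22-mers
  with distinct seeds; 8mer sites injected at `baseline_site_rate`
  (0.5 sites/kb) for every miRNA and ×`site_enrichment_odds` for the master
  miRNA in GPR-gene UTRs. Instead of per-site rejection sampling, all of a
  UTR's injections are placed by uniform sampling over *non-overlapping*
  configurations (order-statistics construction): exact, retry-free, and no
  injected site can overwrite another, so every recorded injection is
  rediscoverable by a string scan. Surplus sites a UTR cannot host are
  dropped at random and counted.
* **Tracks**: one miRNA per 20-kb block on a single chromosome; true
  promoter TRE 0.5–5 kb upstream (strand-aware), decoy TREs placed strictly
  farther upstream or downstream so the designated promoter is always the
  nearest; signal piled uniformly over the locus with per-sample depth and
  lognormal noise ($2^{N(0,0.25)}$); planted up/down miRNAs scale tumor
  signal by their fold change, making their DE transcription-driven.
  Per-base values are rounded to 6 decimals *before* the truth totals are
  derived, so emitted bedGraph sums equal the recorded truth exactly.

What the generator does **not** emulate: isomiR 5'-shifts, read-level noise
and mapping artifacts, sequence composition bias and conservation, overlapping
transcription units, unbalanced batch/condition designs (available via
options but not default). A green test on this world establishes correctness
of the algorithms, not biological fidelity.

Randomness policy: one global seed per run; every generator and the
permutation test derive a child stream (`child_seed(seed, tag)`), so stages
can be re-run independently and full runs are byte-identical (the pipeline
bundle is checksummed in `manifest.json`; wall-clock timings live in a
sidecar file so they do not break identity).

## Numerical choices and degenerate inputs

* Dispersion MoM estimates are clamped to [1e−8, 20] and to within ×30 of
  the trend before log-scale shrinkage.
* IRLS runs at most 40 iterations with linear predictors clamped to ±30 and
  coefficients to ±25 (caps group log-fold-changes when one group is all
  zero); convergence tolerance 1e−8.
* CoV is undefined (absent) for n < 2 or non-positive mean; absent values
  always fail selection filters.
* Empirical p-values are exactly reproducible under a fixed seed; the same
  seed gives both enrichment arms identical null draws for equal-length
  lists.
* Promoter ties break deterministically (gap, then width, then id), making
  locus construction invariant to TRE input order.

## Known limitations

* The NB test is a minimal implementation: no Cox–Reid adjustment, no
  outlier refitting, no independent filtering; it is calibrated in the
  regimes the tests cover (n ≈ 10–40 per group).
* Seed matching ignores conservation, site context and 3'-supplementary
  pairing, so per-gene site counts are noisier than TargetScan-style scores;
  the enrichment test inherits that noise symmetrically under the null.
* Family-wise enrichment p-values from one run are correlated (see above);
  rank order within a run is meaningful, a family-wise FDR across miRNAs is
  not provided.
* The locus model assumes a single promoter TRE; multi-TSS miRNA loci and
  host-gene co-transcription are out of scope.
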