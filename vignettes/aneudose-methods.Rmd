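---
title: "Methods: sex-chromosome dosage analysis in aneudose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome dosage analysis in aneudose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneudose)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## Territories

Genes and SNPs are classified into six territories — AUTOSOME, PAR1, PAR2,
NPX, NPY, MT — from a `territory_map()`. The default map uses the GRCh38
PAR boundaries (X PAR1 10,001–2,781,479; X PAR2 155,701,383–156,030,895,
1-based; Y mirrors), stored internally 0-based half-open. BED input is taken
as-is; the minimal GTF reader shifts starts by one on read.

Two conventions are deliberate:

- **Midpoint classification.** A gene straddling a PAR boundary is assigned
  by its interval midpoint. Boundary-straddling genes are rare (XG is the
  prominent example; the bundled annotation keeps its PAR1 portion so the
  midpoint rule retains the gene in PAR1).
- **No guessed homologs.** The NPX–NPY pair table contains only annotated
  functional pairs (UTY–KDM6A, DDX3Y–DDX3X, ...). Y genes without an
  annotated partner (e.g. the lncRNA TTTY14) return `NA` from
  `homolog_lookup()` rather than a guess.

The bundled PAR annotation follows the Ensembl-style GRCh38 release the
RNA-seq convention targets: 25 PAR1 entries (protein-coding plus named
ncRNA/pseudogene loci) and 4 PAR2 entries (SPRY3, VAMP7, IL9R, WASH6P).
Users with a different release supply their own BED/GTF.

## The synthetic cohort: what it emulates

`simulate_expression_dataset()` states the simulated world once; its
defaults are not tuned per analysis.

| parameter | default | meaning |
|---|---|---|
| karyotypes | 46,XY; 47,XYY; 47,XXY; 46,XX | the four study designs (nX, nY) |
| patients × clones | 3 × 3 per karyotype | patient → clone hierarchy |
| `baseline_mean` | 100 counts | median of log-normal gene baselines (sdlog 1) |
| `nb_dispersion` | 0.05 | typical bulk RNA-seq NB dispersion |
| `patient_sd` | 0.1 | sdlog of the patient-by-gene random effect |
| PAR dosage | mean ∝ (nX+nY)/2 | every sex-chromosome copy expresses PARs |
| NPY dosage | mean ∝ nY | structural zeros at nY = 0 |
| `npx_compensation` | 0.8 per extra Y | applied to 25% of NPX genes; magnitude invented |
| autosomal DEGs | 10% at &#124;log2FC&#124; = 1 | planted in supernumerary karyotypes, concordant between 47,XYY and 47,XXY |

The patient effect is a log-normal multiplier drawn per patient *per gene*
and shared by that patient's clones: clones within a patient are correlated,
which is precisely the confounding the clone-resampling bootstrap exists to
address. A patient-level scalar would be absorbed by normalization and test
nothing.

Karyotype dosage acts multiplicatively on territory means relative to
46,XY. Note one structural consequence used in the tests: PAR means plateau
between 46,XX and 46,XY (both have two sex chromosomes), so PAR expression
correlates with nY only through the 47,XYY group and its attainable Pearson
r is bounded below 1, unlike NPY genes whose means are proportional to nY.

What the generator does **not** emulate: mapping bias and multimapping
between X–Y homologs, batch effects (the real pipeline's batch-correction
step is out of scope here), cell-type differences, mosaicism, and read-level
noise. A green test on this world establishes that the statistics recover
the dosage structure they target; it does not establish robustness to those
artefacts.

Randomness: one global seed; each generator derives its own sub-stream via
`substream_seed(seed, stage_name)` (a deterministic string hash below
2^31), so adding one generator call never perturbs another's draws.

### Allele counts

Heterozygous SNP read counts are binomial at the territory-determined
reference fraction: 1/2 on autosomes; wX·nX/(wX·nX + wY·nY) in the PARs
(1/2 in 46,XY, {1/3, 2/3} in 47,XYY with the ref allele chosen at random);
{0, 1} for hemizygous NPX/NPY SNPs. The per-chromosome weights default to
equal expression; they are exposed because observed cluster centres in real
data can sit below the theoretical 33.3/66.7% (Y-allele under-expression or
mapping bias — not modelled, only parameterized).

### CpG methylation

CpG positions use geometric spacing with mean 25 bp floored at 10 bp, and
planted DMR blocks are laid at CpG-island density (12 bp): RRBS enriches
CpG-dense MspI fragments and real DMRs live in islands, so coverage inside
a differentially methylated block is contiguous — a uniform heavy-tailed
spacing would fragment called regions at the 100 bp intra-region gap limit
for reasons that have nothing to do with methylation signal. Methylated
counts are beta-binomial with replicate overdispersion rho = 0.01, the
homogeneity of clonal lines; depth is Poisson around 30.

## Differential expression

Normalization is median-of-ratios (per sample, the median over
all-positive genes of the ratio to the gene's geometric mean; the test
suite checks exact agreement with DESeq2's implementation) or TMM (weighted
trimmed mean of log-ratios, 30% trim on M and 5% on A, precision weights,
factors normalized to geometric mean 1; checked against edgeR). The
low-expression filter scans 40 log-spaced thresholds in [0.1, 200] and
keeps the one maximizing the mean within-group Jaccard similarity of binary
expression calls, then drops genes below it in every sample.

The per-gene test is a Wald test on the log2 ratio of group means of
normalized counts, with a pseudo-count of 0.5 so zero-mean groups stay
finite. The NB dispersion is estimated by pooled within-group method of
moments on the normalized scale, then shrunk (weight 0.8) toward a fitted
`a0 + a1/mu` mean–dispersion trend and floored at 1e-8.

Two numerical choices deserve notice:

- **Normal reference, not t.** With the trend-dominated dispersion the null
  Wald statistic is empirically standard normal at 4 vs 4; a t(df = n−2)
  reference makes the test 3–4× conservative. The Monte-Carlo calibration
  test (20 reps, 500 genes) asserts type-I error in [0.03, 0.07] at
  alpha = 0.05.
- **Power at the threshold is dispersion-limited.** A 1.5-fold effect at
  dispersion 0.05 with 6 vs 6 has modest power at FDR < 0.05 for *any*
  test — near the information bound. The power test therefore uses
  dispersion 0.02 (clonal lines), where majority detection is attainable,
  and plants balanced up/down effects so median-of-ratios keeps its anchor.

DEG rule: FDR < 0.05 (Benjamini–Hochberg over tested genes) and
|log2FC| > 0.58; a strict FDR < 0.01 variant feeds the dosage
intersection. Outputs are sorted by gene id for determinism.

## Allele-specific expression

`min_depth = 10` and `minor_fraction_threshold = 0.10` are declared
conventions (the source analyses keep theirs in supplementary material);
both are arguments. Status comparison uses a 1e-9 tolerance so a ref/alt
swap maps f to 1−f bit-stably. PAR SNPs are reported on X regardless of
input coordinates (the standard Y-PAR masking convention); NPY SNPs stay on
Y flagged hemizygous.

Cluster count is decided by BIC between a 1-component binomial fit and a
2-component binomial mixture EM initialized deterministically at
(1/3, 2/3). Unimodal groups report the mean fraction; bimodal groups report
component-wise mean fractions. Groups under 20 calls return an explicit
"insufficient" result, never a guess.

## Y-dosage regression

Plain per-gene Pearson correlation of normalized expression with nY
(0/1/2), two-sided t test with df = n−2, BH over tested genes;
zero-variance genes are flagged and excluded from the adjustment.
Patient structure is deliberately ignored here (the source procedure is
plain Pearson); log2(x+1) transformation is available but off by default
because TMM values are correlated directly. Sensitivity rule:
|r| > 0.48, FDR < 0.01.

## Bootstrap stability

Each of 50 iterations draws one clone per patient uniformly (without
replacement within an iteration, with replacement across iterations),
recomputes size factors on the subset — factors depend on the sample set,
so re-normalizing per iteration is the defensible reading of the
procedure — and reruns the NB test at the study thresholds. The global
filtered gene set is reused; there is no per-iteration refiltering.
Control patients are resampled exactly like case patients. Per-gene output
is the percentage of iterations called DEG; with single-clone patients
every iteration is identical and the percentage collapses to {0, 100}.
Genes whose true fold change sits at the 0.58 threshold (PAR1's 1.5-fold
is log2 = 0.585) flicker by construction and are the motivating case for
reporting stability rather than a single call.

## Chromosome profiles

Per gene, MM = median FPKM across 46,XY reference samples after removing
nonexpressed genes — operationalized as FPKM ≥ 0.5 in ≥ 25% of reference
samples with MM > 0, both configurable, since "nonexpressed" has no numeric
definition in the source. FC = FPKM/MM, so the reference-group median FC is
1 per gene. The profile smooths log2 FC against gene midpoint with a
hand-rolled LOESS: tricube weights over the ceil(span·n) nearest
neighbours, local linear fit, no robustness iterations, span 0.45. The
implementation is verified against a per-point weighted-regression oracle
to 1e-8. log2 of FC uses no pseudo-count (MM = 0 genes are pre-excluded);
FC = 0 samples are capped at the 0.5th percentile of finite values — a
plotting convention, flagged as such. The PAR1-excluded variant drops PAR1
genes before fitting and leaves all other point values untouched.

## Cross-syndrome concordance

Shared DEGs are the set intersection of the two contrasts' DEG lists;
each shared gene is concordant-up (both log2FC > 0), concordant-down
(both < 0) or discordant. A zero fold change cannot reach the DEG threshold
— the classifier asserts this instead of assuming it. Percentages are
reported at full precision alongside the integer part, because published
tallies round inconsistently (140+40 of 246 is 73.17%, printed as 74%
in the source literature; the classifier reports 73).

## Methylation

The per-CpG test compares depth-weighted group methylation proportions with
a Wald statistic whose variance is beta-binomial: binomial plus
overdispersion rho. The per-CpG method-of-moments rho at 3 samples per
group is extremely noisy and skewed, so each estimate is moderated toward
the aggregate cross-locus MoM with `prior_df = 20` pseudo-degrees of
freedom — the empirical-Bayes practice of dedicated methylation packages.
CpGs with zero coverage throughout a group are skipped and counted.

DMR calling follows five stated steps: (1) significant CpG ⇔ p < 1e-5 and
|difference| ≥ 0.1; (2) seeds are maximal runs of significant CpGs with
gaps ≤ 100 bp, bounded by first/last significant CpG; (3) seeds spanning
< 50 bp or containing < 3 CpGs (significant or not) are dropped; (4)
surviving regions within 50 bp merge; (5) merged regions keep ≥ 50%
significant CpGs over their whole length. The locus threshold, 50 bp/3 CpG
minimums, 50 bp merge distance and 50% fraction are the study's rules;
`min_effect = 0.1` and `max_intra_gap = 100` are package conventions
exposed in `dmr_config()`. With the defaults the merge step only fires
when `max_intra_gap` is set below `merge_distance`; it exists (and is
tested) for that configuration and for idempotence of re-merging.
Promoters are TSS −2000/+500 strand-aware; promoter precedes gene body.
The DMR × DEG crosstab reports a Haldane-corrected odds ratio (0.5 per
cell when any cell is zero) and `NA` for empty tables.

## Workflow

`run_workflow()` executes qc → filter → normalize → de →
{dosage, bootstrap, profile, concord} with ase and methylation independent,
writes per-stage TSV/JSON sorted by gene id or coordinate, and a manifest
(R and package version, seed, config hash). Configs are R lists or JSON —
no YAML parser ships with the supported R stack, so YAML is intentionally
not a dependency. The numbered scripts under `analysis/` are the narrative
interface to the same functions.

## Known limitations

- The NB test is two-group only; multi-factor designs, LFC shrinkage and
  batch correction are out of scope.
- ASE ignores phasing and mapping bias; the 1/3 vs 2/3 assignment per SNP
  is arbitrary and both are reported.
- The dosage regression ignores patient clustering (by design, matching the
  source procedure), so its p-values are anticonservative under strong
  patient effects.
- DMR calling tests each CpG marginally (no spatial smoothing); the planted
  -block recovery criterion is met by density of significant CpGs, not by
  borrowing strength across neighbours.
- The bundled PAR1 coordinates are approximate gene spans, adequate for
  territory classification, not for base-pair-accurate annotation.
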