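---
title: "Methods: pathway activity, moderated differential expression and CNA profiles for rare disseminated cancer cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway activity, moderated DE and CNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcctools)
library(dplyr)
```

## Scope and scientific setting

Disseminated cancer cells (DCCs) are EpCAM-positive tumour cells detected in
bone marrow at frequencies below one per million nucleated cells. Profiling
them means working with a few dozen single cells per cohort — e.g. 29 cells
from patients without manifest metastasis (M0), 11 from metastatic patients
(M1) and 15 healthy-donor EpCAM+ cells — alongside small-replicate microarray
experiments on related mammary cell populations. `dcctools` implements the
statistical stages such a study chains together:

1. **stats core** — exact Fisher and hypergeometric tests, BH-FDR,
   non-centered correlation, Fisher p-value combination;
2. **preprocessing** — log2 transform, quantile normalization, replicate-probe
   collapse, per-gene probe disambiguation, biotype filtering, top-variable
   gene selection, display-side covariate compensation;
3. **differential expression** — per-gene linear models with covariates,
   empirical-Bayes variance moderation, and the exact differential-calling
   rule (FDR ≤ 0.05, |log2FC| ≥ log2 1.5, the latter optional);
4. **pathway activity** — gene-list enrichment of a differential signature,
   and the per-cell 2×2 membership-enrichment test over expressed genes with
   cohort aggregation and a core-gene partition;
5. **concordance** — differential-list overlap and non-centered fold-change
   correlation between contrast signatures;
6. **CNA frequency profiles** — size/blacklist filtering of per-cell gain and
   loss calls, cytoband annotation, and group-stratified cumulative
   frequencies;
7. **synthetic data** — seeded generators that emulate the structure of all
   of these inputs with ground truth attached.

All results are tibbles; the `run_*_arc()` functions compose the stages into
the four analysis arcs, and `plot_*()` helpers render the standard views.

## Exact tests and their conventions

### Two-sided Fisher exact test

For a 2×2 table with cell `a` and fixed margins, the one-sided (enrichment)
p-value is the upper hypergeometric tail of `a`. For the two-sided p-value
several conventions exist; `fisher_exact_2x2()` sums the probabilities of all
margin-fixed tables whose point probability is at most the observed one,
with a relative tie tolerance of 1e-7. This is the convention of
`stats::fisher.test` and the one under which the xenograft engraftment
comparison (2 of 4 M1-stage vs 0 of 42 M0-stage samples) gives exactly
6/1035 ≈ 0.0058, printing as 0.006. All combinatorics run in log-gamma
space so whole-transcriptome margins (~1e5) cannot overflow.

One caveat worth stating: the enrichment-tail p is bounded by the two-sided
p only when the table actually leans toward enrichment of cell (1,1). For a
depleted table the greater-tail p approaches 1 while the two-sided p does
not; the property tests therefore orient tables before asserting the
inequality.

### Hypergeometric overlap and BH-FDR

Differential-list overlaps use the upper hypergeometric tail computed by
direct log-space summation (`hypergeometric_tail()`), and multiplicity is
handled by Benjamini–Hochberg step-up adjustment (`bh_adjust()`, a validated
wrapper over `stats::p.adjust`). The overlap universe is always the set of
genes measured on *both* platforms after gene-level disambiguation — overlap
can only occur there.

### Non-centered correlation

Fold-change agreement between two contrasts is measured by
`r_nc = Σxy / sqrt(Σx² Σy²)` *without* centering, because agreement relative
to zero log fold change is what matters: two signatures that move the same
genes in the same direction should score high even if their mean fold
changes differ. The p-value maps `r_nc` through
`t = r √((n−2)/(1−r²))` with `n − 2` df — the exact law of the *centered*
Pearson correlation under independence, applied here to the non-centered
statistic. For mean-zero fold-change vectors the two statistics nearly
coincide and the null simulation below shows the size is close to nominal;
for strongly shifted vectors the law is approximate. We keep it because it
is the convention the readout was designed around; the caveat stands
documented rather than silently "fixed".

## Moderated differential expression

Per gene, a weighted least-squares model `value ~ 0 + group (+ covariate)`
yields the contrast coefficient (log2FC), residual mean square `s²_g` and
residual df `d_g`. The empirical-Bayes prior assumes
`s²_g ~ s0² d0 / χ²_{d0}` and is fitted by moments on `log s²`:

* `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`
* solve `ψ′(d0/2) = var(e) − mean(ψ′(d_g/2))` by Newton inversion of the
  trigamma function;
* `log s0² = mean(e) + ψ(d0/2) − log(d0/2)`.

When the spread of `log s²` does not exceed what sampling noise alone
explains, the trigamma equation has no finite solution and `d0` is capped at
1e6 (effectively infinite shrinkage); with exactly equal variances the prior
variance reduces to that common value. The moderated statistic is
`t̃ = log2FC / √(s̃² v_c)` with `s̃² = (d0 s0² + d_g s²_g)/(d0 + d_g)` and
`d0 + d_g` df, where `v_c` is the contrast's unscaled variance from the
design. Setting `moderate = FALSE` recovers the ordinary equal-variance
t-test exactly (verified against `t.test` to 1e-10), and feeding the prior
both ways reproduces `limma::eBayes` t-statistics to 1e-8 — limma serves as
the independent cross-check, never the implementation.

Differential calling uses the study's exact rule: FDR-adjusted p ≤ 0.05 and,
when the fold-change limit is on, |log2FC| ≥ log2(1.5) = 0.58. The
label-retaining-cell arc disables the fold-change limit, mirroring the
pooled LRC vs (nLRC + QSC) analysis. For all-pairwise designs
(`pairwise_de()`) one model is fitted over all groups, the moderation prior
is estimated once from the full-model residuals, and BH runs within each
contrast separately — per-contrast differential counts are the quantity such
studies report.

Patient effects are handled in two deliberately distinct ways: as a model
covariate for inference (the coefficient is unchanged by any balanced
covariate, tested to 1e-9) and by `remove_known_effect()` for display only.
The latter subtracts the fitted covariate term under treatment coding, so a
+2 shift on the affected samples is removed as +2; `limma::removeBatchEffect`
differs only by a per-gene centering constant.

## Per-cell pathway activity

A gene is *expressed* in a cell when its log2 normalized value is strictly
greater than 0 — a value of exactly 0 (dropout) does not count. For every
cell and pathway the 2×2 table crossing expressed/not with member/not over
the universe is tested one-tailed for enrichment of members among expressed
genes. The universe defaults to the protein-coding genes present in the
matrix, matching the upstream biotype filter; whether genes undetected in
every cell should be excluded is genuinely open, so the universe is a plain
argument.

Cell-level p-values must then be aggregated to a cohort statement. No
published rule exists for this step, so `summarize_pathway_enrichment()`
always reports two views side by side: the fraction of cells individually
significant at α = 0.05, and a Fisher combination across cells with BH
adjustment across pathways (`enriched` = combined q ≤ 0.05). The combination
treats cells as independent, which patient structure can violate; the
fraction view is insensitive to that and the two rarely disagree on spiked
synthetic cohorts.

The core-gene partition keeps pathway genes expressed in at least half of
the cells of interest — inclusively, so 20 of 40 qualifies — and splits them
into pathway-private and shared genes with their partner pathways listed.

## CNA frequency profiles

Aberration calls are 1-based closed intervals (cytogenetic convention);
0-based half-open BED input is converted at the I/O boundary. Filtering
drops calls shorter than 1 Mb (strictly: 999,999 bp goes, 1,000,000 bp
stays), calls on chromosomes absent from the cytoband table, and calls whose
overlap with the merged blacklist exceeds 50% of their length. The published
analyses name centromeric/telomeric regions and recurrent artifacts but not
coordinates or an overlap rule, so the 50% threshold is an exposed default
and `default_blacklist()` derives centromeres from the cytoband stain column
plus fixed 1 Mb terminal flanks; any custom blacklist table can be supplied.
Per-rule drop counts are always attached so the record ledger balances.

The frequency profile reports, per group, bin and type, the percentage of
cells carrying at least one overlapping call — a cell counts once per
(bin, type) however many calls it has there, and may count for both gain and
loss. Band-range annotation is ISCN-style (`p12-p11` across the overlapped
bands). Interval overlap runs on IRanges; an independent double-loop oracle
confirms the profiles exactly in the tests.

## What the generators emulate — and what they do not

The synthetic module exists so that every stage is testable without the
controlled-access cohort data. Design choices, frozen once:

* **Single-cell matrices** are zero-inflated on the log2 scale: gene g is
  expressed in cell c with probability π0 (default 0.4), lifted by δ
  (default 0.3) for members of a pathway active in the cell's group;
  expressed values are `max(0, baseline + patient + batch + noise)` with
  baseline ~ U(1, 6) and effect SDs 0.3/0.3/0.5, zeros otherwise. Cohort
  sizes default to 29/11/15 cells from 21/5/7 patients — the study scale —
  with 12 candidate pathways of 40–80 genes, 4 of them active in the DCC
  groups. Counts are *not* simulated: every in-scope operation consumes
  log2-normalized values, so negative-binomial count noise, ambient RNA and
  amplification 3'-bias are out of scope. Passing tests therefore
  demonstrate correctness of the statistics on data with this structure,
  not robustness to raw scRNA-seq artifacts.
* **Bulk two-group matrices** draw gene variances from the scaled
  inverse-chi-square law (d0 = 4, s0² = 0.05 by default), plant 10% true DE
  at |log2FC| = 1 in 5 + 5 replicates, and optionally add balanced paired
  patient shifts.
* **Signature pairs** share a standard-normal latent fold-change vector with
  noise scaled to a target non-centered correlation (σ² = (1−ρ)/ρ), so the
  realized correlation is ρ in expectation.
* **Aberration calls** place Poisson(3) events per cell with log-normal
  lengths centred at 2 Mb (straddling the 1 Mb filter boundary) on a toy
  3-chromosome genome with 10 Mb bands.

Determinism: every generator is a pure function of `(config, seed)`; the
global seed is split into per-generator sub-streams by hashing the generator
name, so adding a generator never perturbs the others. `write_fixtures()`
regenerates its file set bit-identically from the recorded seed.

## Numerical choices and degenerate inputs

* Fisher/hypergeometric tails: log-gamma combinatorics, log-sum-exp
  accumulation, tie tolerance 1e-7 on the two-sided definition.
* All-zero contingency tables give p = 1 and an undefined odds ratio; zero
  p-values entering the Fisher combination are clamped to the smallest
  positive double with a warning, never propagated as −∞.
* Quantile normalization resolves ties by averaging the tied rank targets;
  missing values are rejected rather than imputed.
* "Most variable" genes are ranked by the plain sample variance (the
  unqualified wording of the source analyses), ties broken lexicographically;
  the log2 offset defaults to 1. Both are arguments, not constants.
* Probe disambiguation breaks p-value ties by larger |log2FC|, then by
  lexicographically smaller probe id, so gene tables are reproducible.
* A covariate perfectly confounded with the groups, a rank-deficient design,
  or a contrast group with fewer than two samples are errors naming the
  problem, not silent drops (pairwise contrasts skip under-filled pairs with
  a warning).
* Correlation over fewer than 3 genes yields NaN with a warning; an empty
  differential list yields overlap 0 with p = 1.

The concordance gene selection defaults to the *intersection* of the two
differential lists — the number of common differential genes is the reported
overlap statistic, and correlating exactly those genes keeps the two numbers
coupled — with `selection = "union"` available because the alternative
reading (all genes differential in either list, measured in both) is
plausible; the choice is always echoed in the output.

## Problem sizes used by the test suite

The suite and the acceptance script regenerate everything they measure.
Sizes were chosen to make the checks statistically meaningful on one CPU in
a few minutes: the exhaustive two-sided Fisher sweep covers all 46,376
tables with total ≤ 30 against a factorial oracle; the pathway null
calibration pools four cohorts of 170 cells × 12 pathways (8,160 tests,
pathway sizes 100–200 over a 1,000-gene universe so the discrete-test
lattice is fine near the 5% level); the correlation null uses 1,000
signature pairs; prior recovery uses 5,000 genes; spiked-pathway ranking
uses 50 cohorts of 26 cells.

## Known limitations

* Gene symbols are the only join key between matrices and gene sets; no
  alias resolution is attempted (symbols are case-normalized).
* Array quality weights are accepted as per-sample weights but never
  estimated; background correction is assumed done upstream.
* The Fisher combination across cells assumes independence between cells of
  a cohort; patient clustering makes it anti-conservative, which is why the
  fraction-significant view is always reported alongside.
* The non-centered correlation p-value borrows the centered-Pearson law, as
  discussed above.
* Real NCI-Nature pathway definitions, batch rescaling of single-cell
  counts, and CNA calling from raw reads are outside the package; inputs
  enter at the level of log2-normalized matrices, GMT files and interval
  calls.
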