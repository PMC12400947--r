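---
title: "Batch-level QC of low-pass imputed genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-level QC of low-pass imputed genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdiqc)
```

## The problem

Genotype imputation from ultra-low-coverage whole-genome sequencing
(roughly 0.05–0.3×, e.g. cell-free DNA sequenced for noninvasive prenatal
screening) yields, for each variant and sample, a posterior genotype
probability triplet (GP, over hom-ref / het / hom-alt), an expected
alternate-allele dosage (DS = p(het) + 2·p(hom-alt)), and a hard call (GT).
Per-genotype accuracy is good but not uniform, and the conventional remedy —
setting every genotype with max(GP) < 0.99 to missing, per sample — breaks
down as soon as many samples are pooled: each sample masks a different
20–50% of sites, so in a cohort of hundreds there may be no site left intact
in every sample. That is the *cumulative missingness* problem.

The GDI strategy this package implements filters at the **batch level** and
removes only whole variants and whole samples, never individual genotypes:

1. **INFO exclusion.** A per-variant INFO score is collected for every
   imputation batch; a variant is excluded only if its score falls below
   `info_min` (default 0.4, strict) in *every* batch where it was observed.
2. **MAF restriction.** Analysis is restricted to panel variants with
   minor-allele frequency ≥ `maf_min` (default 5%); rare variants are not
   imputable at useful accuracy at these depths.
3. **GP/DS flags and LQV.** Each remaining genotype is flagged when its
   max(GP) is below `gp_min` (default 0.99) and/or its dosage is
   inconsistent with its call (hom-ref passes at DS ≤ 0.1, hom-alt at
   DS ≥ 1.8, het within [0.8, 1.01]). The fraction of a sample's flagged
   genotypes is its low-quality-variant (LQV) score.
4. **Outlier samples.** Samples with LQV strictly above `lqv_outlier_max`
   (default 40%) are removed. These are, in practice, the lowest-coverage
   samples.
5. **Variant-fraction exclusion.** Variants flagged in strictly more than
   `variant_fail_max` (default 30%) of the retained samples are removed.

The result contains no masked genotypes at all, which is what downstream
tools such as PCA need from a pooled cohort.

## The INFO score

Imputation tools summarise per-variant certainty with an INFO score in
[0, 1]; different tools expose it under different INFO tags (the tag name
is configurable in `read_imputed_vcf()`, and `gdi_config(info_source =
"tag")` uses it). Because the exact formula behind a given tool's tag is
not always documented, the package also recomputes the standard
ratio-of-variances measure of the IMPUTE/STITCH family directly from the
GP posteriors (`info_source = "recompute"`, the default, so a run is
self-contained). With per-sample expected dosage
$e_i = p_i(\mathrm{het}) + 2p_i(\mathrm{hom\text{-}alt})$ and second moment
$f_i = p_i(\mathrm{het}) + 4p_i(\mathrm{hom\text{-}alt})$:

$$\mathrm{INFO} = 1 - \frac{\sum_i (f_i - e_i^2)}
{2N\hat\theta(1-\hat\theta)}, \qquad
\hat\theta = \frac{\sum_i e_i}{2N}.$$

The score is 1 when every posterior is degenerate, and exactly 0 when every
posterior equals the Hardy–Weinberg prior at $\hat\theta$ — a flat,
non-informative distribution. Numerical choices: the score is clamped to
[0, 1]; monomorphic variants ($\hat\theta \in \{0,1\}$) take the
conventional value 1; and values within $10^{-9}$ of 0 are snapped to 0 so
the flat-posterior limit is exact despite floating-point summation (the
residue is orders of magnitude below any threshold anyone would use).

## Threshold semantics

All inequalities follow the published wording and are asserted in the test
suite at their boundaries: INFO exclusion and the two fraction cutoffs are
*strict* (a variant at INFO exactly 0.4, a sample at LQV exactly 0.40, and
a variant flagged in exactly 30% of samples are all retained), while GP
retention is *inclusive* (max(GP) exactly 0.99 passes). The heterozygote
dosage pass interval [0.8, 1.01] is asymmetric; it is kept exactly as
published and both ends are configurable
(`gdi_config(ds_pass_het_range = )`).

Two readings of "fails the GP and DS thresholds" are possible, and both are
implemented via `flag_logic`: `"either"` (default) counts a genotype as low
quality when it fails at least one flag; `"both"` requires failing both.
`"either"` is the default because the flag breakdown is reported in
separate fail-GP / fail-DS / fail-both categories that jointly make up the
removed mass, and because GDI-filtered cohorts demonstrably retain
genotypes with GP < 0.99 — consistent only with variant-level removal under
the broader reading. LQV scores for outlier detection are computed on the
INFO-passing, MAF-restricted variant set (the variant set used is logged in
the result), and outlier samples are excluded from both numerator and
denominator of the step-5 fractions.

The 40% outlier cutoff is a fixed default rather than a distribution-derived
rule; `apply_gdi()` returns the full LQV table and `autoplot()` shows its
distribution so users can re-derive a cutoff suited to their cohort.
Likewise the 30% variant cutoff: `sweep_variant_cutoff()` tabulates kept
variants and residual mean LQV across cutoffs 10%…90% as the programmatic
substitute for choosing the cutoff by visual inspection of embeddings.

## Accuracy metrics

Against a truth set (array or high-coverage calls aligned by
chrom:pos:ref:alt key), `confusion_counts()` tabulates truth × imputed
genotype classes; masked or missing imputed genotypes accumulate into
per-truth-class missing counts rather than the grid, so filtering moves
mass from the grid into `n_missing` and sensitivities are computed over
observed genotypes (with the missing counts reported alongside, as in the
usual published table layout). Per genotype class, sensitivity is
TP/(TP+FN) and precision TP/(TP+FP). Non-reference concordance is

$$\mathrm{NRC} = 1 - \frac{E_{rr}+E_{ra}+E_{aa}}
{E_{rr}+E_{ra}+E_{aa}+M_{ra}+M_{aa}},$$

where $E$ are mismatch counts by truth class and $M$ the het and hom-alt
match counts; hom-ref matches are deliberately excluded so the easy
majority class cannot inflate concordance. Dosage r² is the squared Pearson
correlation between imputed dosages and truth dosage classes. Undefined
rates (empty denominators) are `NA`, never 0, so averaging across samples
skips them.

Stratification uses the *panel* allele frequency, folded to MAF
(min(AF, 1−AF)), in left-closed bins [0.001, 0.01), [0.01, 0.05),
[0.05, 0.1), [0.1, 0.3), [0.3, 0.5] (top bin closed, plus an explicit
"<0.001" bucket). `stratified_metrics()` pools genotypes; for the
across-sample view (box plots, mean ± SD) `sample_het_sensitivity()`
returns one heterozygote sensitivity per sample per bin so averaging is
done across samples, not pooled — both views are emitted, labelled, since
per-bin correct-call totals differ between them.

## The simulator

`simulate_batches()` generates the full observable structure the filters
consume — truth genotypes, per-batch GP/DS/GT, per-batch INFO — without any
restricted data:

* Panel AF per variant from a configurable model (default uniform on
  [0.05, 0.95], i.e. the common-variant regime the filter targets);
  genotypes i.i.d. Hardy–Weinberg.
* Read depth per cell is Poisson. Per-sample depth varies lognormally
  (`coverage_rel_sd`, default 0.2, mean-preserving), mirroring the spread
  of real cohorts; this variation is what gives the LQV distribution its
  tail of genuinely low-coverage outlier samples.
* Each read reports the alternate allele with probability
  $(1-\mathrm{ff})\,\mu(g_m) + \mathrm{ff}\,\mu(g_f)$, where
  $\mu = (\varepsilon,\ 0.5,\ 1-\varepsilon)$ by genotype,
  $\varepsilon$ is the base-calling error (default 0.01), $g_m$ the
  maternal (truth) genotype and $g_f$ a fetal genotype formed from one
  uniformly chosen maternal allele plus one population allele drawn at the
  panel AF — the simplest model that reproduces the observed degradation of
  maternal genotype inference with rising fetal fraction.
* The caller computes $P(g \mid \mathrm{reads}) \propto
  \mathrm{Binom}(n_{alt}; n, \mu(g)) \cdot \mathrm{HWE}(g; AF)$,
  *ignoring* the fetal mixture — deliberately, since that model mismatch is
  exactly what produces contamination-driven miscalls in real
  maternal-plasma data. GT is the posterior argmax (ties to the
  lowest-index class), DS follows from GP, and each batch's INFO is
  recomputed from its own posteriors.

**What the simulator does not model.** Real imputation borrows information
across sites from a haplotype reference panel (linkage disequilibrium); the
simulator is strictly per-site. GDI itself operates purely on
post-imputation fields, so LD realism is unnecessary for exercising the
filters — but a raw per-site posterior at 0.15× would be far less
informative than real imputation output (at 0.15×, ~86% of cells have zero
reads and their posteriors would equal the prior). The
`imputation_gain` parameter therefore acts as an effective-depth
multiplier standing in for panel information: reads are drawn at
Poisson(coverage × gain × sample factor). The default gain of 60 was
calibrated once so that the default 0.15× cohort reproduces the reported
post-imputation landscape — per-sample max(GP) ≥ 0.99 removal mostly
within 20–50% (mean ≈ 0.28 in our calibration runs), pre-filter LQV scores
near 0.28, and batch INFO scores concentrated well above 0.4 — and is not
adjusted per analysis. Consequences for interpretation: passing tests show
that the *filters and metrics* behave correctly and directionally as in
real cohorts (coverage up → sensitivity up; fetal fraction up →
sensitivity down; GDI retains intact sites where per-sample GP filtering
cannot); they do not certify LD-dependent behaviour such as
MAF-dependent imputation accuracy profiles of a specific tool or panel.

Randomness: one master seed spawns fixed per-stage substreams
(truth / depth / reads), so each stage is independently reproducible and
two runs with the same seed are identical down to the emitted VCF text.

## Problem sizes used in the checks

The cohort-level checks run on a simulated cohort of 300 samples × 20,000
common variants in 3 batches at 0.15× (seed 7) — large enough that
per-variant failure fractions and per-bin sensitivities are stable, small
enough to run on a laptop in a few minutes. Monotonicity checks (coverage
grid 0.05–0.5×, fetal-fraction grid 0–0.3) use 10 replicate seeds of
40 × 1,200 cohorts each, sized so that ten-replicate means order strictly.
Oracle-equivalence checks use 200 random instances of at most 50 × 5 with
an independent brute-force implementation.

## Degenerate inputs and numerical conventions

GP triplets off unit sum by more than 1e-3 are renormalized with a warning;
a missing DS field is derived from GP; a missing GP field is fatal (every
filter needs it). Multiallelic records and indels are skipped and counted,
never split. Variants absent from the panel AF table cannot be
MAF-restricted and are dropped and counted before flagging; an absent AF
lookup is `NA`, never 0. Phasing is ignored throughout. If every sample
exceeds the LQV cutoff, `apply_gdi()` aborts rather than returning an
empty cohort. All variant identity is the full chrom:pos:ref:alt tuple in
1-based VCF coordinates.

## Limitations

* The simulator validates mechanism, not tool-specific accuracy (no LD,
  no panel; see above).
* The simulated caller's hard call is always the posterior argmax, so its
  DS is never inconsistent with GT unless GP is also weak: on synthetic
  data the pure fail-DS category is empty and DS failures appear only as
  fail-both. Real imputation tools do emit occasional GT/GP conflicts —
  the very artifact the DS flag exists to catch — so on real data the
  fail-DS category is populated.
* GDI thresholds were designed for ~0.15× cohorts; higher-coverage data
  will likely want re-tuned DS/GP cutoffs (the config exposes all of them).
* Relatedness/duplicate removal, fetal-fraction estimation from reads, and
  embedding-based cutoff choice are out of scope; the sweep table is the
  programmatic stand-in for the latter.
* Aggressive variant filtering preferentially removes heterozygous sites
  (they are the hardest to impute), so overly strict settings can depress
  cohort heterozygosity.
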