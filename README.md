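# gdiqc — batch-level QC for genotypes imputed from low-pass sequencing

Genotype imputation from ultra-low-coverage sequencing (0.05–0.3×, e.g.
cell-free DNA from noninvasive prenatal screening) produces, per variant
and sample, a posterior genotype-probability triplet (GP), an expected
alternate-allele dosage (DS = p(het) + 2·p(hom-alt)) and a hard call (GT).
The conventional per-sample filter — set every genotype with
max(GP) < 0.99 to missing — works on single genomes but collapses in
pooled cohorts: every sample masks a different 20–50% of sites, so almost
no site stays intact across hundreds of samples (*cumulative
missingness*).

`gdiqc` implements the **GDI** batch-level strategy, which removes whole
variants and whole samples but never masks individual genotypes:

1. exclude variants with INFO score < 0.4 in **every** imputation batch
   (the INFO score is the IMPUTE/STITCH-style ratio of observed to
   expected dosage variance, INFO = 1 − Σᵢ(fᵢ − eᵢ²) / (2Nθ̂(1−θ̂)) with
   eᵢ = pᵢ(het) + 2pᵢ(hom-alt), fᵢ = pᵢ(het) + 4pᵢ(hom-alt));
2. restrict to panel variants with MAF ≥ 5%;
3. flag genotypes failing max(GP) ≥ 0.99 and/or the dosage consistency
   ranges (hom-ref: DS ≤ 0.1; hom-alt: DS ≥ 1.8; het: DS ∈ [0.8, 1.01]);
   a sample's **LQV score** is its flagged fraction;
4. drop outlier samples (LQV > 40%);
5. drop variants flagged in > 30% of the retained samples.

The package also provides the per-sample max(GP) filter for comparison,
cumulative-missingness accounting, accuracy metrics against truth
genotypes — per-class sensitivity and precision, non-reference concordance
NRC = 1 − (Err+Era+Eaa)/(Err+Era+Eaa+Mra+Maa), dosage r² — stratified by
panel-MAF bin, and a synthetic low-pass cohort simulator (Hardy–Weinberg
truth, Poisson depth, base-calling error, maternal-plasma fetal-fraction
contamination) so everything is testable without restricted data.

## Worked example

Simulate a two-batch cohort at 0.15× and run the full filter:

```r
library(gdiqc)

cfg <- sim_config(n_samples = 60, n_variants = 1500, n_batches = 2,
                  seed = 42)
sim <- simulate_batches(cfg)      # batches + truth + panel AF table
res <- apply_gdi(sim$batches, sim$af)
res
#> <gdi_result>
#>   variants: 1500 in -> 1316 out (INFO: -0, no panel AF: -0, MAF: -0, fraction: -184)
#>   samples: 60 in -> 54 out (6 LQV outliers)
#>   mean LQV 0.236 -> 0.194
```

184 variants were low quality in more than 30% of retained samples; six
samples (the lowest-coverage ones) exceeded the 40% LQV cutoff. The mean
fraction of low-quality genotypes per sample drops from 0.236 to 0.194,
and `filtered_matrix(res)` contains **zero** missing genotypes, unlike a
per-sample GP filter. Accuracy against truth, by MAF bin:

```r
tab <- stratified_metrics(res$merged, sim$truth, sim$af,
                          regimes = list(raw = regime(),
                                         gdi = regime_from_gdi(res)))
subset(tab, class == "het" & maf_bin >= "[0.05,0.1)",
       c(regime, maf_bin, sensitivity, nrc, dosage_r2))
#>   regime    maf_bin sensitivity       nrc dosage_r2
#> 1    raw [0.05,0.1)   0.9480444 0.9803161 0.9899667
#> 2    raw  [0.1,0.3)   0.9551614 0.9660425 0.9751871
#> 3    raw  [0.3,0.5]   0.9595357 0.9594335 0.9546614
#> 4    gdi [0.05,0.1)   0.9492848 0.9805616 0.9901905
#> 5    gdi  [0.1,0.3)   0.9613862 0.9710523 0.9784270
#> 6    gdi  [0.3,0.5]   0.9660183 0.9670352 0.9620450
```

Heterozygote sensitivity, NRC and dosage r² improve in every common-MAF
bin after GDI filtering while keeping 88% of the variants fully intact.
`glance(res)` gives the one-row summary, `tidy(res)` the per-variant
account, `autoplot(res)` the LQV distribution, and
`sweep_variant_cutoff()` the retention/quality trade-off across step-5
cutoffs. Real data enter through `read_imputed_vcf()` /
`read_truth_vcf()` / `read_af_table()`; `exec/gdi` exposes the same
workflow as a command-line tool (`gdi simulate`, `gdi run`, `gdi gp99`,
`gdi sweep`, `gdi missingness`, `gdi metrics`, `gdi benchmark`).

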