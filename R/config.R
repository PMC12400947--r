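#' GDI filter configuration
#'
#' Bundles every threshold of the GDI strategy. The defaults are the
#' published operating point for ~0.15x cohorts imputed in batches:
#'
#' * `info_min = 0.4`: variants with INFO `< 0.4` in **all** batches are
#'   excluded (strict inequality: a score of exactly 0.4 is retained).
#' * `gp_min = 0.99`: a genotype fails the GP flag when `max(GP) < 0.99`
#'   (so exactly 0.99 passes).
#' * DS pass ranges per called genotype: hom-ref passes when `ds <= 0.1`,
#'   hom-alt when `ds >= 1.8`, het when `ds` lies in `[0.8, 1.01]`. The
#'   asymmetric het upper bound is kept as published; both ends are
#'   configurable.
#' * `flag_logic = "either"`: a genotype counts as low quality when it fails
#'   the GP flag *or* the DS flag; `"both"` requires failing both.
#' * `lqv_outlier_max = 0.40`: samples whose low-quality-variant fraction
#'   strictly exceeds 40% are outliers.
#' * `variant_fail_max = 0.30`: variants flagged in strictly more than 30%
#'   of retained samples are excluded.
#' * `maf_min = 0.05`: flags are computed only for panel variants with
#'   minor-allele frequency at or above 5%.
#'
#' @param info_min,gp_min,ds_pass_homref_max,ds_pass_homalt_min Numeric
#'   thresholds, see above.
#' @param ds_pass_het_range Closed pass interval for het dosages.
#' @param flag_logic `"either"` or `"both"`.
#' @param lqv_outlier_max,variant_fail_max,maf_min Numeric thresholds.
#' @param info_source `"recompute"` (INFO derived from GP posteriors) or
#'   `"tag"` (use the per-variant score carried in the VCF INFO column).
#' @return A list of class `gdi_config`.
#' @export
gdi_config <- function(info_min = 0.4, gp_min = 0.99,
                       ds_pass_homref_max = 0.1, ds_pass_homalt_min = 1.8,
                       ds_pass_het_range = c(0.8, 1.01),
                       flag_logic = c("either", "both"),
                       lqv_outlier_max = 0.40, variant_fail_max = 0.30,
                       maf_min = 0.05,
                       info_source = c("recompute", "tag")) {
  flag_logic <- match.arg(flag_logic)
  info_source <- match.arg(info_source)
  chk01 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(paste0("'", name, "' must be a single value in [0, 1]"))
    }
    x
  }
  chk02 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 2) {
      abort(paste0("'", name, "' must be a single value in [0, 2]"))
    }
    x
  }
  if (length(ds_pass_het_range) != 2 ||
      ds_pass_het_range[1] > ds_pass_het_range[2]) {
    abort("'ds_pass_het_range' must be a non-empty interval c(lo, hi)")
  }
  cfg <- list(
    info_min = chk01(info_min, "info_min"),
    gp_min = chk01(gp_min, "gp_min"),
    ds_pass_homref_max = chk02(ds_pass_homref_max, "ds_pass_homref_max"),
    ds_pass_homalt_min = chk02(ds_pass_homalt_min, "ds_pass_homalt_min"),
    ds_pass_het_range = c(chk02(ds_pass_het_range[1], "ds_pass_het_range"),
                          chk02(ds_pass_het_range[2], "ds_pass_het_range")),
    flag_logic = flag_logic,
    lqv_outlier_max = chk01(lqv_outlier_max, "lqv_outlier_max"),
    variant_fail_max = chk01(variant_fail_max, "variant_fail_max"),
    maf_min = chk01(maf_min, "maf_min"),
    info_source = info_source
  )
  structure(cfg, class = "gdi_config")
}

#' @export
print.gdi_config <- function(x, ...) {
  cat("<gdi_config>\n")
  cat(sprintf("  INFO < %.2f in all batches excluded; flags: max(GP) < %.2f,\n",
              x$info_min, x$gp_min))
  cat(sprintf("  DS pass: hom-ref <= %.2f, hom-alt >= %.2f, het in [%.2f, %.2f]\n",
              x$ds_pass_homref_max, x$ds_pass_homalt_min,
              x$ds_pass_het_range[1], x$ds_pass_het_range[2]))
  cat(sprintf("  flag logic %s; LQV outlier > %.2f; variant fail > %.2f; MAF >= %.2f\n",
              x$flag_logic, x$lqv_outlier_max, x$variant_fail_max, x$maf_min))
  invisible(x)
}

#' Allele-frequency models for the simulator
#'
#' @param lo,hi Bounds of the uniform AF model.
#' @return A list of class `af_model`.
#' @export
af_uniform <- function(lo = 0.05, hi = 0.95) {
  if (lo < 0 || hi > 1 || lo > hi) abort("uniform AF bounds must satisfy 0 <= lo <= hi <= 1")
  if (lo == 0 && hi == 0) abort("degenerate AF model: all mass at 0")
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "af_model")
}

#' @rdname af_uniform
#' @param a,b Shape parameters of the beta AF model.
#' @export
af_beta <- function(a = 0.8, b = 0.8) {
  if (a <= 0 || b <= 0) abort("beta AF shapes must be positive")
  structure(list(kind = "beta", a = a, b = b), class = "af_model")
}

#' @rdname af_uniform
#' @param af Fixed vector of allele frequencies (recycled over variants).
#' @export
af_fixed <- function(af) {
  if (length(af) == 0 || anyNA(af) || any(af < 0 | af > 1)) {
    abort("fixed AF values must lie in [0, 1]")
  }
  if (all(af == 0)) abort("degenerate AF model: all mass at 0")
  structure(list(kind = "fixed", af = as.numeric(af)), class = "af_model")
}

draw_af <- function(model, n) {
  switch(model$kind,
    uniform = runif(n, model$lo, model$hi),
    beta = rbeta(n, model$a, model$b),
    fixed = rep_len(model$af, n),
    abort("unknown AF model")
  )
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: sample and variant counts, the panel
#' allele-frequency model, sequencing depth, base-calling error, and the
#' maternal-plasma fetal-fraction mixture. Defaults reproduce the study
#' regime this package targets: batches of a large NIPS-style cohort
#' sequenced at ~0.15x mean autosomal depth, restricted to common panel
#' variants.
#'
#' `coverage` is raw sequencing depth. `imputation_gain` is the
#' effective-depth multiplier standing in for the information that
#' haplotype-panel imputation borrows across sites (the simulator models no
#' linkage disequilibrium itself): each cell's read count is drawn at
#' `Poisson(coverage * imputation_gain * sample_factor)`. The default gain
#' of 60 is calibrated so that at 0.15x the simulated cohort reproduces the
#' observed post-imputation landscape: per-sample max(GP) >= 0.99 removal
#' mostly within 20-50% with mean near 30%, pre-filter LQV scores near 0.28, and batch INFO scores concentrated
#' well above 0.4. `coverage_rel_sd` adds lognormal per-sample depth
#' variation (mean-preserving), matching the roughly 0.09-0.3x spread seen across
#' real samples; it is what gives low-coverage samples their high LQV
#' scores.
#'
#' @param n_samples,n_variants Cohort dimensions.
#' @param af_model An [af_uniform()], [af_beta()] or [af_fixed()] model.
#' @param coverage Mean sequencing depth per site (x).
#' @param base_error Per-read probability of reading the wrong allele.
#' @param fetal_fraction Proportion of plasma reads of fetal origin, in
#'   `[0, 0.5]`.
#' @param n_batches Number of imputation batches the samples are split into.
#' @param imputation_gain Effective-depth multiplier (see Details).
#' @param coverage_rel_sd Relative SD of per-sample depth (lognormal; 0
#'   disables).
#' @param seed Master seed; stage substreams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_variants = 20000,
                       af_model = af_uniform(0.05, 0.95),
                       coverage = 0.15, base_error = 0.01,
                       fetal_fraction = 0, n_batches = 3,
                       imputation_gain = 60, coverage_rel_sd = 0.2,
                       seed = 1) {
  if (n_samples < 1 || n_variants < 1) {
    abort("n_samples and n_variants must be >= 1")
  }
  if (!inherits(af_model, "af_model")) abort("af_model must be an af_model")
  if (coverage < 0) abort("coverage must be >= 0")
  if (base_error < 0 || base_error >= 0.5) {
    abort("base_error must lie in [0, 0.5)")
  }
  if (fetal_fraction < 0 || fetal_fraction > 0.5) {
    abort("fetal_fraction must lie in [0, 0.5]")
  }
  if (n_batches < 1) abort("n_batches must be >= 1")
  if (n_samples < n_batches) abort("n_samples must be >= n_batches")
  if (imputation_gain <= 0) abort("imputation_gain must be positive")
  if (coverage_rel_sd < 0) abort("coverage_rel_sd must be >= 0")
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants), af_model = af_model,
         coverage = coverage, base_error = base_error,
         fetal_fraction = fetal_fraction, n_batches = as.integer(n_batches),
         imputation_gain = imputation_gain,
         coverage_rel_sd = coverage_rel_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d samples x %d variants in %d batch(es); %.2fx (+/- %.0f%%), gain %g,\n  base error %.3f, fetal fraction %.2f, seed %d\n",
    x$n_samples, x$n_variants, x$n_batches, x$coverage,
    100 * x$coverage_rel_sd, x$imputation_gain, x$base_error,
    x$fetal_fraction, x$seed))
  invisible(x)
}

#' Build configurations from raw key=value pairs
#'
#' Parses a flat named list (e.g. from a config file or command-line flags)
#' into a [gdi_config()] and a [sim_config()]. Unknown keys and out-of-range
#' values are fatal, naming the offending field; every deviation from the
#' defaults is reported via `message()`.
#'
#' @param raw Named list or named character vector of settings. Keys match
#'   the argument names of [gdi_config()] and [sim_config()] (plus
#'   `af_lo`/`af_hi` for the uniform AF model).
#' @return A list with elements `gdi` and `sim`.
#' @export
validate_config <- function(raw = list()) {
  raw <- as.list(raw)
  num_keys <- c("info_min", "gp_min", "ds_pass_homref_max",
                "ds_pass_homalt_min", "ds_pass_het_lo", "ds_pass_het_hi",
                "lqv_outlier_max", "variant_fail_max", "maf_min",
                "n_samples", "n_variants", "coverage", "base_error",
                "fetal_fraction", "n_batches", "imputation_gain",
                "coverage_rel_sd", "seed", "af_lo", "af_hi")
  chr_keys <- c("flag_logic", "info_source")
  unknown <- setdiff(names(raw), c(num_keys, chr_keys))
  if (length(unknown) > 0) {
    abort(paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  }
  val <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    if (key %in% num_keys) {
      x <- suppressWarnings(as.numeric(raw[[key]]))
      if (is.na(x)) abort(paste0("configuration key '", key, "' is not numeric"))
    } else {
      x <- as.character(raw[[key]])
    }
    message(sprintf("config: %s = %s", key, format(x)))
    x
  }
  gdi <- gdi_config(
    info_min = val("info_min", 0.4),
    gp_min = val("gp_min", 0.99),
    ds_pass_homref_max = val("ds_pass_homref_max", 0.1),
    ds_pass_homalt_min = val("ds_pass_homalt_min", 1.8),
    ds_pass_het_range = c(val("ds_pass_het_lo", 0.8),
                          val("ds_pass_het_hi", 1.01)),
    flag_logic = val("flag_logic", "either"),
    lqv_outlier_max = val("lqv_outlier_max", 0.40),
    variant_fail_max = val("variant_fail_max", 0.30),
    maf_min = val("maf_min", 0.05),
    info_source = val("info_source", "recompute")
  )
  sim <- sim_config(
    n_samples = val("n_samples", 300),
    n_variants = val("n_variants", 20000),
    af_model = af_uniform(val("af_lo", 0.05), val("af_hi", 0.95)),
    coverage = val("coverage", 0.15),
    base_error = val("base_error", 0.01),
    fetal_fraction = val("fetal_fraction", 0),
    n_batches = val("n_batches", 3),
    imputation_gain = val("imputation_gain", 60),
    coverage_rel_sd = val("coverage_rel_sd", 0.2),
    seed = val("seed", 1)
  )
  list(gdi = gdi, sim = sim)
}
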