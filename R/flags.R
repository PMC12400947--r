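FLAG_LEVELS <- c("pass", "fail_gp", "fail_ds", "fail_both")

# vectorized flag core over parallel vectors/matrices; returns integer codes
# 0 pass / 1 fail_gp / 2 fail_ds / 3 fail_both, NA where gt is NA
flag_codes <- function(gt, gpmax, ds, cfg) {
  gp_fail <- gpmax < cfg$gp_min
  ds_fail <- (gt == 0L & ds > cfg$ds_pass_homref_max) |
    (gt == 2L & ds < cfg$ds_pass_homalt_min) |
    (gt == 1L & (ds < cfg$ds_pass_het_range[1] |
                   ds > cfg$ds_pass_het_range[2]))
  out <- gp_fail + 2L * ds_fail
  storage.mode(out) <- "integer"
  out
}

is_lowq <- function(codes, flag_logic) {
  if (flag_logic == "both") codes == 3L else codes > 0L
}

#' Flag a genotype against the GP/DS consistency thresholds
#'
#' A called genotype fails the GP flag when its maximum posterior falls
#' below `gp_min`, and fails the DS flag when the dosage is inconsistent
#' with the call: `ds > 0.1` for hom-ref, `ds < 1.8` for hom-alt, or `ds`
#' outside `[0.8, 1.01]` for het (defaults). The two flags are reported
#' separately; how they combine into "low quality" is governed by
#' `flag_logic` (see [gdi_config()]).
#'
#' @param gt Genotype class: 0/1/2 or `"hom_ref"`/`"het"`/`"hom_alt"`
#'   (vectorized). Missing genotypes are an error; exclude them first.
#' @param gp Posterior triplet: a length-3 vector, or an n x 3 matrix for
#'   vectorized use. The maximum over the triplet is compared with `gp_min`
#'   (ties in the call's argmax are irrelevant here).
#' @param ds Dosage value(s) in `[0, 2]`.
#' @param config A [gdi_config()].
#' @return A factor with levels `pass`, `fail_gp`, `fail_ds`, `fail_both`.
#' @examples
#' flag_genotype("hom_ref", c(0.995, 0.005, 0), ds = 0.05)  # pass
#' flag_genotype("hom_ref", c(0.995, 0.005, 0), ds = 0.2)   # fail_ds
#' @export
flag_genotype <- function(gt, gp, ds, config = gdi_config()) {
  if (anyNA(gt)) abort("missing genotypes cannot be flagged; exclude them first")
  gt <- gt_class_code(gt)
  if (is.matrix(gp)) {
    gpmax <- apply(gp, 1, max)
  } else {
    if (length(gp) != 3) abort("gp must be a triplet or an n x 3 matrix")
    gpmax <- max(gp)
  }
  codes <- flag_codes(gt, gpmax, ds, config)
  factor(FLAG_LEVELS[codes + 1L], levels = FLAG_LEVELS)
}

#' Build the GDI flag matrix and per-sample LQV scores
#'
#' Flags every called genotype of the variants that survive the cross-batch
#' INFO exclusion and the panel minor-allele-frequency restriction, then
#' computes each sample's LQV score: the proportion of its flagged variants
#' that are low quality under the configured flag logic. Variants absent
#' from the panel AF table cannot be MAF-restricted and are dropped (and
#' counted) before flagging.
#'
#' @param x A merged [imputed_matrix()] (see [merge_batches()]).
#' @param info_excluded Character vector of variant keys excluded by
#'   [variants_failing_all_batches()].
#' @param af AF table from [read_af_table()] (columns `key`, `af`).
#' @param config A [gdi_config()].
#' @return An object of class `flag_matrix`: the integer flag grid
#'   (`flags`), the flagged `variants` tibble (with `af`, `maf` columns),
#'   `samples`, a per-sample `lqv` tibble, drop counters, and the config.
#' @export
build_flag_matrix <- function(x, info_excluded = character(), af,
                              config = gdi_config()) {
  keys <- x$variants$key
  in_info <- !(keys %in% info_excluded)
  af_vals <- af_lookup(af, keys)
  has_af <- !is.na(af_vals)
  maf <- pmin(af_vals, 1 - af_vals)
  maf_ok <- has_af & maf >= config$maf_min
  keep <- in_info & maf_ok
  n_no_af <- sum(in_info & !has_af)
  n_below_maf <- sum(in_info & has_af & maf < config$maf_min)
  if (!any(keep)) abort("no variants left to flag after INFO/MAF restriction")

  sub <- subset_genotypes(x, keys = keys[keep])
  codes <- flag_codes(sub$gt, gp_max(sub), sub$ds, config)
  dimnames(codes) <- list(sub$variants$key, sub$samples)
  lowq <- is_lowq(codes, config$flag_logic)
  n_eval <- unname(colSums(!is.na(codes)))
  n_lowq <- unname(colSums(lowq, na.rm = TRUE))
  lqv <- tibble::tibble(
    sample = sub$samples, n_eval = n_eval, n_lowq = n_lowq,
    lqv = ifelse(n_eval > 0, n_lowq / n_eval, NA_real_)
  )
  variants <- sub$variants
  variants$af <- af_vals[keep]
  variants$maf <- maf[keep]
  structure(
    list(flags = codes, variants = variants, samples = sub$samples,
         lqv = lqv, config = config,
         n_info_excluded = sum(!in_info),
         n_no_af = n_no_af, n_below_maf = n_below_maf),
    class = "flag_matrix"
  )
}

#' @export
print.flag_matrix <- function(x, ...) {
  cat("<flag_matrix>", nrow(x$flags), "variants x", ncol(x$flags),
      "samples (flag logic:", x$config$flag_logic, ")\n")
  tal <- flag_tally(x)
  cat(" ", paste(names(tal), tal, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Tally of flag outcomes over a flag matrix
#'
#' @param fm A `flag_matrix`.
#' @return Named integer vector over `pass`, `fail_gp`, `fail_ds`,
#'   `fail_both` plus `missing`; the tallies sum to the grid size.
#' @export
flag_tally <- function(fm) {
  counts <- tabulate(fm$flags + 1L, nbins = 4L)
  c(setNames(counts, FLAG_LEVELS), missing = sum(is.na(fm$flags)))
}

#' Low-quality-variant (LQV) score of a sample
#'
#' The proportion of a sample's flagged variants whose genotype is low
#' quality: under `flag_logic = "either"` any of `fail_gp`, `fail_ds`,
#' `fail_both` counts; under `"both"` only `fail_both` does. Missing flags
#' (genotype absent in that sample) are excluded from both numerator and
#' denominator.
#'
#' @param flags A factor/character vector of flag outcomes (levels of
#'   [flag_genotype()]) or integer codes from a `flag_matrix` column.
#' @param config A [gdi_config()] (only `flag_logic` is used).
#' @return The LQV score in `[0, 1]`.
#' @examples
#' compute_lqv(c(rep("pass", 87), rep("fail_gp", 13)))  # 0.13
#' @export
compute_lqv <- function(flags, config = gdi_config()) {
  if (is.factor(flags) || is.character(flags)) {
    codes <- match(as.character(flags), FLAG_LEVELS) - 1L
    if (any(is.na(codes) & !is.na(flags))) abort("unknown flag outcome")
  } else {
    codes <- as.integer(flags)
  }
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) abort("no flagged genotypes to score")
  mean(is_lowq(codes, config$flag_logic))
}

#' Samples whose LQV score marks them as outliers
#'
#' Outliers are samples whose LQV score strictly exceeds
#' `lqv_outlier_max` (a score of exactly the cutoff is kept).
#'
#' @param fm A `flag_matrix` from [build_flag_matrix()].
#' @param config A [gdi_config()].
#' @return Character vector of outlier sample ids.
#' @export
detect_outlier_samples <- function(fm, config = fm$config) {
  fm$lqv$sample[!is.na(fm$lqv$lqv) & fm$lqv$lqv > config$lqv_outlier_max]
}

#' Per-variant low-quality fractions among retained samples
#'
#' For each flagged variant, the fraction of retained (non-outlier) samples
#' whose genotype is low quality. Outlier samples are excluded from both
#' numerator and denominator, as are missing genotypes.
#'
#' @param fm A `flag_matrix`.
#' @param retained_samples Character vector of samples to evaluate (must be
#'   a non-empty subset of the matrix samples).
#' @return A tibble with one row per variant: `key`, `maf`, `n_lowq`,
#'   `n_eval`, `fail_fraction`.
#' @export
variant_failure_fractions <- function(fm, retained_samples = fm$samples) {
  if (length(retained_samples) == 0) abort("retained sample set is empty")
  j <- match(retained_samples, fm$samples)
  if (anyNA(j)) abort("retained_samples must be a subset of the flag matrix samples")
  sub <- fm$flags[, j, drop = FALSE]
  lowq <- is_lowq(sub, fm$config$flag_logic)
  n_eval <- unname(rowSums(!is.na(sub)))
  n_lowq <- unname(rowSums(lowq, na.rm = TRUE))
  tibble::tibble(
    key = fm$variants$key, maf = fm$variants$maf,
    n_lowq = n_lowq, n_eval = n_eval,
    fail_fraction = ifelse(n_eval > 0, n_lowq / n_eval, NA_real_)
  )
}

#' Sweep the variant-removal cutoff
#'
#' Re-applies the variant-fraction exclusion over a grid of cutoffs
#' (by default removing variants low quality in more than 10%, 20%, ...,
#' 90% of samples) and reports, per cutoff, the number of variants kept and
#' the mean per-sample LQV recomputed on the kept variants. This is the
#' programmatic substitute for choosing the cutoff by visual inspection of
#' embeddings: it shows the trade-off between variant loss and residual
#' low-quality mass.
#'
#' @param fm A `flag_matrix`.
#' @param retained_samples Samples over which fractions and LQV are
#'   computed (outliers already removed).
#' @param grid Cutoff grid, values in (0, 1].
#' @return A tibble with columns `cutoff`, `n_variants_kept`, `mean_lqv`.
#'   Kept counts are non-decreasing in the cutoff.
#' @export
sweep_variant_cutoff <- function(fm, retained_samples = fm$samples,
                                 grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0) abort("empty cutoff grid")
  if (any(grid <= 0 | grid > 1)) abort("cutoffs must lie in (0, 1]")
  fr <- variant_failure_fractions(fm, retained_samples)
  j <- match(retained_samples, fm$samples)
  lowq <- is_lowq(fm$flags[, j, drop = FALSE], fm$config$flag_logic)
  evald <- !is.na(fm$flags[, j, drop = FALSE])
  purrr::map_dfr(sort(grid), function(cut) {
    keep <- !is.na(fr$fail_fraction) & fr$fail_fraction <= cut
    n_eval <- colSums(evald[keep, , drop = FALSE])
    n_lowq <- colSums(lowq[keep, , drop = FALSE], na.rm = TRUE)
    lqv <- ifelse(n_eval > 0, n_lowq / n_eval, NA_real_)
    tibble::tibble(cutoff = cut, n_variants_kept = sum(keep),
                   mean_lqv = mean(lqv, na.rm = TRUE))
  })
}
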