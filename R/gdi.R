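#' Apply the full GDI filter to a batched cohort
#'
#' Runs the complete batch-level filtering strategy in its published order:
#'
#' 1. exclude variants whose INFO score is below `info_min` in **every**
#'    batch where they were observed;
#' 2. restrict to panel variants with minor-allele frequency at or above
#'    `maf_min` (variants absent from the AF table are dropped and counted);
#' 3. flag each remaining genotype against the GP/DS thresholds and compute
#'    per-sample LQV scores;
#' 4. remove outlier samples (LQV strictly above `lqv_outlier_max`);
#' 5. exclude variants that are low quality in strictly more than
#'    `variant_fail_max` of the retained samples.
#'
#' GDI removes whole variants and whole samples only: retained genotypes are
#' never set to missing, which is what distinguishes it from the
#' individual-level max(GP) filter (see [apply_gp99()]) and avoids
#' cumulative missingness in batched cohorts.
#'
#' @param batches A list of [imputed_matrix()] objects, or one matrix.
#' @param af AF table from [read_af_table()].
#' @param config A [gdi_config()].
#' @return An object of class `gdi_result` holding the kept variant table,
#'   retained/outlier samples, LQV scores before and after filtering, the
#'   per-variant failure fractions, flag tallies, all exclusion counters and
#'   the merged input matrix. Use [tidy()] for the per-variant account,
#'   [glance()] for the one-row summary and [filtered_matrix()] to
#'   materialize the filtered genotypes.
#' @export
apply_gdi <- function(batches, af, config = gdi_config()) {
  if (inherits(batches, "imputed_matrix")) batches <- list(batches)
  if (length(batches) < 1) abort("at least one batch is required")
  info_tbl <- collect_batch_info(batches, source = config$info_source)
  excluded_info <- variants_failing_all_batches(info_tbl, config$info_min)
  merged <- merge_batches(batches, mode = "union")
  fm <- build_flag_matrix(merged, excluded_info, af, config)

  outliers <- detect_outlier_samples(fm, config)
  retained <- setdiff(fm$samples, outliers)
  if (length(retained) == 0) {
    abort("every sample exceeded the LQV outlier cutoff; nothing retained")
  }
  fractions <- variant_failure_fractions(fm, retained)
  excl_frac <- !is.na(fractions$fail_fraction) &
    fractions$fail_fraction > config$variant_fail_max
  kept_keys <- fractions$key[!excl_frac]

  kept_variants <- fm$variants[match(kept_keys, fm$variants$key), ]
  lqv_before <- dplyr::mutate(fm$lqv, outlier = .data$sample %in% outliers)
  kept_idx <- match(kept_keys, rownames(fm$flags))
  ret_idx <- match(retained, fm$samples)
  sub <- fm$flags[kept_idx, ret_idx, drop = FALSE]
  lowq <- is_lowq(sub, config$flag_logic)
  n_eval <- colSums(!is.na(sub))
  lqv_after <- tibble::tibble(
    sample = retained,
    lqv = ifelse(n_eval > 0, colSums(lowq, na.rm = TRUE) / n_eval, NA_real_)
  )
  report <- list(
    n_variants_in = nrow(merged$variants),
    n_excluded_info = fm$n_info_excluded,
    n_no_af = fm$n_no_af,
    n_below_maf = fm$n_below_maf,
    n_flagged_variants = nrow(fm$flags),
    n_outlier_samples = length(outliers),
    n_excluded_fraction = sum(excl_frac),
    n_variants_out = length(kept_keys),
    n_samples_in = length(fm$samples),
    n_samples_out = length(retained),
    mean_lqv_before = mean(fm$lqv$lqv, na.rm = TRUE),
    mean_lqv_after = mean(lqv_after$lqv, na.rm = TRUE),
    flag_tally = flag_tally(fm)
  )
  stopifnot(report$n_variants_out ==
              report$n_variants_in - report$n_excluded_info - report$n_no_af -
              report$n_below_maf - report$n_excluded_fraction)
  structure(
    list(kept_variants = kept_variants, retained_samples = retained,
         outlier_samples = outliers, excluded_info = excluded_info,
         excluded_fraction = fractions$key[excl_frac],
         lqv = lqv_before, lqv_after = lqv_after,
         variant_fail = fractions, flag_matrix = fm, merged = merged,
         info_table = info_tbl, config = config, report = report),
    class = "gdi_result"
  )
}

#' @export
print.gdi_result <- function(x, ...) {
  r <- x$report
  cat("<gdi_result>\n")
  cat(sprintf("  variants: %d in -> %d out (INFO: -%d, no panel AF: -%d, MAF: -%d, fraction: -%d)\n",
              r$n_variants_in, r$n_variants_out, r$n_excluded_info,
              r$n_no_af, r$n_below_maf, r$n_excluded_fraction))
  cat(sprintf("  samples: %d in -> %d out (%d LQV outliers)\n",
              r$n_samples_in, r$n_samples_out, r$n_outlier_samples))
  cat(sprintf("  mean LQV %.3f -> %.3f\n", r$mean_lqv_before, r$mean_lqv_after))
  invisible(x)
}

#' @method glance gdi_result
#' @export
glance.gdi_result <- function(x, ...) {
  r <- x$report
  tal <- r$flag_tally
  n_flag <- sum(tal[FLAG_LEVELS])
  tibble::tibble(
    n_variants_in = r$n_variants_in, n_excluded_info = r$n_excluded_info,
    n_no_af = r$n_no_af, n_below_maf = r$n_below_maf,
    n_excluded_fraction = r$n_excluded_fraction,
    n_variants_out = r$n_variants_out,
    n_samples_in = r$n_samples_in, n_outlier_samples = r$n_outlier_samples,
    n_samples_out = r$n_samples_out,
    mean_lqv_before = r$mean_lqv_before, mean_lqv_after = r$mean_lqv_after,
    frac_pass = tal[["pass"]] / n_flag,
    frac_fail_gp = tal[["fail_gp"]] / n_flag,
    frac_fail_ds = tal[["fail_ds"]] / n_flag,
    frac_fail_both = tal[["fail_both"]] / n_flag
  )
}

#' @method tidy gdi_result
#' @export
tidy.gdi_result <- function(x, ...) {
  keys <- x$merged$variants$key
  status <- rep("kept", length(keys))
  status[keys %in% x$excluded_fraction] <- "excluded_fraction"
  fm_keys <- x$flag_matrix$variants$key
  af_vals <- af_lookup(
    tibble::tibble(key = x$flag_matrix$variants$key,
                   af = x$flag_matrix$variants$af), keys)
  in_info <- !(keys %in% x$excluded_info)
  status[!in_info] <- "excluded_info"
  not_flagged <- in_info & !(keys %in% fm_keys)
  status[not_flagged] <- "dropped_maf_or_panel"
  out <- tibble::tibble(key = keys, status = status)
  dplyr::left_join(out,
                   x$variant_fail[, c("key", "fail_fraction")],
                   by = "key")
}

#' Materialize the GDI-filtered genotype matrix
#'
#' @param result A `gdi_result` from [apply_gdi()].
#' @return An [imputed_matrix()] restricted to the kept variants and
#'   retained samples. No genotype is masked: GDI removes whole
#'   variants/samples only.
#' @export
filtered_matrix <- function(result) {
  subset_genotypes(result$merged, keys = result$kept_variants$key,
                   samples = result$retained_samples)
}
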