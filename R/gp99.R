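#' Individual-level max(GP) filter
#'
#' The conventional per-sample filter: a genotype is kept when its maximum
#' posterior probability is at least `gp_min` (`max(GP) >= 0.99` by
#' default; the boundary value is retained) and set to missing otherwise.
#' Accurate on single genomes, but in batched cohorts the per-sample masks
#' accumulate and few, if any, sites remain intact across all samples —
#' the cumulative-missingness problem GDI is designed to avoid.
#'
#' @param x An [imputed_matrix()].
#' @param gp_min Retention threshold on `max(GP)`.
#' @return An object of class `gp99_filter`: the logical `mask` (`TRUE` =
#'   genotype removed), a `per_sample` tibble with the fraction of each
#'   sample's called genotypes removed, and `gp_min`.
#' @export
apply_gp99 <- function(x, gp_min = 0.99) {
  gpm <- gp_max(x)
  mask <- !is.na(x$gt) & gpm < gp_min
  n_called <- colSums(!is.na(x$gt))
  n_masked <- colSums(mask)
  per_sample <- tibble::tibble(
    sample = x$samples, n_called = n_called, n_masked = n_masked,
    fraction_removed = ifelse(n_called > 0, n_masked / n_called, NA_real_)
  )
  structure(list(mask = mask, per_sample = per_sample, gp_min = gp_min,
                 variants = x$variants$key),
            class = "gp99_filter")
}

#' @export
print.gp99_filter <- function(x, ...) {
  cat("<gp99_filter> max(GP) >=", x$gp_min, "\n")
  cat(sprintf("  %d genotypes masked; per-sample removal %.1f%% (median)\n",
              sum(x$mask), 100 * median(x$per_sample$fraction_removed,
                                        na.rm = TRUE)))
  invisible(x)
}

#' Cumulative missingness across a cohort
#'
#' Counts, for every variant, in how many samples its genotype is missing
#' (either absent on input or removed by a per-sample mask). A variant is
#' "intact" when no sample is missing — with individual-level GP filtering
#' the intact count collapses as the cohort grows, while GDI keeps every
#' retained site intact.
#'
#' @param x An [imputed_matrix()].
#' @param mask Optional `gp99_filter` or logical variants-x-samples matrix
#'   of genotypes to treat as missing.
#' @param keep_variants Optional character vector of variant keys to
#'   restrict the accounting to (e.g. the GDI-kept set, for a like-for-like
#'   comparison).
#' @return A tibble with one row per variant: `key`, `n_missing` (samples
#'   missing after masking), and `intact`.
#' @export
cumulative_missingness <- function(x, mask = NULL, keep_variants = NULL) {
  if (inherits(mask, "gp99_filter")) mask <- mask$mask
  miss <- is.na(x$gt)
  if (!is.null(mask)) {
    check_grid(mask, nrow(x$variants), length(x$samples), "mask")
    miss <- miss | mask
  }
  keys <- x$variants$key
  if (!is.null(keep_variants)) {
    i <- match(keep_variants, keys)
    if (anyNA(i)) abort("keep_variants contains keys absent from the matrix")
    miss <- miss[i, , drop = FALSE]
    keys <- keys[i]
  }
  n_missing <- rowSums(miss)
  tibble::tibble(key = keys, n_missing = n_missing, intact = n_missing == 0L)
}

#' Summary of a cumulative-missingness table
#'
#' @param miss A tibble from [cumulative_missingness()].
#' @param bins Breakpoints for the distribution of per-variant missing
#'   counts.
#' @return A one-row tibble: variant count, intact count and fraction, and
#'   the maximum per-variant missing count.
#' @export
missingness_summary <- function(miss, bins = NULL) {
  tibble::tibble(
    n_variants = nrow(miss),
    n_intact = sum(miss$intact),
    frac_intact = mean(miss$intact),
    max_missing = if (nrow(miss) > 0) max(miss$n_missing) else NA_integer_
  )
}
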