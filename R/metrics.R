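#' Genotype confusion counts against truth
#'
#' Cross-tabulates imputed genotype classes against truth classes over the
#' samples shared by both containers and the variants present in both
#' (optionally restricted to a subset and/or masked per cell). Masked cells
#' and imputed-missing genotypes accumulate into per-truth-class missing
#' counts, never into the 3x3 grid; truth-missing genotypes are counted
#' separately and take no further part.
#'
#' @param imputed An [imputed_matrix()].
#' @param truth A [truth_matrix()].
#' @param variant_subset Optional character vector of variant keys.
#' @param genotype_mask Optional `gp99_filter` or logical matrix aligned to
#'   `imputed` marking genotypes to treat as missing.
#' @param sample_subset Optional sample ids (intersected with the shared
#'   samples).
#' @return An object of class `confusion_counts`: the 3x3 `grid`
#'   (truth x imputed), `n_missing` per truth class, `n_truth_missing`, and
#'   the total number of compared cells.
#' @export
confusion_counts <- function(imputed, truth, variant_subset = NULL,
                             genotype_mask = NULL, sample_subset = NULL) {
  if (inherits(genotype_mask, "gp99_filter")) genotype_mask <- genotype_mask$mask
  samples <- intersect(imputed$samples, truth$samples)
  if (!is.null(sample_subset)) samples <- intersect(samples, sample_subset)
  if (length(samples) == 0) abort("no shared samples between imputed and truth")
  keys <- intersect(imputed$variants$key, truth$variants$key)
  if (!is.null(variant_subset)) keys <- intersect(keys, variant_subset)

  ri <- match(keys, imputed$variants$key)
  ci <- match(samples, imputed$samples)
  imp <- imputed$gt[ri, ci, drop = FALSE]
  if (!is.null(genotype_mask)) {
    check_grid(genotype_mask, nrow(imputed$variants),
               length(imputed$samples), "genotype_mask")
    imp[genotype_mask[ri, ci, drop = FALSE]] <- NA_integer_
  }
  tru <- truth$dosage[match(keys, truth$variants$key),
                      match(samples, truth$samples), drop = FALSE]
  new_confusion_counts_from_grids(imp, tru)
}

new_confusion_counts_from_grids <- function(imp, tru) {
  tf <- factor(as.vector(tru), levels = 0:2)
  impf <- factor(as.vector(imp), levels = 0:2)
  grid <- table(truth = tf, imputed = impf)
  grid <- matrix(as.integer(grid), 3, 3,
                 dimnames = list(truth = GT_CLASSES, imputed = GT_CLASSES))
  n_missing <- as.integer(table(tf[is.na(impf) & !is.na(tf)]))
  new_confusion_counts(grid, setNames(n_missing, GT_CLASSES),
                       n_truth_missing = sum(is.na(tf)))
}

#' Assemble confusion counts from raw tallies
#'
#' @param grid 3x3 integer matrix of counts, rows = truth class, columns =
#'   imputed class, both in (hom_ref, het, hom_alt) order.
#' @param n_missing Per-truth-class counts of missing/masked imputed
#'   genotypes.
#' @param n_truth_missing Count of cells with missing truth.
#' @return A `confusion_counts` object.
#' @export
new_confusion_counts <- function(grid, n_missing = c(0L, 0L, 0L),
                                 n_truth_missing = 0L) {
  grid <- matrix(as.integer(grid), 3, 3,
                 dimnames = list(truth = GT_CLASSES, imputed = GT_CLASSES))
  if (any(grid < 0) || any(n_missing < 0)) abort("counts must be non-negative")
  structure(
    list(grid = grid,
         n_missing = setNames(as.integer(n_missing), GT_CLASSES),
         n_truth_missing = as.integer(n_truth_missing),
         n_total = sum(grid) + sum(n_missing) + as.integer(n_truth_missing)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> (rows = truth, cols = imputed)\n")
  print(x$grid)
  cat("missing by truth class:", paste(x$n_missing, collapse = " "),
      "| truth missing:", x$n_truth_missing, "\n")
  invisible(x)
}

# mismatch/match aliases: Err/Era/Eaa are the mismatch counts at hom-ref,
# het and hom-alt truth; Mra/Maa the het and hom-alt matches
mismatch_counts <- function(cc) {
  g <- cc$grid
  list(
    err = sum(g["hom_ref", ]) - g["hom_ref", "hom_ref"],
    era = sum(g["het", ]) - g["het", "het"],
    eaa = sum(g["hom_alt", ]) - g["hom_alt", "hom_alt"],
    mra = g["het", "het"],
    maa = g["hom_alt", "hom_alt"]
  )
}

#' Per-class sensitivity
#'
#' `TP / (TP + FN)` for a genotype class: the diagonal count over the truth
#' row total (missing genotypes are excluded from the denominator; see
#' `n_missing` for their bookkeeping).
#'
#' @param counts A `confusion_counts` object.
#' @param cls Genotype class (0/1/2 or `"hom_ref"`/`"het"`/`"hom_alt"`).
#' @return A rate in `[0, 1]`, or `NA` when the class never occurs in truth.
#' @export
sensitivity <- function(counts, cls) {
  i <- gt_class_code(cls) + 1L
  denom <- sum(counts$grid[i, ])
  if (denom == 0) return(NA_real_)
  counts$grid[i, i] / denom
}

#' Per-class precision
#'
#' `TP / (TP + FP)`: the diagonal count over the imputed column total.
#'
#' @inheritParams sensitivity
#' @return A rate in `[0, 1]`, or `NA` when the class is never called.
#' @export
precision <- function(counts, cls) {
  i <- gt_class_code(cls) + 1L
  denom <- sum(counts$grid[, i])
  if (denom == 0) return(NA_real_)
  counts$grid[i, i] / denom
}

#' Non-reference concordance
#'
#' `NRC = 1 - (Err + Era + Eaa) / (Err + Era + Eaa + Mra + Maa)`: one minus
#' the mismatch fraction over mismatches plus het and hom-alt matches.
#' Hom-ref matches are deliberately absent from both numerator and
#' denominator, so concordance is not inflated by the easy majority class.
#'
#' @inheritParams sensitivity
#' @return A rate in `[0, 1]`, or `NA` when no counts enter the formula.
#' @export
nrc <- function(counts) {
  m <- mismatch_counts(counts)
  denom <- m$err + m$era + m$eaa + m$mra + m$maa
  if (denom == 0) return(NA_real_)
  1 - (m$err + m$era + m$eaa) / denom
}

#' Dosage r-squared
#'
#' Squared Pearson correlation between imputed dosages and truth dosage
#' classes, over pairs where both are observed.
#'
#' @param imputed_ds Numeric vector of dosages.
#' @param truth_dosage Vector of truth classes 0/1/2 (`NA` allowed; such
#'   pairs are dropped).
#' @return The squared correlation, or `NA` when fewer than two complete
#'   pairs remain or either side has zero variance.
#' @export
dosage_r2 <- function(imputed_ds, truth_dosage) {
  if (length(imputed_ds) != length(truth_dosage)) {
    abort("dosage vectors must have equal length")
  }
  ok <- !is.na(imputed_ds) & !is.na(truth_dosage)
  x <- imputed_ds[ok]
  y <- as.numeric(truth_dosage[ok])
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Minor-allele-frequency bins
#'
#' Folds panel alternate-allele frequencies to minor-allele frequencies
#' (`min(AF, 1 - AF)`) and assigns them to half-open, left-closed bins; the
#' top bin is closed at 0.5. The default bins are
#' `[0.001, 0.01) [0.01, 0.05) [0.05, 0.1) [0.1, 0.3) [0.3, 0.5]`, with an
#' extra `<0.001` bucket so nothing is silently dropped.
#'
#' @param af Panel alternate-allele frequencies in `[0, 1]` (`NA` allowed).
#' @param breaks Ascending bin boundaries.
#' @return An ordered factor of bin labels (`NA` for `NA` input).
#' @examples
#' maf_bin(c(0.93, 0.05, 0.0005))  # folds 0.93 -> 0.07 -> [0.05,0.1)
#' @export
maf_bin <- function(af, breaks = c(0.001, 0.01, 0.05, 0.1, 0.3, 0.5)) {
  if (is.unsorted(breaks, strictly = TRUE)) abort("breaks must be ascending")
  maf <- pmin(af, 1 - af)
  fmt <- vapply(breaks, format, character(1))
  labels <- c(
    paste0("<", fmt[1]),
    paste0("[", fmt[-length(fmt)], ",", fmt[-1], ")")
  )
  labels[length(labels)] <- sub("\\)$", "]", labels[length(labels)])
  idx <- findInterval(maf, breaks, rightmost.closed = TRUE) + 1L
  idx[!is.na(maf) & maf > breaks[length(breaks)]] <- NA_integer_
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Regime specification for metric stratification
#'
#' A filter regime is, for metric purposes, a keep-set of variants, a
#' keep-set of samples, and/or a per-genotype mask.
#'
#' @param keep_variants Optional character vector of variant keys.
#' @param keep_samples Optional character vector of sample ids.
#' @param mask Optional `gp99_filter` or logical matrix (aligned to the
#'   imputed matrix passed to [stratified_metrics()]).
#' @return A list of class `qc_regime`.
#' @export
regime <- function(keep_variants = NULL, keep_samples = NULL, mask = NULL) {
  if (inherits(mask, "gp99_filter")) mask <- mask$mask
  structure(list(keep_variants = keep_variants, keep_samples = keep_samples,
                 mask = mask), class = "qc_regime")
}

#' @rdname regime
#' @param result A `gdi_result` from [apply_gdi()].
#' @export
regime_from_gdi <- function(result) {
  regime(keep_variants = result$kept_variants$key,
         keep_samples = result$retained_samples)
}

#' @rdname regime
#' @param filter A `gp99_filter` from [apply_gp99()].
#' @export
regime_from_gp99 <- function(filter) regime(mask = filter$mask)

#' Accuracy metrics stratified by regime, MAF bin and genotype class
#'
#' For every filter regime and minor-allele-frequency bin, pools the
#' genotype confusion over all (retained) samples and reports per-class
#' sensitivity and precision together with the bin-level non-reference
#' concordance and dosage r-squared. Pooled counts; for the
#' across-sample view used for box plots and mean/SD summaries see
#' [sample_het_sensitivity()].
#'
#' @param imputed An [imputed_matrix()] (merged cohort).
#' @param truth A [truth_matrix()].
#' @param af AF table (columns `key`, `af`).
#' @param regimes Named list of [regime()] objects, e.g.
#'   `list(raw = regime(), gdi = regime_from_gdi(res))`.
#' @param breaks MAF bin boundaries (see [maf_bin()]).
#' @return A tibble with one row per (regime, maf_bin, class): `n_truth`,
#'   `n_correct`, `n_missing`, `sensitivity`, `precision`, and the
#'   bin-level `nrc` and `dosage_r2` repeated across the bin's class rows.
#'   Undefined rates are `NA`, never 0.
#' @export
stratified_metrics <- function(imputed, truth, af,
                               regimes = list(raw = regime()),
                               breaks = c(0.001, 0.01, 0.05, 0.1, 0.3, 0.5)) {
  af_all <- af_lookup(af, imputed$variants$key)
  bins <- maf_bin(af_all, breaks)
  purrr::imap_dfr(regimes, function(rg, rg_name) {
    keys <- imputed$variants$key
    if (!is.null(rg$keep_variants)) keys <- intersect(keys, rg$keep_variants)
    bin_of <- bins[match(keys, imputed$variants$key)]
    purrr::map_dfr(levels(bins), function(bl) {
      bk <- keys[!is.na(bin_of) & bin_of == bl]
      if (length(bk) == 0) {
        return(tibble::tibble(
          regime = rg_name, maf_bin = factor(bl, levels = levels(bins), ordered = TRUE), class = GT_CLASSES,
          n_truth = 0L, n_correct = 0L, n_missing = 0L,
          sensitivity = NA_real_, precision = NA_real_,
          nrc = NA_real_, dosage_r2 = NA_real_
        ))
      }
      cc <- confusion_counts(imputed, truth, variant_subset = bk,
                             genotype_mask = rg$mask,
                             sample_subset = rg$keep_samples)
      r2 <- regime_dosage_r2(imputed, truth, bk, rg)
      tibble::tibble(
        regime = rg_name, maf_bin = factor(bl, levels = levels(bins), ordered = TRUE), class = GT_CLASSES,
        n_truth = as.integer(rowSums(cc$grid) + cc$n_missing),
        n_correct = diag(cc$grid),
        n_missing = as.integer(cc$n_missing),
        sensitivity = vapply(GT_CLASSES, function(cl) sensitivity(cc, cl), 1),
        precision = vapply(GT_CLASSES, function(cl) precision(cc, cl), 1),
        nrc = nrc(cc), dosage_r2 = r2
      )
    })
  })
}

regime_dosage_r2 <- function(imputed, truth, keys, rg) {
  samples <- intersect(imputed$samples, truth$samples)
  if (!is.null(rg$keep_samples)) samples <- intersect(samples, rg$keep_samples)
  keys <- intersect(keys, truth$variants$key)
  if (length(keys) == 0 || length(samples) == 0) return(NA_real_)
  ri <- match(keys, imputed$variants$key)
  ci <- match(samples, imputed$samples)
  ds <- imputed$ds[ri, ci, drop = FALSE]
  if (!is.null(rg$mask)) ds[rg$mask[ri, ci, drop = FALSE]] <- NA_real_
  tru <- truth$dosage[match(keys, truth$variants$key),
                      match(samples, truth$samples), drop = FALSE]
  dosage_r2(as.vector(ds), as.vector(tru))
}

#' Per-sample heterozygous sensitivity
#'
#' Heterozygote sensitivity computed separately for every sample (the
#' quantity behind per-MAF-bin box plots and mean ± SD error bars, where
#' averaging happens across samples, not pooled genotypes).
#'
#' @inheritParams stratified_metrics
#' @return A tibble with one row per (regime, maf_bin, sample): `n_truth_het`
#'   and `sensitivity` (`NA` when the sample has no het truth genotypes in
#'   the bin).
#' @export
sample_het_sensitivity <- function(imputed, truth, af,
                                   regimes = list(raw = regime()),
                                   breaks = c(0.001, 0.01, 0.05, 0.1, 0.3,
                                              0.5)) {
  af_all <- af_lookup(af, imputed$variants$key)
  bins <- maf_bin(af_all, breaks)
  shared <- intersect(imputed$samples, truth$samples)
  purrr::imap_dfr(regimes, function(rg, rg_name) {
    samples <- shared
    if (!is.null(rg$keep_samples)) samples <- intersect(samples, rg$keep_samples)
    keys <- intersect(imputed$variants$key, truth$variants$key)
    if (!is.null(rg$keep_variants)) keys <- intersect(keys, rg$keep_variants)
    ri <- match(keys, imputed$variants$key)
    ci <- match(samples, imputed$samples)
    imp <- imputed$gt[ri, ci, drop = FALSE]
    if (!is.null(rg$mask)) imp[rg$mask[ri, ci, drop = FALSE]] <- NA_integer_
    tru <- truth$dosage[match(keys, truth$variants$key),
                        match(samples, truth$samples), drop = FALSE]
    bin_of <- bins[ri]
    purrr::map_dfr(levels(bins), function(bl) {
      rows <- !is.na(bin_of) & bin_of == bl
      tru_b <- tru[rows, , drop = FALSE]
      imp_b <- imp[rows, , drop = FALSE]
      het <- !is.na(tru_b) & tru_b == 1L
      observed <- het & !is.na(imp_b)
      correct <- observed & imp_b == 1L
      n_obs <- colSums(observed)
      tibble::tibble(
        regime = rg_name, maf_bin = factor(bl, levels = levels(bins), ordered = TRUE), sample = samples,
        n_truth_het = colSums(het),
        n_missing_het = colSums(het) - n_obs,
        sensitivity = ifelse(n_obs > 0, colSums(correct) / n_obs, NA_real_)
      )
    })
  })
}
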