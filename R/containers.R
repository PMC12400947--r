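#' Variant keys
#'
#' Every filter in the package identifies a variant by the full
#' `chrom:pos:ref:alt` tuple, never by position alone. `variant_key()`
#' builds the canonical key string; `parse_variant_key()` inverts it.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Single-nucleotide reference / alternate alleles.
#' @return A character vector of keys, or for `parse_variant_key()` a tibble
#'   with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' variant_key("chr1", 100, "A", "G")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @param key Character vector of `chrom:pos:ref:alt` keys.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) abort(paste0("malformed variant key: ", key[bad][1]))
  m <- do.call(rbind, parts)
  tibble::tibble(
    chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 3], alt = m[, 4]
  )
}

validate_variant_table <- function(variants) {
  variants <- tibble::as_tibble(variants)
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste("variant table lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) abort("variant positions must be >= 1")
  nts <- c("A", "C", "G", "T")
  if (!all(variants$ref %in% nts) || !all(variants$alt %in% nts)) {
    abort("only single-nucleotide A/C/G/T alleles are supported")
  }
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    abort("duplicate variant keys within one batch")
  }
  variants[, c("chrom", "pos", "ref", "alt", "key")]
}

check_grid <- function(m, n_var, n_samp, what) {
  if (!is.matrix(m) || nrow(m) != n_var || ncol(m) != n_samp) {
    abort(paste0(what, " must be a ", n_var, " x ", n_samp, " matrix"))
  }
  m
}

#' Imputed-genotype batch container
#'
#' Holds one batch (or a merged set of batches) of imputed genotypes as
#' aligned variants-by-samples grids: hard calls `gt` coded as
#' alternate-allele copies (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` =
#' missing), the posterior genotype-probability triplet as three matrices in
#' VCF order (hom-ref, het, hom-alt), and the expected alternate-allele
#' dosage `ds = p(het) + 2 p(hom-alt)` in `[0, 2]`.
#'
#' GP triplets attached to non-missing genotypes must sum to 1; triplets off
#' by more than `1e-3` are renormalized with a warning. A missing `ds` is
#' silently derived from GP. Phasing is irrelevant here: all filters operate
#' at the genotype-class level.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (biallelic SNVs only).
#' @param samples Character vector of sample identifiers.
#' @param gt Integer matrix (variants x samples) of 0/1/2 calls, `NA` missing.
#' @param gp_homref,gp_het,gp_homalt Numeric matrices of posterior genotype
#'   probabilities.
#' @param ds Optional numeric matrix of dosages; recomputed from GP when
#'   `NULL`.
#' @param variant_quality Optional per-variant imputation quality score in
#'   `[0, 1]` (a batch INFO score carried in from the imputation tool).
#' @param batch_id Batch label.
#' @return An object of class `imputed_matrix`.
#' @export
imputed_matrix <- function(variants, samples, gt,
                           gp_homref, gp_het, gp_homalt,
                           ds = NULL, variant_quality = NULL,
                           batch_id = "b1") {
  variants <- validate_variant_table(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicate sample identifiers")
  nv <- nrow(variants)
  ns <- length(samples)
  gt <- check_grid(gt, nv, ns, "gt")
  storage.mode(gt) <- "integer"
  if (!all(gt[!is.na(gt)] %in% 0:2)) abort("gt values must be 0, 1, 2 or NA")
  gp_homref <- check_grid(gp_homref, nv, ns, "gp_homref")
  gp_het <- check_grid(gp_het, nv, ns, "gp_het")
  gp_homalt <- check_grid(gp_homalt, nv, ns, "gp_homalt")

  called <- !is.na(gt)
  gp_missing <- called & (is.na(gp_homref) | is.na(gp_het) | is.na(gp_homalt))
  if (any(gp_missing)) {
    idx <- which(gp_missing, arr.ind = TRUE)[1, ]
    abort(paste0("GP triplet missing for called genotype at variant ",
                 variants$key[idx[1]], ", sample ", samples[idx[2]]))
  }
  rng <- range(c(gp_homref[called], gp_het[called], gp_homalt[called]))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    abort("GP values must lie in [0, 1]")
  }
  s <- gp_homref + gp_het + gp_homalt
  off <- called & abs(s - 1) > 1e-3
  if (any(off)) {
    warn(paste0(sum(off), " GP triplet(s) deviated from sum 1 by more than ",
                "1e-3 and were renormalized"))
  }
  fix <- called & abs(s - 1) > .Machine$double.eps
  if (any(fix)) {
    gp_homref[fix] <- gp_homref[fix] / s[fix]
    gp_het[fix] <- gp_het[fix] / s[fix]
    gp_homalt[fix] <- gp_homalt[fix] / s[fix]
  }
  if (is.null(ds)) {
    ds <- gp_het + 2 * gp_homalt
  } else {
    ds <- check_grid(ds, nv, ns, "ds")
    fill <- called & is.na(ds)   # records carrying GP but no DS field
    if (any(fill)) ds[fill] <- gp_het[fill] + 2 * gp_homalt[fill]
    if (any(ds[called] < -1e-6 | ds[called] > 2 + 1e-6)) {
      abort("ds values must lie in [0, 2]")
    }
    ds <- pmin(pmax(ds, 0), 2)
  }
  ds[!called] <- NA_real_
  gp_homref[!called] <- NA_real_
  gp_het[!called] <- NA_real_
  gp_homalt[!called] <- NA_real_
  if (!is.null(variant_quality)) {
    variant_quality <- as.numeric(variant_quality)
    if (length(variant_quality) != nv) {
      abort("variant_quality must have one value per variant")
    }
    ok <- is.na(variant_quality) |
      (variant_quality >= 0 & variant_quality <= 1)
    if (!all(ok)) abort("variant_quality values must lie in [0, 1]")
  }
  structure(
    list(variants = variants, samples = samples, gt = gt,
         gp_homref = gp_homref, gp_het = gp_het, gp_homalt = gp_homalt,
         ds = ds, variant_quality = variant_quality, batch_id = batch_id,
         n_skipped = 0L),
    class = "imputed_matrix"
  )
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat("<imputed_matrix> batch", x$batch_id, "-",
      nrow(x$variants), "variants x", length(x$samples), "samples\n")
  cat("  missing genotypes:", sum(is.na(x$gt)), "\n")
  if (!is.null(x$variant_quality)) {
    cat("  per-variant quality: present\n")
  }
  invisible(x)
}

#' Number of variants / samples in a container
#' @param x An `imputed_matrix` or `truth_matrix`.
#' @return An integer count.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname n_variants
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a genotype container
#'
#' @param x An `imputed_matrix` or `truth_matrix`.
#' @param keys Variant keys to keep (order preserved as given).
#' @param samples Sample ids to keep.
#' @return A container of the same class.
#' @export
subset_genotypes <- function(x, keys = NULL, samples = NULL) {
  ri <- if (is.null(keys)) seq_len(nrow(x$variants)) else {
    i <- match(keys, x$variants$key)
    if (anyNA(i)) abort("some requested variant keys are absent")
    i
  }
  ci <- if (is.null(samples)) seq_along(x$samples) else {
    j <- match(samples, x$samples)
    if (anyNA(j)) abort("some requested sample ids are absent")
    j
  }
  x$variants <- x$variants[ri, ]
  x$samples <- x$samples[ci]
  for (f in intersect(names(x), c("gt", "gp_homref", "gp_het", "gp_homalt",
                                  "ds", "dosage"))) {
    x[[f]] <- x[[f]][ri, ci, drop = FALSE]
  }
  if (!is.null(x$variant_quality)) x$variant_quality <- x$variant_quality[ri]
  x
}

#' Truth-genotype container
#'
#' High-confidence genotypes (array or high-coverage calls) used as the
#' benchmark truth, stored as a variants-by-samples grid of dosage classes
#' 0/1/2 with `NA` for uncalled genotypes.
#'
#' @inheritParams imputed_matrix
#' @param dosage Integer matrix of 0/1/2 truth classes, `NA` missing.
#' @return An object of class `truth_matrix`.
#' @export
truth_matrix <- function(variants, samples, dosage) {
  variants <- validate_variant_table(variants)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicate sample identifiers")
  dosage <- check_grid(dosage, nrow(variants), length(samples), "dosage")
  storage.mode(dosage) <- "integer"
  if (!all(dosage[!is.na(dosage)] %in% 0:2)) {
    abort("truth dosage classes must be 0, 1, 2 or NA")
  }
  structure(list(variants = variants, samples = samples, dosage = dosage),
            class = "truth_matrix")
}

#' @export
print.truth_matrix <- function(x, ...) {
  cat("<truth_matrix>", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

# max posterior per cell, NA where the genotype is missing
gp_max <- function(x) {
  pmax(x$gp_homref, x$gp_het, x$gp_homalt)
}
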