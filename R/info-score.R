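#' INFO score from genotype posteriors
#'
#' The per-variant imputation INFO score measures how far the posterior
#' genotype distribution is from the flat allele-frequency prior: 1 for
#' fully confident genotypes, 0 when every posterior equals the
#' Hardy-Weinberg prior at the estimated allele frequency. The standard
#' ratio-of-variances measure used by the IMPUTE/STITCH family is computed:
#' with per-sample expected dosage \eqn{e_i = p_i(het) + 2 p_i(hom-alt)} and
#' second moment \eqn{f_i = p_i(het) + 4 p_i(hom-alt)},
#' \deqn{INFO = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\hat\theta(1-\hat\theta)},
#' \qquad \hat\theta = \sum_i e_i / (2N),}
#' clamped to \eqn{[0, 1]}, with the monomorphic convention INFO = 1 when
#' \eqn{\hat\theta \in \{0, 1\}}. Scores within 1e-9 of 0 are snapped to 0
#' so the flat-posterior limit is exact despite floating-point summation.
#'
#' @param gp A numeric matrix with one row per sample and three columns
#'   (hom-ref, het, hom-alt posterior probabilities), or a list of length-3
#'   triplets.
#' @return A single INFO score in `[0, 1]`.
#' @examples
#' info_from_gp(rbind(c(1, 0, 0), c(0, 0, 1)))       # fully certain -> 1
#' info_from_gp(rbind(c(0.25, 0.5, 0.25),
#'                    c(0.25, 0.5, 0.25)))           # HWE-flat -> 0
#' @export
info_from_gp <- function(gp) {
  if (is.list(gp)) gp <- do.call(rbind, gp)
  if (!is.matrix(gp)) gp <- matrix(gp, ncol = 3)
  if (nrow(gp) < 1) abort("at least one GP triplet is required")
  if (ncol(gp) != 3) abort("GP triplets must have three entries")
  if (anyNA(gp) || any(gp < -1e-9 | gp > 1 + 1e-9)) {
    abort("GP values must lie in [0, 1]")
  }
  if (any(abs(rowSums(gp) - 1) > 1e-3)) {
    abort("GP triplets must sum to 1 (tolerance 1e-3)")
  }
  .info_score_core(
    matrix(gp[, 2], ncol = 1) |> t(),
    matrix(gp[, 3], ncol = 1) |> t()
  )[1]
}

# vectorized core: gp_het / gp_homalt are variants x samples matrices;
# returns one score per variant, skipping missing cells
.info_score_core <- function(gp_het, gp_homalt) {
  e <- gp_het + 2 * gp_homalt
  f <- gp_het + 4 * gp_homalt
  n <- rowSums(!is.na(e))
  sum_e <- rowSums(e, na.rm = TRUE)
  theta <- sum_e / (2 * n)
  num <- rowSums(f - e * e, na.rm = TRUE)
  denom <- 2 * n * theta * (1 - theta)
  info <- ifelse(denom > 0, 1 - num / denom, 1)
  info[n == 0] <- NA_real_
  info <- pmin(pmax(info, 0), 1)
  info[!is.na(info) & abs(info) < 1e-9] <- 0
  info
}

#' Per-variant INFO scores for a batch
#'
#' @param x An [imputed_matrix()].
#' @return A numeric vector, one score per variant, computed from the GP
#'   posteriors of that batch (missing genotypes are skipped; a variant with
#'   no called genotypes gets `NA`).
#' @export
batch_info_scores <- function(x) {
  setNames(.info_score_core(x$gp_het, x$gp_homalt), x$variants$key)
}

#' Aggregate INFO scores for the same variants across batches
#'
#' Batches imputed separately produce different INFO scores for the same
#' variant; the cross-batch exclusion rule operates on the collection of
#' per-batch scores.
#'
#' @param batches A list of [imputed_matrix()] objects (or one matrix).
#' @param source `"recompute"` derives each batch's scores from its GP
#'   posteriors via [batch_info_scores()]; `"tag"` uses the per-variant
#'   quality score read from the VCF INFO column (fatal if any variant in a
#'   batch lacks it).
#' @return A tibble with columns `key`, `chrom`, `pos`, `ref`, `alt`,
#'   `batch_id`, `info`: one row per (variant, batch) where the variant is
#'   present.
#' @export
collect_batch_info <- function(batches, source = c("recompute", "tag")) {
  source <- match.arg(source)
  if (inherits(batches, "imputed_matrix")) batches <- list(batches)
  if (length(batches) == 0) abort("no batches supplied")
  purrr::map_dfr(batches, function(b) {
    info <- if (source == "tag") {
      q <- b$variant_quality
      if (is.null(q) || anyNA(q)) {
        bad <- if (is.null(q)) b$variants$key[1] else b$variants$key[which(is.na(q))[1]]
        abort(paste0("batch ", b$batch_id, " lacks a quality tag for variant ",
                     bad, " (source = \"tag\")"))
      }
      q
    } else {
      unname(batch_info_scores(b))
    }
    tibble::tibble(
      key = b$variants$key, chrom = b$variants$chrom, pos = b$variants$pos,
      ref = b$variants$ref, alt = b$variants$alt,
      batch_id = b$batch_id, info = info
    )
  })
}

#' Variants failing the INFO threshold in every batch
#'
#' A variant is excluded only when its INFO score falls below `info_min`
#' (strictly) in *every* batch where it was observed; a single batch at or
#' above the threshold rescues it. This consistency requirement is what
#' makes the rule safe to apply across independently imputed batches.
#'
#' @param info_table Tibble from [collect_batch_info()].
#' @param info_min Exclusion threshold (default 0.4; scores `< info_min`
#'   fail). 0.6 is a documented stricter alternative that in practice does
#'   not improve batch effects.
#' @return Character vector of excluded variant keys.
#' @export
variants_failing_all_batches <- function(info_table, info_min = 0.4) {
  if (nrow(info_table) == 0) abort("empty INFO table")
  tab <- dplyr::summarise(
    dplyr::group_by(info_table, .data$key),
    all_fail = all(.data$info < info_min),
    .groups = "drop"
  )
  tab$key[tab$all_fail]
}

#' Per-variant INFO summary report
#'
#' @param info_table Tibble from [collect_batch_info()].
#' @param info_min Threshold used for the `excluded` flag.
#' @return A tibble with one row per variant: number of batches observed,
#'   min and median score, and whether the cross-batch rule excludes it.
#' @export
info_report <- function(info_table, info_min = 0.4) {
  dplyr::summarise(
    dplyr::group_by(info_table, .data$key),
    n_batches = dplyr::n(),
    min_info = min(.data$info),
    median_info = median(.data$info),
    excluded = all(.data$info < info_min),
    .groups = "drop"
  )
}
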