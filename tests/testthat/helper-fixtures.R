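# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

`%||%` <- function(x, y) if (is.null(x)) y else x

# small imputed matrix from explicit per-cell values ------------------------
toy_variants <- function(n, chrom = "1") {
  tibble::tibble(chrom = chrom, pos = 100L * seq_len(n),
                 ref = rep_len(c("A", "C", "G", "T"), n),
                 alt = rep_len(c("G", "T", "A", "C"), n))
}

# build an imputed_matrix whose GP triplets are sharply concentrated on the
# given gt calls (gp_top on the call, remainder on a neighbour)
toy_matrix <- function(gt, gp_top = 1, samples = NULL, batch_id = "b1",
                       variants = NULL, ds = NULL, variant_quality = NULL) {
  gt <- as.matrix(gt)
  nv <- nrow(gt); ns <- ncol(gt)
  samples <- samples %||% sprintf("S%02d", seq_len(ns))
  variants <- variants %||% toy_variants(nv)
  rest <- 1 - gp_top
  gp_rr <- matrix(ifelse(gt == 0L, gp_top, ifelse(gt == 1L, rest, 0)), nv, ns)
  gp_ra <- matrix(ifelse(gt == 1L, gp_top, rest), nv, ns)
  gp_aa <- matrix(ifelse(gt == 2L, gp_top, 0), nv, ns)
  gp_rr[is.na(gt)] <- NA; gp_ra[is.na(gt)] <- NA; gp_aa[is.na(gt)] <- NA
  imputed_matrix(variants, samples, gt, gp_rr, gp_ra, gp_aa, ds = ds,
                 variant_quality = variant_quality, batch_id = batch_id)
}

toy_af <- function(x, af = 0.5) {
  v <- x$variants
  tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 af = rep_len(af, nrow(v)), key = v$key)
}

# random imputed/truth pair for oracle comparisons --------------------------
random_instance <- function(nv, ns, p_missing = 0.1) {
  variants <- toy_variants(nv)
  samples <- sprintf("S%02d", seq_len(ns))
  tru <- matrix(sample(c(0:2, NA), nv * ns, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), nv, ns)
  gp <- matrix(runif(nv * ns * 3), nv * ns, 3)
  gp <- gp / rowSums(gp)
  gt <- max.col(gp, ties.method = "first") - 1L
  gt_m <- matrix(gt, nv, ns)
  miss <- matrix(runif(nv * ns) < p_missing, nv, ns)
  gt_m[miss] <- NA_integer_
  imp <- imputed_matrix(variants, samples, gt_m,
                        matrix(gp[, 1], nv, ns), matrix(gp[, 2], nv, ns),
                        matrix(gp[, 3], nv, ns))
  list(imp = imp,
       truth = truth_matrix(variants, samples, tru))
}

# independent INFO oracle: plain per-sample loop over the defining formula --
info_oracle <- function(gp) {
  n <- nrow(gp)
  e <- f <- numeric(n)
  for (i in seq_len(n)) {
    e[i] <- gp[i, 2] + 2 * gp[i, 3]
    f[i] <- gp[i, 2] + 4 * gp[i, 3]
  }
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  val <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(max(val, 0), 1)
}

# brute-force confusion/metric oracle: explicit double loop -----------------
confusion_oracle <- function(imp_gt, tru, mask = NULL) {
  grid <- matrix(0L, 3, 3)
  n_missing <- c(0L, 0L, 0L)
  n_truth_missing <- 0L
  for (i in seq_len(nrow(tru))) {
    for (j in seq_len(ncol(tru))) {
      t_ <- tru[i, j]
      g <- imp_gt[i, j]
      if (!is.null(mask) && isTRUE(mask[i, j])) g <- NA
      if (is.na(t_)) {
        n_truth_missing <- n_truth_missing + 1L
      } else if (is.na(g)) {
        n_missing[t_ + 1L] <- n_missing[t_ + 1L] + 1L
      } else {
        grid[t_ + 1L, g + 1L] <- grid[t_ + 1L, g + 1L] + 1L
      }
    }
  }
  list(grid = grid, n_missing = n_missing, n_truth_missing = n_truth_missing)
}

sensitivity_oracle <- function(grid, cls) {
  i <- cls + 1L
  if (sum(grid[i, ]) == 0) return(NA_real_)
  grid[i, i] / sum(grid[i, ])
}

precision_oracle <- function(grid, cls) {
  i <- cls + 1L
  if (sum(grid[, i]) == 0) return(NA_real_)
  grid[i, i] / sum(grid[, i])
}

nrc_oracle <- function(grid) {
  err <- sum(grid[1, c(2, 3)])
  era <- sum(grid[2, c(1, 3)])
  eaa <- sum(grid[3, c(1, 2)])
  mra <- grid[2, 2]; maa <- grid[3, 3]
  denom <- err + era + eaa + mra + maa
  if (denom == 0) return(NA_real_)
  1 - (err + era + eaa) / denom
}

# textbook Pearson r^2 written out, independent of stats::cor ---------------
r2_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  (sxy / sqrt(sxx * syy))^2
}

# one small simulated cohort reused by several test files (memoised) --------
.shared <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.shared$cohort)) {
    cfg <- sim_config(n_samples = 60, n_variants = 1500, n_batches = 2,
                      seed = 7)
    .shared$cohort <- c(simulate_batches(cfg), list(cfg = cfg))
  }
  .shared$cohort
}
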