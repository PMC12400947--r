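# GP/DS flagging, LQV scoring, outlier and variant-fraction exclusion

test_that("per-genotype flags follow the published GP/DS thresholds", {
  expect_equal(as.character(
    flag_genotype("hom_ref", c(0.995, 0.005, 0), ds = 0.05)), "pass")
  expect_equal(as.character(
    flag_genotype("hom_ref", c(0.995, 0.005, 0), ds = 0.2)), "fail_ds")
  expect_equal(as.character(
    flag_genotype("het", c(0.03, 0.95, 0.02), ds = 1.5)), "fail_both")
  # hom-alt dosage must reach 1.8; GP alone can fail
  expect_equal(as.character(
    flag_genotype("hom_alt", c(0, 0.02, 0.98), ds = 1.95)), "fail_gp")
  expect_equal(as.character(
    flag_genotype("hom_alt", c(0, 0.005, 0.995), ds = 1.7)), "fail_ds")
  # boundary semantics: max(GP) = 0.99 passes the GP flag (inclusive)
  expect_equal(as.character(
    flag_genotype("het", c(0.005, 0.99, 0.005), ds = 1.0)), "pass")
  # het dosage boundaries are part of the pass interval
  expect_equal(as.character(
    flag_genotype("het", c(0, 1, 0), ds = 0.8)), "pass")
  expect_equal(as.character(
    flag_genotype("het", c(0, 1, 0), ds = 1.01)), "pass")
  expect_error(flag_genotype(NA, c(1, 0, 0), 0), "missing")
})

test_that("LQV is the flagged fraction under the configured logic", {
  expect_equal(compute_lqv(rep("pass", 50)), 0)
  expect_equal(compute_lqv(c(rep("fail_gp", 50), rep("pass", 50))), 0.5)
  expect_equal(compute_lqv(c(rep("fail_ds", 13), rep("pass", 87))), 0.13)
  # under "both" logic only fail_both counts
  both_cfg <- gdi_config(flag_logic = "both")
  expect_equal(compute_lqv(c("fail_gp", "fail_ds", "fail_both"), both_cfg),
               1 / 3)
  expect_error(compute_lqv(character(0)), "no flagged")
})

test_that("flag matrix restricts to INFO-passing, panel, common variants", {
  gt <- matrix(rep(c(0L, 1L, 2L), length.out = 10 * 4), 10, 4)
  x <- toy_matrix(gt, gp_top = 1)
  af <- toy_af(x, af = c(rep(0.5, 6), 0.01, 0.5, 0.5, 0.5))
  af_small <- af[af$key != x$variants$key[8], ]   # variant 8 not in panel
  excl <- x$variants$key[1:2]
  fm <- build_flag_matrix(x, info_excluded = excl, af = af_small)
  # 10 - 2 INFO - 1 below MAF - 1 absent from panel = 6 flagged variants
  expect_equal(nrow(fm$flags), 6L)
  expect_equal(fm$n_info_excluded, 2L)
  expect_equal(fm$n_below_maf, 1L)
  expect_equal(fm$n_no_af, 1L)
  # fully certain genotypes: everything passes, all LQV zero
  expect_true(all(fm$flags == 0L))
  expect_true(all(fm$lqv$lqv == 0))
})

test_that("flag tallies conserve the grid size", {
  set.seed(33)
  inst <- random_instance(30, 8)
  x <- inst$imp
  fm <- build_flag_matrix(x, character(), toy_af(x))
  tal <- flag_tally(fm)
  expect_equal(sum(tal), length(fm$flags))
  # "both" logic flags a subset of "either" in every cell
  fm_both <- build_flag_matrix(x, character(), toy_af(x),
                               gdi_config(flag_logic = "both"))
  expect_equal(fm$flags, fm_both$flags)  # codes identical; logic differs
  expect_true(all(fm_both$lqv$lqv <= fm$lqv$lqv + 1e-12))
})

test_that("outlier detection is strict at the LQV cutoff", {
  fm <- list(lqv = tibble::tibble(sample = c("a", "b", "c"),
                                  lqv = c(0.45, 0.40, 0.1)),
             config = gdi_config())
  class(fm) <- "flag_matrix"
  expect_equal(detect_outlier_samples(fm, gdi_config()), "a")
  fm$lqv$lqv <- c(0.1, 0.1, 0.1)
  expect_equal(detect_outlier_samples(fm, gdi_config()), character(0))
})

test_that("variant failure fractions exclude outlier samples entirely", {
  # variant 1 flagged only in the outlier sample S03
  gt <- matrix(0L, 2, 3)
  ds <- rbind(c(0, 0, 0.5), c(0, 0, 0))   # high ds in hom-ref = DS fail
  x <- toy_matrix(gt, gp_top = 1, ds = ds)
  fm <- build_flag_matrix(x, character(), toy_af(x))
  fr_all <- variant_failure_fractions(fm)
  expect_equal(fr_all$fail_fraction, c(1 / 3, 0))
  fr_ret <- variant_failure_fractions(fm, c("S01", "S02"))
  expect_equal(fr_ret$fail_fraction, c(0, 0))
  expect_equal(fr_ret$n_eval, c(2L, 2L))
  expect_error(variant_failure_fractions(fm, character(0)), "empty")
  expect_error(variant_failure_fractions(fm, "nope"), "subset")
})

test_that("apply_gdi runs the pipeline in order and accounts for every variant", {
  set.seed(44)
  co <- small_cohort()
  res <- apply_gdi(co$batches, co$af)
  r <- res$report
  expect_equal(r$n_variants_out,
               r$n_variants_in - r$n_excluded_info - r$n_no_af -
                 r$n_below_maf - r$n_excluded_fraction)
  expect_equal(r$n_samples_out + r$n_outlier_samples, r$n_samples_in)
  # no kept variant exceeds the failure cutoff among retained samples
  kept_fr <- res$variant_fail$fail_fraction[
    res$variant_fail$key %in% res$kept_variants$key]
  expect_true(all(kept_fr <= res$config$variant_fail_max))
  # GDI never masks genotypes: the filtered matrix is fully intact
  fx <- filtered_matrix(res)
  expect_equal(sum(is.na(fx$gt)), 0L)
  # filtering reduces the residual low-quality mass
  expect_lt(r$mean_lqv_after, r$mean_lqv_before)
})

test_that("variant_fail_max = 1 disables the fraction step; certain data sail through", {
  gt <- matrix(rep(c(0L, 1L, 2L), length.out = 8 * 5), 8, 5)
  x <- toy_matrix(gt, gp_top = 1)
  res <- apply_gdi(x, toy_af(x),
                   gdi_config(variant_fail_max = 1.0))
  expect_equal(res$report$n_excluded_fraction, 0L)
  res2 <- apply_gdi(x, toy_af(x))
  expect_equal(res2$report$n_excluded_fraction, 0L)
  expect_equal(res2$report$n_outlier_samples, 0L)
  expect_equal(res2$report$n_variants_out, 8L)
})

test_that("applying GDI to its own output excludes nothing further", {
  co <- small_cohort()
  res <- apply_gdi(co$batches, co$af)
  fx <- filtered_matrix(res)
  res2 <- apply_gdi(fx, co$af, res$config)
  expect_equal(res2$report$n_excluded_info, 0L)
  expect_equal(res2$report$n_excluded_fraction, 0L)
  expect_equal(res2$report$n_variants_out, res$report$n_variants_out)
})

test_that("cutoff sweep kept-counts are monotone and end at full retention", {
  co <- small_cohort()
  res <- apply_gdi(co$batches, co$af)
  sw <- sweep_variant_cutoff(res$flag_matrix, res$retained_samples,
                             grid = c(seq(0.1, 0.9, 0.1), 1.0))
  expect_true(all(diff(sw$n_variants_kept) >= 0))
  expect_equal(sw$n_variants_kept[nrow(sw)], nrow(res$flag_matrix$flags))
  # a cutoff below every observed positive fraction keeps only clean variants
  fr <- res$variant_fail$fail_fraction
  tiny <- min(fr[fr > 0]) / 2
  sw0 <- sweep_variant_cutoff(res$flag_matrix, res$retained_samples,
                              grid = tiny)
  expect_equal(sw0$n_variants_kept, sum(fr == 0))
  expect_error(sweep_variant_cutoff(res$flag_matrix,
                                    res$retained_samples, grid = numeric(0)),
               "empty")
})

test_that("gp99 masks below-threshold genotypes and keeps the boundary", {
  gt <- matrix(c(0L, 1L, 2L), 3, 1)
  x <- toy_matrix(gt, gp_top = 1)
  x$gp_homref[1, 1] <- 0.98; x$gp_het[1, 1] <- 0.02   # masked
  x$gp_het[2, 1] <- 0.99; x$gp_homref[2, 1] <- 0.01   # kept at boundary
  g <- apply_gp99(x)
  expect_true(g$mask[1, 1])
  expect_false(g$mask[2, 1])
  expect_false(g$mask[3, 1])
  expect_equal(g$per_sample$fraction_removed, 1 / 3)
  # all-certain matrix yields an empty mask
  g2 <- apply_gp99(toy_matrix(gt, gp_top = 1))
  expect_equal(sum(g2$mask), 0L)
})

test_that("cumulative missingness counts masked samples per variant", {
  gt <- matrix(0L, 3, 3)
  x <- toy_matrix(gt, gp_top = 1)
  mask <- matrix(FALSE, 3, 3); mask[1, 2] <- TRUE
  miss <- cumulative_missingness(x, mask = mask)
  expect_equal(miss$n_missing, c(1L, 0L, 0L))
  expect_equal(sum(miss$intact), 2L)
  # empty mask: everything intact; full-row mask: count = sample count
  expect_true(all(cumulative_missingness(x)$intact))
  mask[1, ] <- TRUE
  expect_equal(cumulative_missingness(x, mask = mask)$n_missing[1], 3L)
})

test_that("lenient gp_min never raises LQV; GDI keeps more intact sites than GP99", {
  co <- small_cohort()
  merged <- merge_batches(co$batches, "union")
  fm_strict <- build_flag_matrix(merged, character(), co$af,
                                 gdi_config(gp_min = 0.99))
  fm_lenient <- build_flag_matrix(merged, character(), co$af,
                                  gdi_config(gp_min = 0.9))
  expect_true(all(fm_lenient$lqv$lqv <= fm_strict$lqv$lqv + 1e-12))

  res <- apply_gdi(co$batches, co$af)
  g <- apply_gp99(merged)
  kept <- res$kept_variants$key
  n_intact_gdi <- sum(cumulative_missingness(filtered_matrix(res))$intact)
  n_intact_gp99 <- sum(cumulative_missingness(merged, mask = g,
                                              keep_variants = kept)$intact)
  expect_gte(n_intact_gdi, n_intact_gp99)
})
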