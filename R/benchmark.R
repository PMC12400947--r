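#' End-to-end simulated benchmark of the filter regimes
#'
#' Generates one synthetic cohort, applies the four filter regimes —
#' `raw` (no filter), `gp99` (per-sample max(GP) masking), `info_only`
#' (cross-batch INFO exclusion alone) and `gdi` (the full batch-level
#' strategy) — and computes the stratified accuracy metrics, the per-sample
#' heterozygous sensitivities, the cumulative-missingness comparison on the
#' GDI-kept variant set, and the variant-cutoff sweep. Everything is
#' deterministic given `sim_cfg$seed`.
#'
#' @param sim_cfg A [sim_config()].
#' @param gdi_cfg A [gdi_config()].
#' @param out_dir Optional directory; when given, metric tables (TSV) and a
#'   JSON run manifest are written there (partial outputs are removed on
#'   failure).
#' @return An object of class `gdi_benchmark`: `metrics` (pooled tibble),
#'   `het_by_sample`, `gdi` (the `gdi_result`), `gp99` (the filter),
#'   `missingness` (intact-site comparison tibble), `sweep`, and the
#'   `manifest` list.
#' @export
run_benchmark <- function(sim_cfg = sim_config(), gdi_cfg = gdi_config(),
                          out_dir = NULL) {
  sim <- simulate_batches(sim_cfg)
  gdi_res <- apply_gdi(sim$batches, sim$af, gdi_cfg)
  merged <- gdi_res$merged
  gp99 <- apply_gp99(merged, gdi_cfg$gp_min)
  info_keep <- setdiff(merged$variants$key, gdi_res$excluded_info)

  regimes <- list(
    raw = regime(),
    gp99 = regime_from_gp99(gp99),
    info_only = regime(keep_variants = info_keep),
    gdi = regime_from_gdi(gdi_res)
  )
  metrics <- stratified_metrics(merged, sim$truth, sim$af, regimes)
  het_by_sample <- sample_het_sensitivity(merged, sim$truth, sim$af, regimes)

  kept <- gdi_res$kept_variants$key
  miss_gdi <- cumulative_missingness(
    filtered_matrix(gdi_res)
  )
  miss_gp99 <- cumulative_missingness(merged, mask = gp99,
                                      keep_variants = kept)
  missingness <- dplyr::bind_rows(
    dplyr::mutate(missingness_summary(miss_gdi), filter = "gdi"),
    dplyr::mutate(missingness_summary(miss_gp99), filter = "gp99")
  )
  sweep <- sweep_variant_cutoff(gdi_res$flag_matrix,
                                gdi_res$retained_samples)
  manifest <- list(
    tool = "gdiqc",
    version = as.character(packageVersion("gdiqc")),
    seed = sim_cfg$seed,
    sim_config = unclass(sim_cfg)[setdiff(names(sim_cfg), "af_model")],
    af_model = unclass(sim_cfg$af_model),
    gdi_config = unclass(gdi_cfg),
    counts = gdi_res$report[c("n_variants_in", "n_excluded_info", "n_no_af",
                              "n_below_maf", "n_excluded_fraction",
                              "n_variants_out", "n_samples_in",
                              "n_outlier_samples", "n_samples_out")],
    flag_tally = as.list(gdi_res$report$flag_tally),
    mean_lqv_before = gdi_res$report$mean_lqv_before,
    mean_lqv_after = gdi_res$report$mean_lqv_after
  )
  # counters must reconcile: every variant/sample is kept or excluded once
  stopifnot(
    manifest$counts$n_variants_in == manifest$counts$n_variants_out +
      manifest$counts$n_excluded_info + manifest$counts$n_no_af +
      manifest$counts$n_below_maf + manifest$counts$n_excluded_fraction,
    manifest$counts$n_samples_in == manifest$counts$n_samples_out +
      manifest$counts$n_outlier_samples
  )
  out <- structure(
    list(metrics = metrics, het_by_sample = het_by_sample, gdi = gdi_res,
         gp99 = gp99, missingness = missingness, sweep = sweep,
         manifest = manifest, truth = sim$truth, af = sim$af),
    class = "gdi_benchmark"
  )
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("metrics.tsv", "het_by_sample.tsv",
                                "lqv.tsv", "variant_fail.tsv", "sweep.tsv",
                                "missingness.tsv", "manifest.json"))
  tryCatch({
    tsv <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    tsv(bench$metrics, paths[1])
    tsv(bench$het_by_sample, paths[2])
    tsv(bench$gdi$lqv, paths[3])
    tsv(bench$gdi$variant_fail, paths[4])
    tsv(bench$sweep, paths[5])
    tsv(bench$missingness, paths[6])
    jsonlite::write_json(bench$manifest, paths[7], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(paths)
    abort(paste("failed to write benchmark outputs:", conditionMessage(e)))
  })
  invisible(out_dir)
}

#' @export
print.gdi_benchmark <- function(x, ...) {
  cat("<gdi_benchmark> seed", x$manifest$seed, "\n")
  print(x$gdi)
  cat("  intact sites: gdi", x$missingness$n_intact[x$missingness$filter == "gdi"],
      "vs gp99", x$missingness$n_intact[x$missingness$filter == "gp99"],
      "(on the GDI-kept set)\n")
  invisible(x)
}

#' @method glance gdi_benchmark
#' @export
glance.gdi_benchmark <- function(x, ...) {
  het <- dplyr::filter(x$metrics, .data$class == "het",
                       .data$maf_bin >= "[0.05,0.1)")
  agg <- dplyr::summarise(
    dplyr::group_by(het, .data$regime),
    het_sensitivity = sum(.data$n_correct) /
      sum(.data$n_truth - .data$n_missing),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg, names_from = "regime",
                             values_from = "het_sensitivity",
                             names_prefix = "het_sens_")
  dplyr::bind_cols(
    glance(x$gdi),
    wide,
    tibble::tibble(
      n_intact_gdi = x$missingness$n_intact[x$missingness$filter == "gdi"],
      n_intact_gp99 = x$missingness$n_intact[x$missingness$filter == "gp99"]
    )
  )
}
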