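# per-stage substreams: one master seed deterministically spawns the seeds
# for truth / depth / reads / posterior stages, so each stage is
# independently reproducible
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 4),
           c("truth", "depth", "reads", "posterior"))
}

#' Simulate truth genotypes under Hardy-Weinberg equilibrium
#'
#' Draws a panel allele frequency per variant from the configured AF model,
#' then genotypes i.i.d. as Binomial(2, AF) per sample — Hardy-Weinberg
#' proportions \eqn{(1-\theta)^2, 2\theta(1-\theta), \theta^2}. Variants are
#' laid out as biallelic A>G SNVs at 1 kb spacing on one chromosome (the
#' coordinates are synthetic bookkeeping; every filter operates on keys).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `truth` (a [truth_matrix()]) and `af`
#'   (a tibble usable with [af_lookup()]).
#' @export
simulate_truth <- function(cfg) {
  seeds <- stage_seeds(cfg$seed)
  set.seed(seeds[["truth"]])
  af <- draw_af(cfg$af_model, cfg$n_variants)
  if (all(af == 0)) abort("degenerate AF model: every variant has frequency 0")
  variants <- tibble::tibble(
    chrom = "1", pos = 1000L * seq_len(cfg$n_variants),
    ref = "A", alt = "G"
  )
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  dosage <- matrix(
    rbinom(cfg$n_variants * cfg$n_samples, size = 2, prob = af),
    nrow = cfg$n_variants, ncol = cfg$n_samples
  )
  truth <- truth_matrix(variants, samples, dosage)
  af_tab <- tibble::tibble(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, af = af, key = truth$variants$key
  )
  list(truth = truth, af = af_tab)
}

# alt-read probability by genotype dosage: hom-ref reads are alt only
# through base error, het reads are a coin flip, hom-alt reads are alt
# unless misread
mu_alt <- function(dosage, base_error) {
  c(base_error, 0.5, 1 - base_error)[dosage + 1L]
}

#' Simulate sequencing reads over truth genotypes
#'
#' Per (variant, sample) cell, read depth is Poisson with mean
#' `coverage * imputation_gain * sample_factor`, where the per-sample factor
#' is lognormal with relative SD `coverage_rel_sd` (see [sim_config()] for
#' why the gain stands in for haplotype-panel information). Each read is an
#' alternate-allele read with probability
#' \deqn{(1 - ff)\,\mu(g_m) + ff\,\mu(g_f),}
#' where \eqn{\mu} maps genotype to alt-read probability
#' (`base_error`, 0.5, `1 - base_error`), \eqn{g_m} is the maternal (truth)
#' genotype and the fetal genotype \eqn{g_f} inherits one maternal allele
#' chosen uniformly plus one population allele drawn at the panel AF. The
#' fetal mixture is what degrades imputation from maternal plasma at high
#' fetal fraction.
#'
#' @param truth A [truth_matrix()].
#' @param af AF table aligned to the truth variants.
#' @param cfg A [sim_config()].
#' @return A list of class `read_counts` with matrices `n` (depth) and
#'   `n_alt`, plus the per-sample depth factors.
#' @export
simulate_reads <- function(truth, af, cfg) {
  seeds <- stage_seeds(cfg$seed)
  nv <- nrow(truth$variants)
  ns <- length(truth$samples)
  af_v <- af_lookup(af, truth$variants$key)
  if (anyNA(af_v)) abort("AF missing for some truth variants")

  set.seed(seeds[["depth"]])
  sample_factor <- if (cfg$coverage_rel_sd > 0) {
    sdlog <- sqrt(log(1 + cfg$coverage_rel_sd^2))
    rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, ns)
  lambda <- cfg$coverage * cfg$imputation_gain *
    matrix(sample_factor, nv, ns, byrow = TRUE)
  n <- matrix(rpois(nv * ns, lambda), nv, ns)

  set.seed(seeds[["reads"]])
  # fetal genotype: one transmitted maternal allele + one population allele
  transmitted <- matrix(rbinom(nv * ns, 1, truth$dosage / 2), nv, ns)
  pop_allele <- matrix(rbinom(nv * ns, 1, af_v), nv, ns)
  g_f <- transmitted + pop_allele
  p_alt <- (1 - cfg$fetal_fraction) * mu_alt(truth$dosage, cfg$base_error) +
    cfg$fetal_fraction * mu_alt(g_f, cfg$base_error)
  p_alt <- matrix(p_alt, nv, ns)
  n_alt <- matrix(rbinom(nv * ns, size = n, prob = p_alt), nv, ns)
  structure(
    list(n = n, n_alt = n_alt, variants = truth$variants,
         samples = truth$samples, sample_factor = sample_factor),
    class = "read_counts"
  )
}

#' Genotype posteriors from read counts
#'
#' The simulator's stand-in for an imputation caller: per cell,
#' \deqn{P(g \mid reads) \propto \mathrm{Binom}(n_{alt}; n, \mu(g)) \cdot
#' \mathrm{HWE}(g; AF),} over the three genotypes. The fetal mixture is
#' deliberately ignored here — exactly the model mismatch that produces
#' contamination-driven miscalls in real maternal-plasma data. At depth 0
#' the posterior equals the Hardy-Weinberg prior, so the variant-level INFO
#' score of an unsequenced variant is exactly 0. The hard call is the
#' posterior argmax (ties resolve to the lowest-index class) and
#' `DS = p(het) + 2 p(hom-alt)`.
#'
#' @param reads A `read_counts` object from [simulate_reads()].
#' @param af AF table aligned to the read variants.
#' @param base_error Per-read error rate assumed by the caller.
#' @param batch_id Label for the resulting batch.
#' @return An [imputed_matrix()] (without `variant_quality`; see
#'   [simulate_batches()] for per-batch INFO attachment).
#' @export
posterior_gp <- function(reads, af, base_error = 0.01, batch_id = "b1") {
  af_v <- af_lookup(af, reads$variants$key)
  if (anyNA(af_v)) abort("AF missing for some variants")
  nv <- nrow(reads$n)
  ns <- ncol(reads$n)
  prior_rr <- matrix((1 - af_v)^2, nv, ns)
  prior_ra <- matrix(2 * af_v * (1 - af_v), nv, ns)
  prior_aa <- matrix(af_v^2, nv, ns)
  l_rr <- dbinom(reads$n_alt, reads$n, base_error)
  l_ra <- dbinom(reads$n_alt, reads$n, 0.5)
  l_aa <- dbinom(reads$n_alt, reads$n, 1 - base_error)
  w_rr <- prior_rr * l_rr
  w_ra <- prior_ra * l_ra
  w_aa <- prior_aa * l_aa
  z <- w_rr + w_ra + w_aa
  gp_rr <- w_rr / z
  gp_ra <- w_ra / z
  gp_aa <- w_aa / z
  # argmax with lowest-index tie break
  gt <- matrix(0L, nv, ns)
  gt[gp_ra > gp_rr & gp_ra > gp_aa] <- 1L
  gt[gp_aa > gp_rr & gp_aa > gp_ra] <- 2L
  gt[gp_ra > gp_rr & gp_ra == gp_aa] <- 1L
  imputed_matrix(reads$variants[, c("chrom", "pos", "ref", "alt")],
                 reads$samples, gt, gp_rr, gp_ra, gp_aa,
                 batch_id = batch_id)
}

#' Simulate a batched low-pass imputed cohort
#'
#' End-to-end generator: truth genotypes and panel AF, reads per cell, and
#' per-batch genotype posteriors. Samples are partitioned evenly across
#' `n_batches` (all batches share the variant set), and each batch's
#' per-variant quality score is its recomputed INFO score — mirroring how
#' large cohorts are imputed in separate batches that each report their own
#' consensus INFO.
#'
#' @param cfg A [sim_config()].
#' @return A list with `batches` (list of [imputed_matrix()]), `truth`
#'   (a [truth_matrix()]) and `af` (tibble).
#' @export
simulate_batches <- function(cfg) {
  sim <- simulate_truth(cfg)
  reads <- simulate_reads(sim$truth, sim$af, cfg)
  full <- posterior_gp(reads, sim$af, cfg$base_error)
  batch_of <- sort(rep_len(seq_len(cfg$n_batches), cfg$n_samples))
  batches <- lapply(seq_len(cfg$n_batches), function(i) {
    b <- subset_genotypes(full, samples = full$samples[batch_of == i])
    b$batch_id <- sprintf("b%02d", i)
    b$variant_quality <- unname(batch_info_scores(b))
    b
  })
  list(batches = batches, truth = sim$truth, af = sim$af)
}
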