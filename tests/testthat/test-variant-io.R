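# VCF parsing, writing, AF tables and batch merging

vcf_lines <- function(records, samples = c("S01", "S02"),
                      format = "GT:GP:DS") {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description=\"score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"gp\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ds\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r) paste(r, collapse = "\t"), character(1)))
}

write_tmp_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a clean VCF parses into a full matrix with derived dosages", {
  path <- write_tmp_vcf(vcf_lines(list(
    c("1", 100, ".", "A", "G", ".", "PASS", "INFO_SCORE=0.9", "GT:GP:DS",
      "0/0:0.99,0.01,0:0.01", "0/1:0.02,0.96,0.02:1.0"),
    c("1", 200, ".", "C", "T", ".", "PASS", ".", "GT:GP",
      "0/1:0.1,0.8,0.1", "1/1:0,0.05,0.95"),
    c("1", 300, ".", "G", "A", ".", "PASS", ".", "GT:GP",
      "1|1:0,0,1", "./.:.")
  )))
  x <- read_imputed_vcf(path)
  expect_equal(n_variants(x), 3L)
  expect_equal(n_samples(x), 2L)
  expect_equal(x$n_skipped, 0L)
  # dosage recomputed from GP where DS absent: 0.8 + 2*0.1 = 1.0
  expect_equal(x$ds[2, 1], 1.0, tolerance = 1e-9)
  # phased hom-alt treated as genotype class 2; uncalled cell missing
  expect_equal(x$gt[3, 1], 2L)
  expect_true(is.na(x$gt[3, 2]))
  # INFO tag picked up only where present
  expect_equal(x$variant_quality, c(0.9, NA, NA))
})

test_that("indels and multiallelic records are skipped and counted", {
  path <- write_tmp_vcf(vcf_lines(list(
    c("1", 100, ".", "A", "G", ".", ".", ".", "GT:GP",
      "0/0:1,0,0", "0/0:1,0,0"),
    c("1", 150, ".", "AT", "A", ".", ".", ".", "GT:GP",
      "0/0:1,0,0", "0/0:1,0,0"),
    c("1", 200, ".", "C", "T,G", ".", ".", ".", "GT:GP",
      "0/0:1,0,0", "0/0:1,0,0"),
    c("1", 250, ".", "C", "T", ".", ".", ".", "GT:GP",
      "0/1:0,1,0", "0/0:1,0,0"),
    c("1", 300, ".", "G", "A", ".", ".", ".", "GT:GP",
      "1/1:0,0,1", "0/0:1,0,0")
  )))
  x <- read_imputed_vcf(path)
  expect_equal(n_variants(x), 3L)
  expect_equal(x$n_skipped, 2L)
  expect_equal(x$n_skipped + n_variants(x), 5L)
})

test_that("a record without GP is a fatal format error naming it", {
  path <- write_tmp_vcf(vcf_lines(list(
    c("1", 100, ".", "A", "G", ".", ".", ".", "GT:DS", "0/0:0.0", "0/1:1.0")
  )))
  expect_error(read_imputed_vcf(path), "GP")
})

test_that("truth VCF genotype strings map to dosage classes", {
  path <- write_tmp_vcf(vcf_lines(list(
    c("1", 100, ".", "A", "G", ".", ".", ".", "GT", "0/1", "0/0"),
    c("1", 200, ".", "C", "T", ".", ".", ".", "GT", "./.", "1|1")
  )))
  tr <- read_truth_vcf(path)
  expect_equal(tr$dosage[1, ], c(1L, 0L))
  expect_true(is.na(tr$dosage[2, 1]))
  expect_equal(tr$dosage[2, 2], 2L)
})

test_that("AF tables parse, bound-check, deduplicate, and distinguish absent keys", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf",
               "chr1\t100\tA\tG\t0.25",
               "chr1\t200\tC\tT\t0.9",
               "chr1\t100\tA\tG\t0.30"), path)
  expect_warning(af <- read_af_table(path), "duplicate")
  expect_equal(af_lookup(af, "chr1:100:A:G"), 0.30)   # last wins
  expect_equal(af_lookup(af, "chr1:200:C:T"), 0.9)
  expect_true(is.na(af_lookup(af, "chr1:999:A:G")))   # absent != 0

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\taf", "chr1\t100\tA\tG\t1.3"), bad)
  expect_error(read_af_table(bad), "\\[0, 1\\]")
})

test_that("merging batches intersects or unions the variant space", {
  b1 <- toy_matrix(matrix(0L, 10, 2), batch_id = "b1")
  v2 <- toy_variants(10)[c(1:8, 9, 10), ]
  v2$pos[9:10] <- c(5000L, 6000L)   # two variants unique to batch 2
  b2 <- toy_matrix(matrix(1L, 10, 2), variants = v2,
                   samples = c("T01", "T02"), batch_id = "b2")
  shared <- intersect(b1$variants$key, b2$variants$key)
  expect_length(shared, 8L)

  mi <- merge_batches(list(b1, b2), mode = "intersection")
  expect_equal(n_variants(mi), 8L)
  expect_equal(mi$samples, c("S01", "S02", "T01", "T02"))
  expect_false(anyNA(mi$gt))

  mu <- merge_batches(list(b1, b2), mode = "union")
  expect_equal(n_variants(mu), 12L)
  # variants absent from a batch are missing for that batch's samples
  only_b1 <- setdiff(b1$variants$key, shared)
  expect_true(all(is.na(mu$gt[match(only_b1, mu$variants$key), 3:4])))
  # counts bracket the per-batch counts
  expect_lte(n_variants(mi), min(n_variants(b1), n_variants(b2)))
  expect_lte(n_variants(mu), n_variants(b1) + n_variants(b2))

  b_dup <- toy_matrix(matrix(0L, 10, 2), samples = c("S01", "X"),
                      batch_id = "b3")
  expect_error(merge_batches(list(b1, b_dup)), "duplicated")
})

test_that("write/read round-trip preserves GT exactly and GP/DS to 1e-4", {
  set.seed(42)
  inst <- random_instance(6, 3)
  x <- inst$imp
  x$variant_quality <- round(runif(6), 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_imputed_vcf(x, path)
  y <- read_imputed_vcf(path)
  expect_equal(y$gt, x$gt, ignore_attr = TRUE)
  expect_equal(y$gp_het, x$gp_het, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(y$gp_homalt, x$gp_homalt, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(y$ds, x$ds, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(y$variant_quality, x$variant_quality, tolerance = 1e-4)

  # keep-set restricts the emitted records
  write_imputed_vcf(x, path, keep_variants = x$variants$key[2])
  z <- read_imputed_vcf(path)
  expect_equal(n_variants(z), 1L)
  expect_equal(z$variants$key, x$variants$key[2])

  # masked cells read back as missing
  mask <- matrix(FALSE, 6, 3); mask[1, 1] <- TRUE
  write_imputed_vcf(x, path, genotype_mask = mask)
  w <- read_imputed_vcf(path)
  expect_true(is.na(w$gt[1, 1]))
  expect_equal(sum(is.na(w$gt)) - sum(is.na(x$gt)), 1L)
})

test_that("GP triplets that do not normalize are renormalized with a warning", {
  variants <- toy_variants(1)
  expect_warning(
    x <- imputed_matrix(variants, "S01", matrix(1L, 1, 1),
                        matrix(0.2), matrix(1.0), matrix(0.2)),
    "renormalized"
  )
  expect_equal(x$gp_het[1, 1], 1 / 1.4, tolerance = 1e-12)
})
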