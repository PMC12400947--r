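#' Read an imputed VCF into an `imputed_matrix`
#'
#' Reads a VCF 4.2 file carrying per-sample `GT` and `GP` (posterior triplet)
#' fields, and optionally `DS`. Only biallelic single-nucleotide variants are
#' retained; indels and multiallelic records are skipped and counted in the
#' `n_skipped` field of the result. A missing `DS` field is derived from GP;
#' a missing `GP` field is a fatal format error because every downstream
#' filter needs it. Phased separators are treated like unphased ones.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param sample_subset Optional character vector of sample ids to keep.
#' @param info_tag Name of the INFO-column tag carrying the per-variant
#'   imputation quality score (tools differ; default `"INFO_SCORE"`). Absent
#'   tags simply leave `variant_quality` as `NA`.
#' @param batch_id Batch label; defaults to the file name.
#' @return An [imputed_matrix()] with an `n_skipped` count of dropped records.
#' @export
read_imputed_vcf <- function(path, sample_subset = NULL,
                             info_tag = "INFO_SCORE", batch_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_total <- nrow(fix)
  nts <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% nts & fix[, "ALT"] %in% nts
  n_skipped <- sum(!keep)

  fmt <- v@gt[, "FORMAT"]
  has_gp <- grepl("(^|:)GP(:|$)", fmt)
  if (!all(has_gp[keep])) {
    i <- which(keep & !has_gp)[1]
    abort(paste0("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                 " lacks the GP FORMAT field required for filtering"))
  }
  has_ds <- any(grepl("(^|:)DS(:|$)", fmt[keep]))

  gt_chr <- vcfR::extract.gt(v, "GT")[keep, , drop = FALSE]
  gp_chr <- vcfR::extract.gt(v, "GP")[keep, , drop = FALSE]
  gp_rr <- vcfR::masplit(gp_chr, delim = ",", record = 1, sort = 0)
  gp_ra <- vcfR::masplit(gp_chr, delim = ",", record = 2, sort = 0)
  gp_aa <- vcfR::masplit(gp_chr, delim = ",", record = 3, sort = 0)
  ds <- if (has_ds) {
    suppressWarnings(vcfR::extract.gt(v, "DS", as.numeric = TRUE))[keep, , drop = FALSE]
  } else NULL

  variants <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"]
  )
  quality <- rep(NA_real_, nrow(variants))
  if (!is.null(info_tag)) {
    q <- suppressWarnings(
      vcfR::extract.info(v, element = info_tag, as.numeric = TRUE)
    )
    if (!is.null(q)) quality <- as.numeric(q)[keep]
  }
  gt <- parse_gt_strings(gt_chr, variants)

  x <- imputed_matrix(
    variants, colnames(gt_chr), gt, gp_rr, gp_ra, gp_aa, ds = ds,
    variant_quality = if (all(is.na(quality))) NULL else quality,
    batch_id = batch_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  )
  x$n_skipped <- n_skipped
  if (!is.null(sample_subset)) x <- subset_genotypes(x, samples = sample_subset)
  x
}

# GT strings -> 0/1/2/NA; phasing collapsed; anything else is fatal
parse_gt_strings <- function(gt_chr, variants) {
  u <- unique(as.vector(gt_chr))
  norm <- gsub("|", "/", u, fixed = TRUE)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "./." = NA_integer_, "." = NA_integer_)
  code <- map[norm]
  unknown <- !is.na(u) & !(norm %in% names(map))
  if (any(unknown)) {
    bad_val <- u[unknown][1]
    hit <- which(gt_chr == bad_val, arr.ind = TRUE)[1, ]
    abort(paste0("malformed GT '", bad_val, "' at ",
                 variants$chrom[hit[1]], ":", variants$pos[hit[1]]))
  }
  out <- code[match(as.vector(gt_chr), u)]
  matrix(out, nrow = nrow(gt_chr), ncol = ncol(gt_chr))
}

#' Read truth genotypes from a VCF
#'
#' Maps the `GT` field of a VCF to dosage classes 0/1/2; uncalled genotypes
#' (`./.`) map to missing. Non-SNV and multiallelic records are skipped.
#'
#' @param path Path to a VCF with a GT FORMAT field.
#' @return A [truth_matrix()].
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nts <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% nts & fix[, "ALT"] %in% nts
  gt_chr <- vcfR::extract.gt(v, "GT")[keep, , drop = FALSE]
  variants <- tibble::tibble(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"]
  )
  truth_matrix(variants, colnames(gt_chr), parse_gt_strings(gt_chr, variants))
}

#' Read a panel allele-frequency table
#'
#' Loads the reference-panel alternate-allele frequencies used for the
#' minor-allele-frequency restriction and binning. Accepts either a
#' tab-separated table with columns `chrom`, `pos`, `ref`, `alt`, `af`
#' (header required, case-insensitive) or a sites VCF carrying an `AF`
#' INFO tag.
#'
#' @param path Path to the table.
#' @param format `"auto"` (by content), `"tsv"`, or `"vcf_sites"`.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `af`, `key`.
#'   Duplicate keys keep the last row, with a warning. Lookups for keys not
#'   present in the table must be treated as "not in panel" (see
#'   [af_lookup()]), never as frequency 0.
#' @export
read_af_table <- function(path, format = c("auto", "tsv", "vcf_sites")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf_sites" else "tsv"
  }
  if (format == "vcf_sites") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    tab <- tibble::tibble(
      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"], alt = fix[, "ALT"],
      af = as.numeric(vcfR::extract.info(v, element = "AF", as.numeric = TRUE))
    )
  } else {
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(raw) <- tolower(names(raw))
    need <- c("chrom", "pos", "ref", "alt", "af")
    if (!all(need %in% names(raw))) {
      abort("AF table must have columns chrom, pos, ref, alt, af")
    }
    tab <- tibble::as_tibble(raw[, need])
    tab$pos <- as.integer(tab$pos)
    tab$af <- as.numeric(tab$af)
  }
  if (anyNA(tab$af) || any(tab$af < 0 | tab$af > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(tab$key)) {
    warn("duplicate variant keys in AF table; keeping the last occurrence")
    tab <- tab[!duplicated(tab$key, fromLast = TRUE), ]
  }
  tab
}

#' Look up panel allele frequencies by variant key
#'
#' @param af_table A tibble from [read_af_table()] (or any tibble with `key`
#'   and `af` columns).
#' @param keys Character vector of variant keys.
#' @return Numeric vector of frequencies, `NA` for keys absent from the
#'   panel (distinguishable from a true frequency of 0).
#' @export
af_lookup <- function(af_table, keys) {
  af_table$af[match(keys, af_table$key)]
}

#' Merge imputed batches over a common variant space
#'
#' Large cohorts are imputed in batches and merged afterwards for a common
#' set of variants. `intersection` keeps only variants present in every
#' batch; `union` keeps all variants, with missing calls where a batch lacks
#' the variant. Sample ids must be disjoint across batches; sample order is
#' batch order.
#'
#' @param batches A list of [imputed_matrix()] objects (a single matrix is
#'   accepted and returned as-is).
#' @param mode `"intersection"` or `"union"`.
#' @return An [imputed_matrix()] spanning all samples. Per-batch quality
#'   scores are not merged (they are batch properties; see
#'   [collect_batch_info()]).
#' @export
merge_batches <- function(batches, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (inherits(batches, "imputed_matrix")) return(batches)
  if (length(batches) == 0) abort("no batches supplied")
  if (length(batches) == 1) return(batches[[1]])
  all_samples <- unlist(lapply(batches, function(b) b$samples))
  if (anyDuplicated(all_samples)) {
    abort(paste0("sample id duplicated across batches: ",
                 all_samples[duplicated(all_samples)][1]))
  }
  key_list <- lapply(batches, function(b) b$variants$key)
  keys <- Reduce(if (mode == "intersection") intersect else union, key_list)
  if (length(keys) == 0) abort("no variants shared across batches")
  var_all <- dplyr::bind_rows(lapply(batches, function(b) b$variants))
  variants <- var_all[match(keys, var_all$key), c("chrom", "pos", "ref", "alt")]
  nv <- length(keys)
  ns <- length(all_samples)
  blank <- function() matrix(NA_real_, nv, ns)
  gt <- matrix(NA_integer_, nv, ns)
  gp_rr <- blank(); gp_ra <- blank(); gp_aa <- blank(); ds <- blank()
  col0 <- 0L
  for (b in batches) {
    ri <- match(b$variants$key, keys)
    present <- !is.na(ri)
    cj <- col0 + seq_along(b$samples)
    gt[ri[present], cj] <- b$gt[present, , drop = FALSE]
    gp_rr[ri[present], cj] <- b$gp_homref[present, , drop = FALSE]
    gp_ra[ri[present], cj] <- b$gp_het[present, , drop = FALSE]
    gp_aa[ri[present], cj] <- b$gp_homalt[present, , drop = FALSE]
    ds[ri[present], cj] <- b$ds[present, , drop = FALSE]
    col0 <- col0 + length(b$samples)
  }
  imputed_matrix(variants, all_samples, gt, gp_rr, gp_ra, gp_aa, ds = ds,
                 batch_id = paste(vapply(batches, function(b) b$batch_id,
                                         character(1)), collapse = "+"))
}

#' Write an `imputed_matrix` to a VCF
#'
#' Emits a plain-text VCF 4.2 with `GT:GP:DS` FORMAT fields (and the
#' per-variant quality score as an INFO tag when present). Reading the file
#' back reproduces genotype classes exactly and GP/DS within 1e-4.
#'
#' @param x An [imputed_matrix()].
#' @param path Output path.
#' @param keep_variants Optional character vector of variant keys to emit.
#' @param genotype_mask Optional logical variants-x-samples matrix (aligned
#'   to `x`); `TRUE` cells are written as missing genotypes.
#' @param info_tag INFO tag name used for `variant_quality`.
#' @return Invisibly, the path.
#' @export
write_imputed_vcf <- function(x, path, keep_variants = NULL,
                              genotype_mask = NULL, info_tag = "INFO_SCORE") {
  if (!is.null(genotype_mask)) {
    if (inherits(genotype_mask, "gp99_filter")) genotype_mask <- genotype_mask$mask
    check_grid(genotype_mask, nrow(x$variants), length(x$samples),
               "genotype_mask")
  }
  ri <- if (is.null(keep_variants)) seq_len(nrow(x$variants)) else {
    i <- match(keep_variants, x$variants$key)
    if (anyNA(i)) abort("keep_variants contains keys absent from the matrix")
    sort(i)
  }
  gt <- x$gt[ri, , drop = FALSE]
  if (!is.null(genotype_mask)) {
    gt[genotype_mask[ri, , drop = FALSE]] <- NA_integer_
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gp_str <- matrix(
    sprintf("%.6f,%.6f,%.6f", x$gp_homref[ri, ], x$gp_het[ri, ],
            x$gp_homalt[ri, ]),
    nrow = nrow(gt)
  )
  ds_str <- matrix(sprintf("%.6f", x$ds[ri, ]), nrow = nrow(gt))
  cells <- matrix(paste(gt_str, gp_str, ds_str, sep = ":"), nrow = nrow(gt))
  cells[is.na(gt)] <- "./.:.:."
  info <- rep(".", length(ri))
  if (!is.null(x$variant_quality)) {
    q <- x$variant_quality[ri]
    info <- ifelse(is.na(q), ".", sprintf("%s=%.6f", info_tag, q))
  }
  v <- x$variants[ri, ]
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT:GP:DS",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Per-variant imputation quality score\">", info_tag),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Posterior genotype probabilities (hom-ref,het,hom-alt)\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a truth matrix to a GT-only VCF
#'
#' @param x A [truth_matrix()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_vcf <- function(x, path) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$dosage + 1L],
                   nrow = nrow(x$dosage))
  gt_str[is.na(x$dosage)] <- "./."
  v <- x$variants
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
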