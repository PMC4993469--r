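#' Read a VCF file into a long genotype tibble
#'
#' Loads a VCF (4.x, GT required, DP optional) and converts it to the
#' package's uniform genotype representation: one row per site x sample with
#' a categorical call in `gt` (`hom_ref`, `het`, `hom_alt`, `missing`) and
#' an integer read depth in `dp` (NA when the VCF carries no DP).
#'
#' Multi-allelic records (two or more alternative alleles) are dropped and
#' counted in the load report, mirroring the truth-set construction where
#' such variants are removed before comparison. Half-missing diploid calls
#' (`./0`, `1/.`) are treated as missing; phased (`|`) and unphased (`/`)
#' separators are equivalent and genotype order is ignored (`1/0` is `het`).
#'
#' Sites are returned sorted by (chromosome, position) under a natural
#' collation: purely numeric chromosome names (after an optional `chr`
#' prefix strip) sort by value ahead of non-numeric names, which sort
#' lexicographically.
#'
#' @param path path to a VCF file.
#' @param sample_subset optional character vector restricting the samples
#'   kept (order follows the subset).
#' @param normalize_chr strip a leading `"chr"` prefix from chromosome
#'   names (default TRUE) so that catalogues from differently-styled
#'   references match positionally.
#' @return a tibble with columns `chrom`, `pos`, `variant_class`
#'   (`"SNP"`/`"indel"`), `ref`, `alt`, `sample`, `gt`, `dp`, carrying the
#'   ordered sample list in `attr(,"samples")` and the load accounting in
#'   `attr(,"load_summary")` / `attr(,"load_report")` (see
#'   [load_report()]).
#' @seealso [write_vcf()], [catalogue_sites()]
#' @export
read_vcf <- function(path, sample_subset = NULL, normalize_chr = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) {
      stop(sprintf("format error reading VCF '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  samples <- colnames(vcf)
  if (length(samples) == 0L) {
    stop("input error: VCF has zero sample columns: ", path, call. = FALSE)
  }
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s)) {
      stop("input error: samples not in VCF: ",
           paste(missing_s, collapse = ", "), call. = FALSE)
    }
    vcf <- vcf[, sample_subset]
    samples <- sample_subset
  }

  total <- nrow(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt_list) > 1L
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom_all <- as.character(GenomicRanges::seqnames(rr))
  pos_all <- GenomicRanges::start(rr)
  if (normalize_chr) chrom_all <- sub("^chr", "", chrom_all)

  report <- tibble::tibble(
    record = paste0(chrom_all[multi], ":", pos_all[multi]),
    reason = rep("multi-allelic", sum(multi))
  )

  vcf <- vcf[!multi, ]
  chrom <- chrom_all[!multi]
  pos <- pos_all[!multi]
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  if (length(alt) == 0L) alt <- character(0)
  vclass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "indel")

  gt_mat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_mat)) stop("format error: VCF lacks a GT FORMAT field",
                            call. = FALSE)
  dp_mat <- VariantAnnotation::geno(vcf)$DP

  n_site <- length(pos)
  calls <- tibble::tibble(
    chrom = rep(chrom, times = length(samples)),
    pos = rep(pos, times = length(samples)),
    variant_class = rep(vclass, times = length(samples)),
    ref = rep(ref, times = length(samples)),
    alt = rep(alt, times = length(samples)),
    sample = rep(samples, each = n_site),
    gt = gt_from_string(as.vector(gt_mat)),
    dp = if (is.null(dp_mat)) NA_integer_ else as.integer(as.vector(dp_mat))
  )
  calls <- sort_sites(calls)
  new_geno(calls, samples = samples,
           load_summary = tibble::tibble(
             n_records = total, n_loaded = n_site,
             n_multiallelic = sum(multi), n_malformed = 0L),
           load_report = report)
}

#' @keywords internal
gt_from_string <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0", "0")] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% c("1/1", "1")] <- "hom_alt"
  out
}

#' @keywords internal
gt_to_string <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[gt]
}

#' @keywords internal
new_geno <- function(calls, samples = NULL, load_summary = NULL,
                     load_report = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample)
  attr(calls, "samples") <- samples
  if (!is.null(load_summary)) attr(calls, "load_summary") <- load_summary
  if (!is.null(load_report)) attr(calls, "load_report") <- load_report
  calls
}

#' Ordered sample list of a genotype tibble
#'
#' Falls back to the samples present in the rows when the tibble does not
#' carry an explicit sample attribute (e.g. after dplyr manipulation); the
#' attribute is what preserves samples across a zero-site matrix.
#'
#' @param geno genotype tibble.
#' @return character vector of sample identifiers.
#' @export
geno_samples <- function(geno) {
  s <- attr(geno, "samples")
  if (is.null(s)) s <- unique(geno$sample)
  s
}

#' Load accounting of a VCF read
#'
#' @param geno genotype tibble from [read_vcf()].
#' @param what `"summary"` for record counts (total = loaded +
#'   multi-allelic + malformed), `"records"` for the per-dropped-record
#'   (record, reason) table.
#' @return a tibble.
#' @export
load_report <- function(geno, what = c("summary", "records")) {
  what <- match.arg(what)
  out <- attr(geno, if (what == "summary") "load_summary" else "load_report")
  if (is.null(out)) stop("no load report attached; was this read by read_vcf()?",
                         call. = FALSE)
  out
}

#' Write a genotype tibble as minimal VCF 4.2
#'
#' Emits GT for every cell and DP when any depth is present; the inverse of
#' [read_vcf()] on valid matrices (round-trips call states and depths).
#' Sample column order follows `geno_samples(geno)`.
#'
#' @param geno genotype tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  assert_geno(geno)
  samples <- geno_samples(geno)
  has_dp <- "dp" %in% names(geno) && any(!is.na(geno$dp))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error: cannot write ", path,
                                           call. = FALSE))
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gbseval",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(hdr, con)
  if (nrow(geno) == 0L) return(invisible(path))

  geno <- sort_sites(geno)
  sites <- distinct_sites(geno)
  key <- paste(geno$chrom, geno$pos, geno$variant_class, sep = ":")
  skey <- paste(sites$chrom, sites$pos, sites$variant_class, sep = ":")
  fld <- gt_to_string(geno$gt)
  if (has_dp) {
    fld <- paste0(fld, ":", ifelse(is.na(geno$dp), ".", geno$dp))
  }
  # site x sample grid in declared sample order
  m <- matrix(".", nrow = nrow(sites), ncol = length(samples))
  m[cbind(match(key, skey), match(geno$sample, samples))] <- fld
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", ".",
                ".", if (has_dp) "GT:DP" else "GT",
                apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Catalogue of sites, restricted to variant classes
#'
#' The catalogue of a pipeline is the set of loci it reports; SNPs and
#' indels are counted separately in the summary tables.
#'
#' @param geno genotype tibble.
#' @param classes variant classes to keep (subset of `c("SNP", "indel")`).
#' @return tibble of distinct sites (`chrom`, `pos`, `variant_class`,
#'   `ref`, `alt`).
#' @export
catalogue_sites <- function(geno, classes = c("SNP", "indel")) {
  classes <- match.arg(classes, several.ok = TRUE)
  dplyr::filter(distinct_sites(geno), .data$variant_class %in% classes)
}
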