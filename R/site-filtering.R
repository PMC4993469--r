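#' Shared site-filter parameters
#'
#' The four filters every pipeline's calls are subjected to before
#' accuracy assessment: a minimum per-call read depth (calls below it are
#' masked to missing), a per-site maximum missing-data fraction, a minimum
#' minor allele frequency among called genotypes, and a purge of sites
#' whose called genotypes are predominantly heterozygous — in a panel of
#' highly homozygous inbred lines such sites are the signature of
#' collapsed paralogs rather than real residual heterozygosity.
#'
#' Boundary semantics: depth `>= min_depth` kept, missing rate
#' `<= max_missing` kept, MAF `>= min_maf` kept, het fraction
#' `> het_locus_threshold` removed (strict).
#'
#' @param min_depth minimum read depth per genotype call (default 2).
#' @param max_missing maximum per-site missing fraction (default 0.80).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param het_locus_threshold heterozygous-call fraction above which a
#'   site is purged (default 0.50).
#' @return a `gbs_filter_params` list.
#' @export
filter_params <- function(min_depth = 2L, max_missing = 0.80,
                          min_maf = 0.05, het_locus_threshold = 0.50) {
  stopifnot(min_depth >= 0,
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1,
            het_locus_threshold >= 0, het_locus_threshold <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 max_missing = max_missing, min_maf = min_maf,
                 het_locus_threshold = het_locus_threshold),
            class = "gbs_filter_params")
}

#' Mask genotype calls below a depth threshold
#'
#' Calls supported by fewer than `min_depth` reads become missing; no site
#' is removed at this stage. A matrix without depth information is
#' returned unchanged with a warning.
#'
#' @param geno genotype tibble.
#' @param min_depth minimum depth.
#' @return genotype tibble with low-depth calls set to `missing`.
#' @export
mask_low_depth <- function(geno, min_depth = 2L) {
  assert_geno(geno)
  if (min_depth <= 0) return(geno)
  if (!"dp" %in% names(geno) || all(is.na(geno$dp))) {
    warning("matrix carries no depth; depth mask is a no-op")
    return(geno)
  }
  low <- !is.na(geno$dp) & geno$dp < min_depth & geno$gt != "missing"
  geno$gt[low] <- "missing"
  geno
}

#' Per-site missingness, allele frequency and heterozygosity
#'
#' MAF is computed from called genotypes only: each non-missing diploid
#' call contributes two alleles (het contributes one of each). A site with
#' no called genotypes reports `maf = 0` and `het_fraction = 0`.
#'
#' @param geno genotype tibble.
#' @return per-site tibble with `n_samples`, `n_missing`, `missing_rate`,
#'   `n_het`, `het_fraction`, `maf`.
#' @export
site_statistics <- function(geno) {
  assert_geno(geno)
  n_samp <- length(geno_samples(geno))
  geno |>
    dplyr::group_by(.data$chrom, .data$pos, .data$variant_class,
                    .data$ref, .data$alt) |>
    dplyr::summarise(
      n_samples = n_samp,
      n_missing = sum(.data$gt == "missing") + (n_samp - dplyr::n()),
      n_called = dplyr::n() - sum(.data$gt == "missing"),
      n_het = sum(.data$gt == "het"),
      alt_alleles = 2L * sum(.data$gt == "hom_alt") + n_het,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      missing_rate = .data$n_missing / .data$n_samples,
      het_fraction = ifelse(.data$n_called > 0,
                            .data$n_het / .data$n_called, 0),
      alt_freq = ifelse(.data$n_called > 0,
                        .data$alt_alleles / (2 * .data$n_called), 0),
      maf = pmin(.data$alt_freq, 1 - .data$alt_freq) *
        (.data$n_called > 0)
    ) |>
    dplyr::select(-"alt_alleles", -"alt_freq")
}

#' Apply the shared site filters
#'
#' Order: depth mask, then site removal by missing rate, then by MAF, then
#' the heterozygous-locus purge. The order matters — masking changes both
#' missingness and allele counts, so it must come first; the het purge is
#' last because it removes sites from the otherwise-final catalogue. Each
#' removed site is logged with the first rule it failed and the measured
#' value; removal is audited so that `removed + retained = input`.
#'
#' @param geno genotype tibble.
#' @param params [filter_params()].
#' @return list with `genotypes` (filtered tibble), `log` (per-removed-site
#'   tibble: site columns, `rule`, `value`) and `summary` (counts per rule
#'   plus retained). The filter is idempotent.
#' @export
apply_filters <- function(geno, params = filter_params()) {
  assert_geno(geno)
  stopifnot(inherits(params, "gbs_filter_params"))
  masked <- if ("dp" %in% names(geno) && any(!is.na(geno$dp))) {
    mask_low_depth(geno, params$min_depth)
  } else geno

  stats <- site_statistics(masked)
  rule <- rep(NA_character_, nrow(stats))
  value <- rep(NA_real_, nrow(stats))
  fail_md <- stats$missing_rate > params$max_missing
  fail_maf <- !fail_md & stats$maf < params$min_maf
  fail_het <- !fail_md & !fail_maf &
    stats$het_fraction > params$het_locus_threshold
  rule[fail_md] <- "max_missing"; value[fail_md] <- stats$missing_rate[fail_md]
  rule[fail_maf] <- "min_maf";    value[fail_maf] <- stats$maf[fail_maf]
  rule[fail_het] <- "het_locus";  value[fail_het] <- stats$het_fraction[fail_het]

  removed <- !is.na(rule)
  log <- dplyr::bind_cols(
    stats[removed, c("chrom", "pos", "variant_class")],
    tibble::tibble(rule = rule[removed], value = value[removed])
  )
  keep_keys <- site_keys(stats[!removed, , drop = FALSE])
  out <- masked[paste(masked$chrom, masked$pos, masked$variant_class,
                      sep = ":") %in% keep_keys, , drop = FALSE]
  out <- new_geno(out, samples = geno_samples(geno))
  summary <- tibble::tibble(
    n_input = nrow(stats),
    n_removed_missing = sum(fail_md),
    n_removed_maf = sum(fail_maf),
    n_removed_het = sum(fail_het),
    n_retained = sum(!removed)
  )
  list(genotypes = out, log = log, summary = summary)
}

#' Count sites exceeding a heterozygosity threshold
#'
#' Sites with strictly more than `threshold` heterozygous calls among
#' called genotypes — the catalogue's likely paralog-collapse loci.
#'
#' @param geno genotype tibble.
#' @param threshold het-call fraction (default 0.5; strict inequality).
#' @return integer count.
#' @export
count_het_loci <- function(geno, threshold = 0.5) {
  sum(site_statistics(geno)$het_fraction > threshold)
}
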