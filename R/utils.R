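# shared internal helpers

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field
#' round half up. Used for every reported percentage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
pct_of <- function(n, total, digits = 1) {
  ifelse(total > 0, round_half_up(100 * n / total, digits), NA_real_)
}

GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")

#' @keywords internal
assert_geno <- function(x, arg = deparse(substitute(x))) {
  need <- c("chrom", "pos", "variant_class", "ref", "alt", "sample", "gt")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("`%s` must be a genotype tibble with columns %s",
                 arg, paste(need, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(x$gt), GT_STATES)
  if (length(bad)) {
    stop(sprintf("`%s` has invalid genotype states: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Site keys of a genotype table
#'
#' A site is identified by (chromosome, 1-based position, variant class);
#' alleles are deliberately excluded so that catalogues from different
#' pipelines can be matched positionally. An indel and a SNP anchored at
#' the same coordinate are distinct sites.
#'
#' @param x genotype tibble, site tibble, or character vector of keys.
#' @return character vector of unique `"chrom:pos:class"` keys.
#' @export
site_keys <- function(x) {
  if (is.character(x)) return(unique(x))
  stopifnot(is.data.frame(x))
  if (!all(c("chrom", "pos", "variant_class") %in% names(x))) {
    stop("need columns chrom, pos, variant_class (or a character key vector)",
         call. = FALSE)
  }
  unique(paste(x$chrom, x$pos, x$variant_class, sep = ":"))
}

#' @keywords internal
chrom_collation <- function(chrom) {
  # natural order: numeric names first (by value), others lexicographic
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

#' @keywords internal
sort_sites <- function(geno) {
  idx <- chrom_collation(geno$chrom)
  geno[order(match(geno$chrom, unique(geno$chrom[idx])), geno$pos,
             geno$variant_class, method = "radix"), , drop = FALSE]
}

#' @keywords internal
distinct_sites <- function(geno) {
  dplyr::distinct(geno, .data$chrom, .data$pos, .data$variant_class,
                  .data$ref, .data$alt)
}

#' @keywords internal
n_sites <- function(geno) nrow(distinct_sites(geno))

#' @keywords internal
n_samples_of <- function(geno) length(unique(geno$sample))
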