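#' Construct a truth set
#'
#' Wraps a truth genotype matrix (e.g. deep whole-genome resequencing
#' calls) together with its completeness convention. `"complete"` means
#' the truth callset covers the genome, so a site absent from it is taken
#' to be invariant (`hom_ref`) in every line; `"partial"` means absent
#' sites are simply not comparable and are excluded from the accuracy
#' denominator. Concordance reports always carry both denominators.
#'
#' @param geno genotype tibble of truth calls.
#' @param completeness `"complete"` (default) or `"partial"`.
#' @return a `gbs_truth` object.
#' @export
truth_set <- function(geno, completeness = c("complete", "partial")) {
  assert_geno(geno)
  structure(list(genotypes = geno, completeness = match.arg(completeness)),
            class = "gbs_truth")
}

#' Number of genotype cells in a matrix
#'
#' Sites times samples — the "number of genotypes" row of the accuracy
#' tables.
#'
#' @param geno genotype tibble (or an integer site count).
#' @param n_samples sample count, required when `geno` is a bare count.
#' @return integer.
#' @export
genotype_cell_count <- function(geno, n_samples = NULL) {
  if (is.numeric(geno)) {
    stopifnot(!is.null(n_samples))
    return(as.integer(geno) * as.integer(n_samples))
  }
  assert_geno(geno)
  n_sites(geno) * length(geno_samples(geno))
}

#' Compare GBS genotype calls to a truth set
#'
#' Scores every non-missing GBS call against the truth genotype at the
#' same site and sample. Missing GBS calls are excluded from the accuracy
#' denominator but counted in the missing-data percentage; truth-missing
#' cells are excluded and counted separately; a heterozygous call against
#' either homozygote is a plain mismatch (no allele half-credit). Sites
#' absent from the truth are scored against `hom_ref` under the
#' `"complete"` convention and excluded under `"partial"`; both
#' denominators are always reported, the headline `accuracy_pct` follows
#' `truth$completeness`.
#'
#' @param geno genotype tibble (typically the output of [apply_filters()]).
#' @param truth a [truth_set()].
#' @param het_loci_purged optional integer carried through to the report
#'   (the count of >50%-heterozygote loci removed upstream).
#' @return a `gbs_concordance` object; see [glance.gbs_concordance()] for
#'   the one-row summary and [tidy.gbs_concordance()] for per-site /
#'   per-sample breakdowns.
#' @export
compare_to_truth <- function(geno, truth, het_loci_purged = NA_integer_) {
  assert_geno(geno)
  stopifnot(inherits(truth, "gbs_truth"))
  samples <- geno_samples(geno)
  tsamples <- geno_samples(truth$genotypes)
  if (nrow(geno) == 0L) {
    empty <- tibble::tibble(site = character(), n_compared = integer(),
                            n_match = integer(), accuracy_pct = double())
    summary <- tibble::tibble(
      n_sites = 0L, n_samples = length(samples), n_genotype_cells = 0L,
      n_missing = 0L, missing_pct = NA_real_, n_het = 0L,
      het_pct = NA_real_, het_loci_purged = het_loci_purged,
      n_truth_missing = 0L, n_absent_from_truth = 0L,
      n_compared_complete = 0L, n_matching_complete = 0L,
      accuracy_complete_pct = NA_real_, n_compared_partial = 0L,
      n_matching_partial = 0L, accuracy_partial_pct = NA_real_,
      completeness = truth$completeness, n_compared = 0L,
      n_matching = 0L, accuracy_pct = NA_real_)
    empty_sample <- tibble::tibble(sample = character(),
                                   n_compared = integer(),
                                   n_match = integer(),
                                   accuracy_pct = double())
    return(structure(list(summary = summary, per_site = empty,
                          per_sample = empty_sample),
                     class = "gbs_concordance"))
  }
  common <- intersect(samples, tsamples)
  if (length(common) == 0L) {
    stop("input error: no overlapping samples between matrix and truth",
         call. = FALSE)
  }
  if (length(common) < length(samples)) {
    warning("samples absent from truth are dropped: ",
            paste(setdiff(samples, common), collapse = ", "))
  }
  g <- geno[geno$sample %in% common, , drop = FALSE]
  tg <- truth$genotypes
  tg <- tg[tg$sample %in% common, c("chrom", "pos", "variant_class",
                                    "sample", "gt")]
  names(tg)[names(tg) == "gt"] <- "gt_truth"

  cmp <- dplyr::left_join(
    g, tg, by = c("chrom", "pos", "variant_class", "sample"))
  cmp$in_truth <- paste(cmp$chrom, cmp$pos, cmp$variant_class, sep = ":") %in%
    site_keys(tg)
  gbs_called <- cmp$gt != "missing"
  truth_missing <- cmp$in_truth &
    (is.na(cmp$gt_truth) | cmp$gt_truth == "missing")
  # absent-from-truth rows under the complete convention score as hom_ref
  truth_complete <- ifelse(cmp$in_truth, cmp$gt_truth, "hom_ref")

  compared_complete <- gbs_called & !truth_missing
  compared_partial <- gbs_called & cmp$in_truth & !truth_missing
  match_cell <- !is.na(truth_complete) & cmp$gt == truth_complete

  n_cells <- genotype_cell_count(g)
  n_missing <- sum(!gbs_called)
  n_het <- sum(cmp$gt == "het")
  n_called <- sum(gbs_called)

  conv <- truth$completeness
  active_cmp <- if (conv == "complete") compared_complete else compared_partial
  per_site <- tibble::tibble(
    site = paste(cmp$chrom, cmp$pos, cmp$variant_class, sep = ":"),
    compared = active_cmp, match = active_cmp & match_cell
  ) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(n_compared = sum(.data$compared),
                     n_match = sum(.data$match), .groups = "drop") |>
    dplyr::mutate(accuracy_pct = pct_of(.data$n_match, .data$n_compared))
  per_sample <- tibble::tibble(
    sample = cmp$sample, compared = active_cmp,
    match = active_cmp & match_cell
  ) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_compared = sum(.data$compared),
                     n_match = sum(.data$match), .groups = "drop") |>
    dplyr::mutate(accuracy_pct = pct_of(.data$n_match, .data$n_compared))

  summary <- tibble::tibble(
    n_sites = n_sites(g),
    n_samples = length(common),
    n_genotype_cells = n_cells,
    n_missing = n_missing,
    missing_pct = pct_of(n_missing, n_cells),
    n_het = n_het,
    het_pct = pct_of(n_het, n_called),
    het_loci_purged = het_loci_purged,
    n_truth_missing = sum(gbs_called & truth_missing),
    n_absent_from_truth = sum(gbs_called & !cmp$in_truth & !truth_missing),
    n_compared_complete = sum(compared_complete),
    n_matching_complete = sum(compared_complete & match_cell),
    accuracy_complete_pct = pct_of(sum(compared_complete & match_cell),
                                   sum(compared_complete)),
    n_compared_partial = sum(compared_partial),
    n_matching_partial = sum(compared_partial & match_cell),
    accuracy_partial_pct = pct_of(sum(compared_partial & match_cell),
                                  sum(compared_partial)),
    completeness = conv
  )
  summary$n_compared <- if (conv == "complete") summary$n_compared_complete
    else summary$n_compared_partial
  summary$n_matching <- if (conv == "complete") summary$n_matching_complete
    else summary$n_matching_partial
  summary$accuracy_pct <- if (conv == "complete")
    summary$accuracy_complete_pct else summary$accuracy_partial_pct

  structure(list(summary = summary, per_site = per_site,
                 per_sample = per_sample),
            class = "gbs_concordance")
}

#' @export
print.gbs_concordance <- function(x, ...) {
  s <- x$summary
  cat("GBS genotype concordance (", s$completeness, " truth convention)\n",
      sep = "")
  cat(sprintf("  sites: %d  samples: %d  genotype cells: %d\n",
              s$n_sites, s$n_samples, s$n_genotype_cells))
  cat(sprintf("  missing: %.1f%%  heterozygous (of called): %.1f%%\n",
              s$missing_pct, s$het_pct))
  cat(sprintf("  accuracy: %.1f%% (%d of %d compared)\n",
              s$accuracy_pct, s$n_matching, s$n_compared))
  invisible(x)
}

#' Side-by-side comparison of two concordance reports
#'
#' Produces the cross-platform / cross-pipeline comparison table (number
#' of sites, missing %, >50%-het loci purged, het %, accuracy %) and, when
#' catalogues are supplied, their positional overlap.
#'
#' @param report_a,report_b `gbs_concordance` objects scored against the
#'   same truth set.
#' @param names labels for the two runs.
#' @param catalogue_a,catalogue_b optional site catalogues (tibbles or key
#'   vectors) for a [platform_overlap()] block.
#' @return a tibble (metric, one column per run, `delta` = a − b); overlap
#'   attached as `attr(, "overlap")`; `attr(, "no_comparison")` is TRUE
#'   when either report has zero sites.
#' @export
cross_platform_compare <- function(report_a, report_b,
                                   names = c("A", "B"),
                                   catalogue_a = NULL, catalogue_b = NULL) {
  stopifnot(inherits(report_a, "gbs_concordance"),
            inherits(report_b, "gbs_concordance"))
  a <- report_a$summary; b <- report_b$summary
  metrics <- c("n_sites", "missing_pct", "het_loci_purged", "het_pct",
               "accuracy_pct")
  out <- tibble::tibble(
    metric = metrics,
    a = as.numeric(unlist(a[1, metrics])),
    b = as.numeric(unlist(b[1, metrics]))
  )
  out$delta <- out$a - out$b
  names(out)[2:3] <- names
  if (!is.null(catalogue_a) && !is.null(catalogue_b)) {
    attr(out, "overlap") <- platform_overlap(catalogue_a, catalogue_b,
                                             names = names)
  }
  attr(out, "no_comparison") <- a$n_sites == 0L || b$n_sites == 0L
  out
}
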