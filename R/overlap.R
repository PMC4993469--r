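#' @keywords internal
as_keys <- function(x, snps_only = FALSE) {
  if (is.data.frame(x) && snps_only &&
      "variant_class" %in% names(x)) {
    x <- x[x$variant_class == "SNP", , drop = FALSE]
  }
  site_keys(x)
}

#' Pairwise overlap between two site catalogues
#'
#' Positional set arithmetic on site keys: `common + only_a = total_a` and
#' `common + only_b = total_b` by construction. Percentages of common
#' sites are reported relative to each catalogue at one decimal
#' (half-up), with integer-rounded variants alongside for comparisons
#' quoted at integer precision.
#'
#' @param cat_a,cat_b site catalogues: tibbles with
#'   `chrom`/`pos`/`variant_class` columns or character key vectors.
#' @param names labels for the two catalogues.
#' @param snps_only restrict tibble catalogues to SNPs (default TRUE;
#'   overlap tables in this methodology count SNP loci).
#' @return one-row tibble: `name_a`, `name_b`, `total_a`, `total_b`,
#'   `common`, `only_a`, `only_b`, `pct_common_of_a`, `pct_common_of_b`,
#'   `pct_common_of_a_int`, `pct_common_of_b_int`.
#' @export
pairwise_overlap <- function(cat_a, cat_b, names = c("A", "B"),
                             snps_only = TRUE) {
  a <- as_keys(cat_a, snps_only); b <- as_keys(cat_b, snps_only)
  common <- length(intersect(a, b))
  tibble::tibble(
    name_a = names[1], name_b = names[2],
    total_a = length(a), total_b = length(b),
    common = common,
    only_a = length(a) - common, only_b = length(b) - common,
    pct_common_of_a = pct_of(common, length(a)),
    pct_common_of_b = pct_of(common, length(b)),
    pct_common_of_a_int = pct_of(common, length(a), 0),
    pct_common_of_b_int = pct_of(common, length(b), 0)
  )
}

#' Cross-platform overlap of one pipeline's catalogues
#'
#' Identical computation to [pairwise_overlap()], labelled as a
#' cross-platform comparison (same pipeline run on reads from two
#' sequencing technologies).
#'
#' @inheritParams pairwise_overlap
#' @return one-row tibble as [pairwise_overlap()] plus
#'   `comparison = "cross_platform"`.
#' @export
platform_overlap <- function(cat_a, cat_b, names = c("A", "B"),
                             snps_only = TRUE) {
  out <- pairwise_overlap(cat_a, cat_b, names = names, snps_only = snps_only)
  out$comparison <- "cross_platform"
  out
}

#' Partition the union of site catalogues by exact membership subset
#'
#' Every site in the union of the catalogues is assigned to the cell for
#' the exact subset of catalogues containing it (the cells of a Venn
#' diagram). Cells are pairwise disjoint, their union is the union of the
#' catalogues, and each catalogue's size equals the sum of the cells whose
#' subset contains it — these conservation identities are asserted on
#' every call.
#'
#' @param catalogues named list of site catalogues (tibbles or key
#'   vectors); 1 to 10 catalogues.
#' @param snps_only restrict tibble catalogues to SNPs.
#' @return a `gbs_overlap_partition`: tibble with `subset` (catalogue
#'   names joined by `"+"`), `n_catalogues`, `n_sites` and a `sites`
#'   list-column of keys; catalogue names in `attr(, "catalogues")`.
#' @export
nway_partition <- function(catalogues, snps_only = TRUE) {
  stopifnot(is.list(catalogues), length(catalogues) >= 1)
  if (length(catalogues) > 10) {
    stop("refusing to partition more than 10 catalogues (cell explosion)",
         call. = FALSE)
  }
  nm <- names(catalogues)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("catalogues must be uniquely named", call. = FALSE)
  }
  keys <- lapply(catalogues, as_keys, snps_only = snps_only)
  universe <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  label <- apply(member, 1L, function(row) paste(nm[row], collapse = "+"))
  cells <- tibble::tibble(site = universe, subset = label,
                          n_catalogues = rowSums(member)) |>
    dplyr::group_by(.data$subset, .data$n_catalogues) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     sites = list(.data$site), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_catalogues), .data$subset)
  # conservation identities
  stopifnot(sum(cells$n_sites) == length(universe))
  for (i in seq_along(nm)) {
    in_cell <- vapply(strsplit(cells$subset, "+", fixed = TRUE),
                      function(s) nm[i] %in% s, logical(1))
    stopifnot(sum(cells$n_sites[in_cell]) == length(keys[[i]]))
  }
  structure(cells, class = c("gbs_overlap_partition", class(cells)),
            catalogues = nm)
}

#' Per-cell accuracy and shared/unique weighted means of a partition
#'
#' For each membership cell, pools the compared and matching genotype
#' counts of the cell's sites over the catalogues that contain them and
#' reports pooled accuracy. Weighted means over shared cells (subset size
#' at least 2) and unique cells (size 1) weight each cell by its compared
#' genotype count. With a single catalogue the shared mean is absent (NA).
#'
#' @param partition a [nway_partition()].
#' @param per_site_accuracy named list (one element per catalogue, names
#'   matching the partition's) of per-site concordance tibbles with
#'   columns `site`, `n_compared`, `n_match` — e.g. the `per_site` element
#'   of [compare_to_truth()].
#' @return a `gbs_partition_accuracy`: the partition tibble plus
#'   `n_compared`, `n_match`, `accuracy_pct`, with the weighted means in
#'   `attr(, "weighted_means")` (also via [glance()]).
#' @export
partition_accuracy <- function(partition, per_site_accuracy) {
  stopifnot(inherits(partition, "gbs_overlap_partition"))
  nm <- attr(partition, "catalogues")
  if (!all(nm %in% names(per_site_accuracy))) {
    stop("per_site_accuracy must cover every catalogue: ",
         paste(setdiff(nm, names(per_site_accuracy)), collapse = ", "),
         call. = FALSE)
  }
  lookup <- lapply(per_site_accuracy[nm], function(d) {
    stopifnot(all(c("site", "n_compared", "n_match") %in% names(d)))
    d
  })
  cell_stats <- purrr::map2_dfr(
    partition$subset, partition$sites,
    function(lab, sites, ...) {
      members <- strsplit(lab, "+", fixed = TRUE)[[1]]
      nc <- 0L; nmatch <- 0L
      for (cat in members) {
        d <- lookup[[cat]]
        hit <- d[d$site %in% sites, , drop = FALSE]
        nc <- nc + sum(hit$n_compared)
        nmatch <- nmatch + sum(hit$n_match)
      }
      tibble::tibble(n_compared = nc, n_match = nmatch)
    })
  out <- dplyr::bind_cols(partition, cell_stats)
  out$accuracy_pct <- pct_of(out$n_match, out$n_compared)
  wm <- function(rows) {
    nc <- sum(out$n_compared[rows])
    if (!any(rows) || nc == 0) return(NA_real_)
    pct_of(sum(out$n_match[rows]), nc)
  }
  means <- tibble::tibble(
    shared_weighted_accuracy_pct =
      if (length(nm) < 2) NA_real_ else wm(out$n_catalogues >= 2),
    unique_weighted_accuracy_pct = wm(out$n_catalogues == 1)
  )
  structure(out, class = c("gbs_partition_accuracy",
                           "gbs_overlap_partition", class(partition)[-1]),
            catalogues = nm, weighted_means = means)
}
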