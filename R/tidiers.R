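#' Tidy a concordance report
#'
#' @param x a `gbs_concordance` object.
#' @param unit `"site"` (default) or `"sample"` breakdown.
#' @param ... unused.
#' @return per-site or per-sample tibble with `n_compared`, `n_match`,
#'   `accuracy_pct`.
#' @export
tidy.gbs_concordance <- function(x, unit = c("site", "sample"), ...) {
  unit <- match.arg(unit)
  if (unit == "site") x$per_site else x$per_sample
}

#' One-row summary of a concordance report
#'
#' @param x a `gbs_concordance` object.
#' @param ... unused.
#' @return one-row tibble (sites, samples, missing %, het %, both
#'   accuracy conventions and the headline accuracy).
#' @export
glance.gbs_concordance <- function(x, ...) x$summary

#' @export
autoplot.gbs_concordance <- function(object, ...) {
  d <- object$per_sample
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$sample,
                                                     .data$accuracy_pct),
                                  y = .data$accuracy_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Genotype accuracy (%)",
                  title = "Per-sample concordance with truth") +
    ggplot2::theme_minimal()
}

#' Tidy an overlap partition
#'
#' @param x a `gbs_overlap_partition` (or `gbs_partition_accuracy`).
#' @param ... unused.
#' @return the cell tibble without the site list-column.
#' @export
tidy.gbs_overlap_partition <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$sites <- NULL
  out
}

#' Weighted-mean accuracy of shared vs unique partition cells
#'
#' @param x a `gbs_partition_accuracy`.
#' @param ... unused.
#' @return one-row tibble with the two weighted means.
#' @export
glance.gbs_partition_accuracy <- function(x, ...) {
  attr(x, "weighted_means")
}

#' @export
autoplot.gbs_overlap_partition <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$sites <- NULL
  has_acc <- "accuracy_pct" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$subset, .data$n_sites),
    y = .data$n_sites,
    fill = factor(.data$n_catalogues))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SNP loci in cell",
                  fill = "Catalogues",
                  title = "Catalogue overlap partition") +
    ggplot2::theme_minimal()
  if (has_acc) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$accuracy_pct)),
      hjust = -0.05, size = 3)
  }
  p
}

#' Tidy attribution results
#'
#' @param x a `gbs_attribution` object.
#' @param ... unused.
#' @return the per-site records tibble.
#' @export
tidy.gbs_attribution <- function(x, ...) x$records

#' Per-pipeline attribution summary
#'
#' @param x a `gbs_attribution` object.
#' @param ... unused.
#' @return the summary tibble (one row per pipeline).
#' @export
glance.gbs_attribution <- function(x, ...) x$summary

#' @export
autoplot.gbs_attribution <- function(object, ...) {
  d <- object$records
  d <- d[d$sharing == "unique", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pipeline, fill = .data$cause)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "Unique inaccurate sites",
                  fill = "Cause",
                  title = "Attribution of unique inaccurate SNP calls") +
    ggplot2::theme_minimal()
}

#' Tidy a demultiplexing report
#'
#' @param x a `gbs_demux` object.
#' @param ... unused.
#' @return per-sample read-count tibble (including the unassigned row).
#' @export
tidy.gbs_demux <- function(x, ...) x$counts

#' Totals of a demultiplexing report
#'
#' @param x a `gbs_demux` object.
#' @param ... unused.
#' @return one-row tibble with total, assigned, unassigned counts and the
#'   unassigned fraction.
#' @export
glance.gbs_demux <- function(x, ...) x$totals

#' @export
autoplot.gbs_demux <- function(object, ...) {
  d <- object$counts
  d$is_unassigned <- d$sample == "unassigned"
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$sample,
                                                     .data$n_reads),
                                  y = .data$n_reads,
                                  fill = .data$is_unassigned)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Reads",
                  title = "Reads per sample after demultiplexing") +
    ggplot2::theme_minimal()
}
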