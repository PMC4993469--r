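#' Paralogy decision rule for read hits
#'
#' A supporting read is deemed to originate from a paralogue when it has
#' at least `min_hits` genomic hits, each covering the full read
#' (`coverage >= min_coverage`) at high identity
#' (`identity >= min_identity`). Defaults follow the rule "at least 2 hits
#' with 100% coverage and a minimum of 96% identity".
#'
#' @param min_hits minimum qualifying hits (>= 2).
#' @param min_coverage minimum aligned fraction of the read query.
#' @param min_identity minimum alignment identity fraction.
#' @return a `gbs_paralogy_rule` list.
#' @export
paralogy_rule <- function(min_hits = 2L, min_coverage = 1.00,
                          min_identity = 0.96) {
  stopifnot(min_hits >= 2, min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(min_hits = as.integer(min_hits),
                 min_coverage = min_coverage, min_identity = min_identity),
            class = "gbs_paralogy_rule")
}

#' Assemble read-alignment evidence for sites
#'
#' Evidence is a long tibble of hit records for the reads supporting each
#' site, against the normal reference and (optionally) the hard-masked
#' reference. Whether masked-reference evidence exists at all is recorded
#' on the object: without it, multi-position sites cannot be split into
#' repetitive vs paralogous and are reported `unresolved_no_evidence`.
#'
#' @param hits tibble with columns `site` (site key), `read_id`,
#'   `reference` (`"normal"` or `"masked"`), `target`, `start`, `end`,
#'   `coverage`, `identity`.
#' @param has_masked whether masked-reference remapping was performed;
#'   defaults to the presence of any `"masked"` row.
#' @return a `gbs_evidence` tibble.
#' @export
alignment_evidence <- function(hits,
                               has_masked = any(hits$reference == "masked")) {
  need <- c("site", "read_id", "reference", "target", "start", "end",
            "coverage", "identity")
  stopifnot(is.data.frame(hits), all(need %in% names(hits)))
  bad <- setdiff(unique(hits$reference), c("normal", "masked"))
  if (length(bad)) stop("reference must be 'normal' or 'masked'",
                        call. = FALSE)
  stopifnot(all(hits$coverage >= 0 & hits$coverage <= 1),
            all(hits$identity >= 0 & hits$identity <= 1))
  structure(tibble::as_tibble(hits),
            class = c("gbs_evidence", class(tibble::tibble())),
            has_masked = has_masked)
}

#' Read BLAST tabular hits (outfmt-6 dialect) as evidence rows
#'
#' Expects the columns `qseqid sseqid pident length qlen sstart send`;
#' coverage is `length / qlen` and identity `pident / 100`. The query id
#' names the read; the read-to-site assignment is supplied separately.
#'
#' @param path TSV file of hits (no header).
#' @param read_sites tibble mapping `read_id` to `site` key.
#' @param reference `"normal"` or `"masked"`.
#' @return a `gbs_evidence` tibble (single-reference; combine normal and
#'   masked tables with [combine_evidence()]).
#' @export
read_blast_hits <- function(path, read_sites,
                            reference = c("normal", "masked")) {
  reference <- match.arg(reference)
  raw <- readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "qlen",
                  "sstart", "send"),
    col_types = "ccdddii", progress = FALSE)
  stopifnot(all(c("read_id", "site") %in% names(read_sites)))
  hits <- raw |>
    dplyr::transmute(
      read_id = .data$qseqid,
      reference = reference,
      target = .data$sseqid,
      start = pmin(.data$sstart, .data$send),
      end = pmax(.data$sstart, .data$send),
      coverage = pmin(.data$length / .data$qlen, 1),
      identity = .data$pident / 100
    ) |>
    dplyr::inner_join(read_sites, by = "read_id")
  alignment_evidence(hits, has_masked = reference == "masked")
}

#' Combine evidence tables (e.g. normal + masked references)
#'
#' @param ... `gbs_evidence` tibbles.
#' @return a single `gbs_evidence` tibble; `has_masked` is TRUE if any
#'   input had masked evidence.
#' @export
combine_evidence <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "gbs_evidence")))
  alignment_evidence(
    dplyr::bind_rows(lapply(parts, tibble::as_tibble)),
    has_masked = any(vapply(parts, function(p) isTRUE(attr(p, "has_masked")),
                            logical(1))))
}

#' Split sites into accurate and inaccurate
#'
#' A site is inaccurate when its pooled per-site accuracy falls below
#' `threshold`; at the default `threshold = 1` this is "any mismatching
#' compared genotype". Sites with no compared genotypes are counted
#' accurate (no evidence of error).
#'
#' @param per_site per-site concordance tibble (`site`, `n_compared`,
#'   `n_match`), e.g. `compare_to_truth(...)$per_site`.
#' @param threshold accuracy fraction below which a site is inaccurate.
#' @return list with `accurate` and `inaccurate` character key vectors.
#' @export
split_accurate <- function(per_site, threshold = 1) {
  stopifnot(all(c("site", "n_compared", "n_match") %in% names(per_site)))
  acc <- ifelse(per_site$n_compared > 0,
                per_site$n_match / per_site$n_compared, 1)
  list(accurate = per_site$site[acc >= threshold],
       inaccurate = per_site$site[acc < threshold])
}

#' Label inaccurate sites as unique to one pipeline or shared
#'
#' A site is `unique` when it is inaccurate in exactly one pipeline's
#' catalogue, `shared` when inaccurate in two or more. With a single
#' pipeline no sharing can be assessed and every site is
#' `not_applicable` (with a warning).
#'
#' @param inaccurate_by_pipeline named list of inaccurate site-key vectors,
#'   one per pipeline.
#' @return tibble `site`, `pipeline`, `n_pipelines_inaccurate`, `sharing`.
#' @export
classify_sharing <- function(inaccurate_by_pipeline) {
  stopifnot(is.list(inaccurate_by_pipeline),
            !is.null(names(inaccurate_by_pipeline)))
  long <- tibble::tibble(
    pipeline = rep(names(inaccurate_by_pipeline),
                   lengths(inaccurate_by_pipeline)),
    site = unlist(inaccurate_by_pipeline, use.names = FALSE)
  )
  if (length(inaccurate_by_pipeline) < 2) {
    warning("single pipeline: sharing is not assessable")
    long$n_pipelines_inaccurate <- 1L
    long$sharing <- "not_applicable"
    return(long)
  }
  long |>
    dplyr::add_count(.data$site, name = "n_pipelines_inaccurate") |>
    dplyr::mutate(sharing = ifelse(.data$n_pipelines_inaccurate == 1L,
                                   "unique", "shared"))
}

#' @keywords internal
merged_locus_count <- function(target, start, end) {
  # distinct loci = non-overlapping intervals after merging overlaps
  total <- 0L
  for (t in unique(target)) {
    i <- target == t
    total <- total +
      length(IRanges::reduce(IRanges::IRanges(start = start[i],
                                              end = end[i])))
  }
  total
}

#' Does a site's read support map to one locus or several?
#'
#' A read is multi-hit when its normal-reference hits, after merging
#' overlapping target intervals, span two or more distinct loci. Under the
#' default `"any"` aggregation a site is `multiple_positions` as soon as
#' any supporting read is multi-hit; `"majority"` requires more than half
#' of the supporting reads.
#'
#' @param sites site keys to classify.
#' @param evidence a [alignment_evidence()] tibble.
#' @param aggregate `"any"` (default) or `"majority"`.
#' @return tibble `site`, `multiplicity` (`unique_position`,
#'   `multiple_positions`, or `unresolved_no_evidence` when the site has
#'   no normal-reference hits).
#' @export
mapping_multiplicity <- function(sites, evidence, aggregate = c("any",
                                                                "majority")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(evidence, "gbs_evidence"))
  ev <- evidence[evidence$reference == "normal" &
                   evidence$site %in% sites, , drop = FALSE]
  per_read <- ev |>
    dplyr::group_by(.data$site, .data$read_id) |>
    dplyr::summarise(
      n_loci = merged_locus_count(.data$target, .data$start, .data$end),
      .groups = "drop")
  per_site <- per_read |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      multi = if (aggregate == "any") any(.data$n_loci >= 2)
              else mean(.data$n_loci >= 2) > 0.5,
      .groups = "drop")
  out <- tibble::tibble(site = sites) |>
    dplyr::left_join(per_site, by = "site")
  out$multiplicity <- dplyr::case_when(
    is.na(out$multi) ~ "unresolved_no_evidence",
    out$multi ~ "multiple_positions",
    TRUE ~ "unique_position")
  out$multi <- NULL
  out
}

#' Repetitive-region test by masked-reference remapping
#'
#' For sites whose reads map to multiple positions: when the supporting
#' reads have no hits at all on the hard-masked reference, the locus
#' vanished under masking — the site is attributed to repetitive
#' sequence. Sites whose reads still map to the masked reference are
#' retained for the paralogy test. If the evidence carries no
#' masked-reference remapping at all, sites are `unresolved_no_evidence`.
#'
#' @param sites site keys (normally the `multiple_positions` ones).
#' @param evidence a [alignment_evidence()] tibble.
#' @return tibble `site`, `masked_class` (`repetitive`, `retained`, or
#'   `unresolved_no_evidence`).
#' @export
masked_remap_class <- function(sites, evidence) {
  stopifnot(inherits(evidence, "gbs_evidence"))
  if (!isTRUE(attr(evidence, "has_masked"))) {
    return(tibble::tibble(site = sites,
                          masked_class = "unresolved_no_evidence"))
  }
  masked_sites <- unique(evidence$site[evidence$reference == "masked"])
  tibble::tibble(
    site = sites,
    masked_class = ifelse(sites %in% masked_sites, "retained", "repetitive"))
}

#' Paralogy test on retained multi-position sites
#'
#' A site is paralogous when at least one supporting read satisfies the
#' [paralogy_rule()]: `min_hits` or more normal-reference hits, each at
#' full coverage and high identity. The reported `n_hits` (max qualifying
#' hits over supporting reads) feeds the mean-hits-per-paralogous-site
#' statistic.
#'
#' @param sites site keys retained after the masked-remap test.
#' @param evidence a [alignment_evidence()] tibble.
#' @param rule a [paralogy_rule()].
#' @return tibble `site`, `paralog_class` (`paralogous` / `unresolved`),
#'   `n_hits`.
#' @export
paralogy_test <- function(sites, evidence, rule = paralogy_rule()) {
  stopifnot(inherits(evidence, "gbs_evidence"),
            inherits(rule, "gbs_paralogy_rule"))
  ev <- evidence[evidence$reference == "normal" &
                   evidence$site %in% sites, , drop = FALSE]
  qual <- ev$coverage >= rule$min_coverage & ev$identity >= rule$min_identity
  per_read <- tibble::tibble(site = ev$site, read_id = ev$read_id,
                             qual = qual) |>
    dplyr::group_by(.data$site, .data$read_id) |>
    dplyr::summarise(n_qual = sum(.data$qual), .groups = "drop")
  per_site <- per_read |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(n_hits = max(.data$n_qual), .groups = "drop")
  out <- tibble::tibble(site = sites) |>
    dplyr::left_join(per_site, by = "site")
  out$n_hits[is.na(out$n_hits)] <- 0L
  out$paralog_class <- ifelse(out$n_hits >= rule$min_hits,
                              "paralogous", "unresolved")
  out
}

#' Attribute unique inaccurate sites to their likely cause
#'
#' Runs the systematic decision tree over every pipeline: split sites into
#' accurate/inaccurate against truth, keep the inaccurate sites unique to
#' one pipeline, classify their read support as single- vs
#' multi-position, test multi-position sites for repetitive origin by
#' masked-reference remapping, and test the remainder for paralogy. Every
#' unique inaccurate site receives exactly one terminal cause:
#' `caller_error` (unique mapping position — the variant caller itself
#' erred), `repetitive`, `paralogous`, `unresolved` (multi-position but
#' failing both structural tests), or `unresolved_no_evidence`.
#'
#' @param catalogues named list of site catalogues (tibbles or key
#'   vectors), one per pipeline.
#' @param per_site_accuracy named list of per-site concordance tibbles
#'   (`site`, `n_compared`, `n_match`), one per pipeline.
#' @param evidence named list of [alignment_evidence()] tibbles per
#'   pipeline, or a single evidence tibble shared by all.
#' @param rule a [paralogy_rule()].
#' @param accuracy_threshold per-site accuracy below which a site is
#'   inaccurate (default 1: any mismatch).
#' @return a `gbs_attribution` object: `records` (site, pipeline, sharing,
#'   cause, n_hits) and `summary` (per-pipeline counts and percentages in
#'   the shape of the unique-inaccurate-SNP characteristics table).
#' @export
attribute_errors <- function(catalogues, per_site_accuracy, evidence,
                             rule = paralogy_rule(),
                             accuracy_threshold = 1) {
  nm <- names(catalogues)
  stopifnot(!is.null(nm), all(nm %in% names(per_site_accuracy)))
  if (inherits(evidence, "gbs_evidence")) {
    evidence <- stats::setNames(rep(list(evidence), length(nm)), nm)
  }
  stopifnot(all(nm %in% names(evidence)))

  inaccurate <- lapply(nm, function(p) {
    split_accurate(per_site_accuracy[[p]], accuracy_threshold)$inaccurate
  })
  names(inaccurate) <- nm
  sharing <- classify_sharing(inaccurate)

  records <- sharing
  records$cause <- ifelse(records$sharing == "unique",
                          NA_character_, "not_applicable")
  records$n_hits <- NA_integer_
  for (p in nm) {
    idx <- which(records$pipeline == p & records$sharing == "unique")
    if (!length(idx)) next
    s <- records$site[idx]
    ev <- evidence[[p]]
    mm <- mapping_multiplicity(s, ev)
    cause <- stats::setNames(rep(NA_character_, length(s)), s)
    cause[mm$site[mm$multiplicity == "unique_position"]] <- "caller_error"
    cause[mm$site[mm$multiplicity == "unresolved_no_evidence"]] <-
      "unresolved_no_evidence"
    multi <- mm$site[mm$multiplicity == "multiple_positions"]
    if (length(multi)) {
      mc <- masked_remap_class(multi, ev)
      cause[mc$site[mc$masked_class == "repetitive"]] <- "repetitive"
      cause[mc$site[mc$masked_class == "unresolved_no_evidence"]] <-
        "unresolved_no_evidence"
      retained <- mc$site[mc$masked_class == "retained"]
      if (length(retained)) {
        pt <- paralogy_test(retained, ev, rule)
        cause[pt$site] <- pt$paralog_class
        hits <- stats::setNames(pt$n_hits, pt$site)
        records$n_hits[idx][match(names(hits), s)] <- hits
      }
    }
    records$cause[idx] <- unname(cause[s])
  }
  summary <- attribution_summary(records,
                                 catalogue_sizes = vapply(
                                   lapply(catalogues, as_keys),
                                   length, integer(1)))
  structure(list(records = records, summary = summary),
            class = "gbs_attribution")
}

#' Summarise attribution records per pipeline
#'
#' Builds the count/percentage summary of unique inaccurate sites per
#' pipeline. Percentages use the published denominators: unique
#' inaccurate as % of the pipeline's catalogue; unique- and
#' multiple-position as % of unique inaccurate; repetitive, paralogous and
#' unresolved as % of multiple-position. Counts are authoritative and
#' percentages are always recomputed from them.
#'
#' @param records attribution records tibble (`site`, `pipeline`,
#'   `sharing`, `cause`, optionally `n_hits`).
#' @param catalogue_sizes named integer vector of catalogue sizes per
#'   pipeline (for the %-of-catalogue row); NA when omitted.
#' @return per-pipeline summary tibble.
#' @export
attribution_summary <- function(records, catalogue_sizes = NULL) {
  stopifnot(all(c("site", "pipeline", "sharing", "cause") %in%
                  names(records)))
  if (!"n_hits" %in% names(records)) records$n_hits <- NA_integer_
  pipes <- unique(records$pipeline)
  purrr::map_dfr(pipes, function(p) {
    r <- records[records$pipeline == p & records$sharing == "unique", ,
                 drop = FALSE]
    n_ui <- nrow(r)
    n_unique_pos <- sum(r$cause == "caller_error")
    n_rep <- sum(r$cause == "repetitive")
    n_par <- sum(r$cause == "paralogous")
    n_unres <- sum(r$cause == "unresolved")
    n_noev <- sum(r$cause == "unresolved_no_evidence")
    n_multi <- n_rep + n_par + n_unres
    cat_size <- if (!is.null(catalogue_sizes) && p %in% names(catalogue_sizes))
      catalogue_sizes[[p]] else NA_integer_
    tibble::tibble(
      pipeline = p,
      catalogue_size = cat_size,
      unique_inaccurate = n_ui,
      pct_of_catalogue = pct_of(n_ui, cat_size),
      unique_position = n_unique_pos,
      pct_unique_position = pct_of(n_unique_pos, n_ui),
      multiple_position = n_multi,
      pct_multiple_position = pct_of(n_multi, n_ui),
      repetitive = n_rep,
      pct_repetitive = pct_of(n_rep, n_multi),
      paralogous = n_par,
      pct_paralogous = pct_of(n_par, n_multi),
      unresolved = n_unres,
      pct_unresolved = pct_of(n_unres, n_multi),
      unresolved_no_evidence = n_noev,
      mean_hits_paralogous =
        if (n_par > 0) mean(r$n_hits[r$cause == "paralogous"], na.rm = TRUE)
        else NA_real_
    )
  })
}

#' @export
print.gbs_attribution <- function(x, ...) {
  cat("Attribution of unique inaccurate sites\n")
  print(x$summary)
  invisible(x)
}
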