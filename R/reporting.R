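#' Configuration for a full evaluation run
#'
#' Either a synthetic-study parameter block or real input paths must be
#' given (not neither). Real inputs are per-pipeline VCFs plus a truth
#' VCF; read-alignment evidence may be supplied as evidence TSVs (see
#' [read_evidence_tsv()]) or prebuilt [alignment_evidence()] objects, and
#' reads as a FASTQ + barcode TSV for the demultiplexing table.
#'
#' @param sim optional [sim_params()] block.
#' @param pipeline_vcfs named character vector of per-pipeline VCF paths.
#' @param truth_vcf truth VCF path.
#' @param truth_completeness `"complete"` or `"partial"`.
#' @param evidence named list (per pipeline) of evidence TSV paths or
#'   `gbs_evidence` objects.
#' @param reads_fastq,barcode_tsv optional demultiplexing inputs.
#' @param filter a [filter_params()].
#' @param rule a [paralogy_rule()].
#' @param reference_pipeline anchor for the pairwise overlap table
#'   (default: first pipeline).
#' @param simulate_reads when `sim` is given, also simulate reads and
#'   report demultiplexing (default TRUE).
#' @return a `gbs_run_config` list.
#' @export
run_config <- function(sim = NULL, pipeline_vcfs = NULL, truth_vcf = NULL,
                       truth_completeness = "complete", evidence = NULL,
                       reads_fastq = NULL, barcode_tsv = NULL,
                       filter = filter_params(), rule = paralogy_rule(),
                       reference_pipeline = NULL, simulate_reads = TRUE) {
  if (is.null(sim) && (is.null(pipeline_vcfs) || is.null(truth_vcf))) {
    stop("config error: provide either `sim` or pipeline_vcfs + truth_vcf",
         call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "gbs_sim_params"))
  structure(list(sim = sim, pipeline_vcfs = pipeline_vcfs,
                 truth_vcf = truth_vcf,
                 truth_completeness = truth_completeness,
                 evidence = evidence, reads_fastq = reads_fastq,
                 barcode_tsv = barcode_tsv, filter = filter, rule = rule,
                 reference_pipeline = reference_pipeline,
                 simulate_reads = simulate_reads),
            class = "gbs_run_config")
}

#' Read an evidence TSV written by [run_study()]/[write_evidence_tsv()]
#'
#' @param path TSV with header columns site, read_id, reference, target,
#'   start, end, coverage, identity.
#' @return a [alignment_evidence()] tibble.
#' @export
read_evidence_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = "cccciidd", progress = FALSE)
  alignment_evidence(d)
}

#' @rdname read_evidence_tsv
#' @param evidence a `gbs_evidence` tibble.
#' @export
write_evidence_tsv <- function(evidence, path) {
  readr::write_tsv(tibble::as_tibble(evidence), path)
  invisible(path)
}

#' Run the complete evaluation and write the report tables
#'
#' Orchestrates filtering, truth concordance, catalogue overlap,
#' error attribution and (when reads are available) demultiplexing from a
#' single config, writing the paper-shaped TSV tables plus a JSON
#' manifest recording every parameter. Reruns of the same config produce
#' byte-identical tables.
#'
#' Written files: `catalogue_summary.tsv`, `concordance.tsv`,
#' `overlap_pairwise.tsv`, `overlap_partition.tsv`, `attribution.tsv`,
#' `demux.tsv` (when reads are supplied), `manifest.json`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results and `dir`.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "gbs_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  demux_report <- NULL
  if (!is.null(config$sim)) {
    study <- simulate_gbs_study(config$sim,
                                reads = isTRUE(config$simulate_reads))
    raw_calls <- study$calls
    truth <- study$truth
    evidence <- study$evidence
    if (!is.null(study$reads)) {
      demux_report <- assign_reads(study$reads, study$barcodes,
                                   max_mismatch = 0L)
    }
    seed <- config$sim$seed
  } else {
    raw_calls <- lapply(config$pipeline_vcfs, read_vcf)
    truth <- truth_set(read_vcf(config$truth_vcf),
                       completeness = config$truth_completeness)
    evidence <- lapply(config$evidence, function(e) {
      if (inherits(e, "gbs_evidence")) e else read_evidence_tsv(e)
    })
    if (!is.null(config$reads_fastq) && !is.null(config$barcode_tsv)) {
      demux_report <- assign_reads(config$reads_fastq,
                                   read_barcode_table(config$barcode_tsv),
                                   max_mismatch = 0L)
    }
    seed <- NA_integer_
  }
  pipes <- names(raw_calls)
  ref_pipe <- config$reference_pipeline %||% pipes[1]
  stopifnot(ref_pipe %in% pipes)

  filtered <- list(); concord <- list(); catalogues <- list()
  filter_summaries <- list()
  for (p in pipes) {
    fr <- apply_filters(raw_calls[[p]], config$filter)
    filtered[[p]] <- fr$genotypes
    filter_summaries[[p]] <- fr$summary
    concord[[p]] <- compare_to_truth(
      fr$genotypes, truth,
      het_loci_purged = fr$summary$n_removed_het)
    catalogues[[p]] <- site_keys(
      catalogue_sites(fr$genotypes, classes = "SNP"))
  }

  catalogue_summary <- purrr::map_dfr(pipes, function(p) {
    cs <- catalogue_sites(filtered[[p]])
    tibble::tibble(pipeline = p,
                   n_snps = sum(cs$variant_class == "SNP"),
                   n_indels = sum(cs$variant_class == "indel"),
                   n_input_sites = filter_summaries[[p]]$n_input,
                   n_removed_missing = filter_summaries[[p]]$n_removed_missing,
                   n_removed_maf = filter_summaries[[p]]$n_removed_maf,
                   n_removed_het = filter_summaries[[p]]$n_removed_het)
  })
  concordance_tbl <- purrr::map_dfr(pipes, function(p) {
    dplyr::bind_cols(tibble::tibble(pipeline = p), concord[[p]]$summary)
  })

  others <- setdiff(pipes, ref_pipe)
  overlap_pairwise <- purrr::map_dfr(others, function(p) {
    pairwise_overlap(catalogues[[p]], catalogues[[ref_pipe]],
                     names = c(p, ref_pipe))
  })

  per_site <- lapply(concord, `[[`, "per_site")
  partition <- nway_partition(catalogues)
  pacc <- partition_accuracy(partition, per_site)
  partition_tbl <- tibble::as_tibble(pacc)[, c("subset", "n_catalogues",
                                               "n_sites", "n_compared",
                                               "n_match", "accuracy_pct")]
  wm <- attr(pacc, "weighted_means")

  attribution <- if (length(pipes) >= 2 && length(evidence)) {
    attribute_errors(catalogues, per_site, evidence, rule = config$rule)
  } else NULL

  readr::write_tsv(catalogue_summary, file.path(out_dir,
                                                "catalogue_summary.tsv"))
  readr::write_tsv(concordance_tbl, file.path(out_dir, "concordance.tsv"))
  readr::write_tsv(overlap_pairwise, file.path(out_dir,
                                               "overlap_pairwise.tsv"))
  readr::write_tsv(partition_tbl, file.path(out_dir, "overlap_partition.tsv"))
  if (!is.null(attribution)) {
    readr::write_tsv(attribution$summary, file.path(out_dir,
                                                    "attribution.tsv"))
  }
  if (!is.null(demux_report)) {
    demux_tbl <- dplyr::bind_cols(
      demux_report$counts,
      tibble::tibble(total_reads = demux_report$totals$total_reads,
                     unassigned_fraction =
                       demux_report$totals$unassigned_fraction))
    readr::write_tsv(demux_tbl, file.path(out_dir, "demux.tsv"))
  }
  manifest <- list(
    package = "gbseval",
    seed = seed,
    reference_pipeline = ref_pipe,
    pipelines = pipes,
    filter = unclass(config$filter),
    paralogy_rule = unclass(config$rule),
    sim = if (!is.null(config$sim)) {
      s <- unclass(config$sim)
      s$pipelines <- lapply(s$pipelines, unclass)
      s
    },
    weighted_means = as.list(wm)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dir = out_dir, filtered = filtered, concordance = concord,
                 catalogues = catalogues, partition = pacc,
                 overlap_pairwise = overlap_pairwise,
                 attribution = attribution, demux = demux_report,
                 catalogue_summary = catalogue_summary))
}

#' Validate the cross-table identities of a report directory
#'
#' Re-checks, from the written TSVs alone, the arithmetic identities the
#' methodology guarantees: genotype cells = sites x samples, pairwise
#' overlap margins (`common + only_a = total_a`, `common + only_b =
#' total_b`), partition marginal sums against catalogue sizes, and the
#' attribution partition sums. Counts are authoritative; every percentage
#' must be recomputable from counts in the same file.
#'
#' @param dir report directory written by [run_study()].
#' @return tibble (`check`, `table`, `pass`, `detail`); overall pass in
#'   `attr(, "pass")`.
#' @export
validate_tables <- function(dir) {
  checks <- list()
  add <- function(check, table, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, table = table, pass = pass, detail = detail)
  }
  conc <- readr::read_tsv(file.path(dir, "concordance.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  add("n_genotype_cells = n_sites * n_samples", "concordance.tsv",
      all(conc$n_genotype_cells == conc$n_sites * conc$n_samples))
  add("n_matching <= n_compared", "concordance.tsv",
      all(conc$n_matching <= conc$n_compared))
  add("0 <= accuracy_pct <= 100", "concordance.tsv",
      all(is.na(conc$accuracy_pct) |
            (conc$accuracy_pct >= 0 & conc$accuracy_pct <= 100)))

  ov <- readr::read_tsv(file.path(dir, "overlap_pairwise.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  add("common + only_a = total_a", "overlap_pairwise.tsv",
      all(ov$common + ov$only_a == ov$total_a))
  add("common + only_b = total_b", "overlap_pairwise.tsv",
      all(ov$common + ov$only_b == ov$total_b))

  part <- readr::read_tsv(file.path(dir, "overlap_partition.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  cat_sum <- readr::read_tsv(file.path(dir, "catalogue_summary.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  marg_ok <- TRUE
  for (p in cat_sum$pipeline) {
    in_cell <- vapply(strsplit(part$subset, "+", fixed = TRUE),
                      function(s) p %in% s, logical(1))
    marg_ok <- marg_ok &&
      sum(part$n_sites[in_cell]) ==
        cat_sum$n_snps[cat_sum$pipeline == p]
  }
  add("partition marginals = catalogue sizes", "overlap_partition.tsv",
      marg_ok)

  attr_path <- file.path(dir, "attribution.tsv")
  if (file.exists(attr_path)) {
    at <- readr::read_tsv(attr_path, show_col_types = FALSE,
                          progress = FALSE)
    add("unique_position + multiple_position + no_evidence = unique_inaccurate",
        "attribution.tsv",
        all(at$unique_position + at$multiple_position +
              at$unresolved_no_evidence == at$unique_inaccurate))
    add("repetitive + paralogous + unresolved = multiple_position",
        "attribution.tsv",
        all(at$repetitive + at$paralogous + at$unresolved ==
              at$multiple_position))
  }
  demux_path <- file.path(dir, "demux.tsv")
  if (file.exists(demux_path)) {
    dm <- readr::read_tsv(demux_path, show_col_types = FALSE,
                          progress = FALSE)
    add("sum of per-sample reads + unassigned = total", "demux.tsv",
        sum(dm$n_reads) == dm$total_reads[1])
  }
  out <- dplyr::bind_rows(checks)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Export a synthetic study to a directory of standard files
#'
#' FASTA (reference + hard-masked), BED annotations (0-based half-open),
#' truth and per-pipeline VCFs, evidence and label TSVs, barcode TSV,
#' FASTQ reads when present, and a JSON manifest.
#'
#' @param study a [simulate_gbs_study()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "gbs_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(study$reference,
                              file.path(dir, "reference.fa"))
  Biostrings::writeXStringSet(study$masked,
                              file.path(dir, "reference_hardmasked.fa"))
  readr::write_tsv(study$annotations, file.path(dir, "annotations.bed"),
                   col_names = FALSE)
  write_vcf(study$truth$genotypes, file.path(dir, "truth.vcf"))
  for (p in names(study$calls)) {
    write_vcf(study$calls[[p]], file.path(dir, paste0(p, ".vcf")))
    write_evidence_tsv(study$evidence[[p]],
                       file.path(dir, paste0(p, "_hits.tsv")))
  }
  readr::write_tsv(study$labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(tibble::as_tibble(study$barcodes),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  if (!is.null(study$reads)) {
    Biostrings::writeQualityScaledXStringSet(study$reads,
                                             file.path(dir, "reads.fastq"))
  }
  manifest <- unclass(study$params)
  manifest$pipelines <- lapply(manifest$pipelines, unclass)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
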