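#' Parametric error profile of a GBS pipeline
#'
#' Real SNP-calling pipelines differ in how many true sites they discover,
#' how often they miscall a genotype outright, and how prone they are to
#' collapsing paralogous copies or mismapping reads from repeat families.
#' The generator emulates a pipeline as this small parameter vector
#' instead of re-implementing it.
#'
#' @param name profile label.
#' @param sensitivity probability a true polymorphic site enters the
#'   pipeline's catalogue.
#' @param genotype_error per-cell miscall probability at structurally
#'   clean sites (the "caller error" cause).
#' @param paralog_collapse probability a site inside a planted paralog
#'   family is corrupted by collapsed copies.
#' @param repeat_mismap probability a site inside a repeat family is
#'   corrupted by mismapped reads.
#' @param missing_rate per-cell missing probability.
#' @param calls_indels whether the profile reports indels at all.
#' @return a `gbs_pipeline_profile` list.
#' @export
pipeline_profile <- function(name, sensitivity = 0.9, genotype_error = 0.01,
                             paralog_collapse = 0.3, repeat_mismap = 0.3,
                             missing_rate = 0.35, calls_indels = FALSE) {
  rates <- c(sensitivity, genotype_error, paralog_collapse, repeat_mismap,
             missing_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(name = name, sensitivity = sensitivity,
                 genotype_error = genotype_error,
                 paralog_collapse = paralog_collapse,
                 repeat_mismap = repeat_mismap, missing_rate = missing_rate,
                 calls_indels = calls_indels),
            class = "gbs_pipeline_profile")
}

#' Named pipeline presets
#'
#' Three profiles loosely shaped on the behaviours observed across real
#' pipelines: `"fast"` — high sensitivity, very low caller error, modest
#' structural error, reports indels (a Fast-GBS-like best case);
#' `"short_tag"` — aggressive discovery with frequent paralog collapse
#' and repeat mismapping, the signature of very short alignment tags;
#' `"sparse"` — conservative discovery with heavy missingness.
#'
#' @param names subset of `c("fast", "short_tag", "sparse")`.
#' @return named list of [pipeline_profile()]s.
#' @export
pipeline_presets <- function(names = c("fast", "short_tag", "sparse")) {
  all <- list(
    fast = pipeline_profile("fast", sensitivity = 0.95,
                            genotype_error = 0.005, paralog_collapse = 0.15,
                            repeat_mismap = 0.15, missing_rate = 0.30,
                            calls_indels = TRUE),
    short_tag = pipeline_profile("short_tag", sensitivity = 0.90,
                                 genotype_error = 0.02,
                                 paralog_collapse = 0.85,
                                 repeat_mismap = 0.60, missing_rate = 0.28),
    sparse = pipeline_profile("sparse", sensitivity = 0.50,
                              genotype_error = 0.01, paralog_collapse = 0.10,
                              repeat_mismap = 0.10, missing_rate = 0.45)
  )
  names <- match.arg(names, several.ok = TRUE)
  all[names]
}

#' Parameters of a synthetic GBS study
#'
#' The stated world the generator emulates: a medium-sized diploid genome
#' reduced to ApeKI (GCWGC) fragments, 24 highly homozygous inbred lines
#' with ~1% residual heterozygosity, planted segmental duplications
#' (paralog families, mean ~2.4 copies, 94-100% inter-copy identity) and
#' dispersed repeat families, and per-pipeline call matrices generated
#' from parametric error profiles. Reads come in two regimes: fixed
#' 100 bp (Illumina-like, low error) or variable 50-135 bp (Ion
#' Torrent-like, elevated error with occasional indels).
#'
#' @param seed integer; fully determines every generated artifact.
#' @param genome_length total genome size in bp (default 1e6).
#' @param n_chromosomes number of chromosomes (default 2).
#' @param n_sites number of polymorphic truth sites (default 5000).
#' @param paralog_families number of planted duplication families.
#' @param paralog_copy_mean mean genomic copy number of a family
#'   (copies = 2 + Poisson(mean − 2), so the minimum is a true pair).
#' @param paralog_identity inter-copy identity range (uniform draw per
#'   family).
#' @param paralog_length length of each duplicated segment (bp).
#' @param paralog_het_intensity range of the per-site collapse intensity:
#'   when a site collapses, each genotype cell reads heterozygous with a
#'   probability drawn from this range (high intensities push the site
#'   past the >50%-het purge; lower ones leave it in the catalogue as an
#'   inaccurate call).
#' @param repeat_families,repeat_copies,repeat_unit_length repeat family
#'   count, copies per family (>= 5) and unit length.
#' @param motif restriction motif (IUPAC; default ApeKI `"GCWGC"`).
#' @param fragment_window retained fragment size window (bp).
#' @param n_lines number of inbred lines (default 24).
#' @param residual_het_rate residual heterozygosity of the lines.
#' @param maf_spectrum range of the uniform minor-allele-frequency draw.
#' @param indel_fraction fraction of truth sites that are short indels.
#' @param read_profile `"fixed_100bp"` or `"variable_50_135bp"`.
#' @param base_error per-base substitution error in reads (default 0.001
#'   fixed profile, 0.01 variable).
#' @param read_indel_rate per-read single-base indel probability
#'   (variable profile only).
#' @param depth_mean,depth_dispersion negative-binomial read depth per
#'   fragment per line (mean 6, dispersion 2 — a standard GBS coverage
#'   model).
#' @param corrupt_barcode_rate fraction of reads whose barcode is given a
#'   single substitution (for demultiplexing-loss experiments).
#' @param barcode_length barcode length in nt (fixed length, pairwise
#'   Hamming distance >= 2, so one substitution can never reassign a read).
#' @param pipelines named list of [pipeline_profile()]s.
#' @return a `gbs_sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       genome_length = 1e6, n_chromosomes = 2L,
                       n_sites = 5000L,
                       paralog_families = 12L, paralog_copy_mean = 2.4,
                       paralog_identity = c(0.94, 1.00),
                       paralog_length = 1500L,
                       paralog_het_intensity = c(0.2, 1.0),
                       repeat_families = 3L, repeat_copies = 8L,
                       repeat_unit_length = 500L,
                       motif = "GCWGC", fragment_window = c(100L, 400L),
                       n_lines = 24L, residual_het_rate = 0.01,
                       maf_spectrum = c(0.05, 0.5),
                       indel_fraction = 0.10,
                       read_profile = c("fixed_100bp", "variable_50_135bp"),
                       base_error = NULL, read_indel_rate = 0.002,
                       depth_mean = 6, depth_dispersion = 2,
                       corrupt_barcode_rate = 0,
                       barcode_length = 6L,
                       pipelines = pipeline_presets()) {
  read_profile <- match.arg(read_profile)
  if (is.null(base_error)) {
    base_error <- if (read_profile == "fixed_100bp") 0.001 else 0.01
  }
  stopifnot(seed == as.integer(seed), genome_length > 0, n_chromosomes >= 1,
            paralog_copy_mean >= 2, repeat_copies >= 5 || repeat_families == 0,
            residual_het_rate >= 0, residual_het_rate <= 1,
            maf_spectrum[1] >= 0, maf_spectrum[2] <= 0.5,
            corrupt_barcode_rate >= 0, corrupt_barcode_rate <= 1)
  stopifnot(length(pipelines) >= 1,
            all(vapply(pipelines, inherits, logical(1),
                       "gbs_pipeline_profile")))
  if (is.null(names(pipelines))) {
    names(pipelines) <- vapply(pipelines, `[[`, character(1), "name")
  }
  structure(as.list(environment()), class = "gbs_sim_params")
}

#' @keywords internal
random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' @keywords internal
mutate_dna <- function(chars, rate) {
  n_mut <- stats::rbinom(1L, length(chars), rate)
  if (n_mut == 0L) return(chars)
  pos <- sample.int(length(chars), n_mut)
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Generate a reference genome with planted paralogs and repeats
#'
#' Builds a random genome, inserts segmental duplications (each family: a
#' source segment plus 1+ divergent copies at the family's inter-copy
#' identity) and dispersed repeat copies, and derives the hard-masked
#' companion in which every repeat interval is replaced by N. Every
#' planted interval is recorded in a BED-style annotation table
#' (0-based half-open).
#'
#' @param params a [sim_params()].
#' @return list: `reference` and `masked` (`Biostrings::DNAStringSet`),
#'   `annotations` tibble (`chrom`, `start`, `end`, `type`, `family`,
#'   `copy`, `identity`).
#' @export
make_reference <- function(params) {
  stopifnot(inherits(params, "gbs_sim_params"))
  set.seed(params$seed)
  chrom_len <- rep(floor(params$genome_length / params$n_chromosomes),
                   params$n_chromosomes)
  chrom_names <- paste0("chr", seq_len(params$n_chromosomes))
  genome <- lapply(chrom_len, random_dna)
  names(genome) <- chrom_names

  # feature placement on a non-overlapping slot grid
  feat_len <- max(params$paralog_length, params$repeat_unit_length)
  slot <- feat_len + 200L
  slots <- dplyr::bind_rows(lapply(seq_along(chrom_names), function(i) {
    starts <- seq(100L, chrom_len[i] - feat_len - 100L, by = slot)
    tibble::tibble(chrom = chrom_names[i], start = starts)
  }))

  copies_per_family <- if (params$paralog_families > 0) {
    2L + stats::rpois(params$paralog_families, params$paralog_copy_mean - 2)
  } else integer(0)
  n_needed <- sum(copies_per_family) +
    params$repeat_families * params$repeat_copies
  if (n_needed > nrow(slots)) {
    stop(sprintf(
      "parameter error: genome too short for %d planted features (%d slots)",
      n_needed, nrow(slots)), call. = FALSE)
  }
  picked <- slots[sample.int(nrow(slots), n_needed), , drop = FALSE]
  ann <- list(); k <- 0L

  place <- function(chrom, start, chars) {
    genome[[chrom]][start:(start + length(chars) - 1L)] <<- chars
  }

  for (f in seq_len(params$paralog_families)) {
    fam_id <- runif(1, params$paralog_identity[1], params$paralog_identity[2])
    src <- random_dna(params$paralog_length)
    for (cp in seq_len(copies_per_family[f])) {
      k <- k + 1L
      chars <- if (cp == 1L) src else mutate_dna(src, 1 - fam_id)
      place(picked$chrom[k], picked$start[k], chars)
      ann[[k]] <- tibble::tibble(
        chrom = picked$chrom[k], start = picked$start[k] - 1L,
        end = picked$start[k] - 1L + params$paralog_length,
        type = "paralog", family = paste0("par", f), copy = cp,
        identity = fam_id)
    }
  }
  for (f in seq_len(params$repeat_families)) {
    unit <- random_dna(params$repeat_unit_length)
    for (cp in seq_len(params$repeat_copies)) {
      k <- k + 1L
      place(picked$chrom[k], picked$start[k], mutate_dna(unit, 0.01))
      ann[[k]] <- tibble::tibble(
        chrom = picked$chrom[k], start = picked$start[k] - 1L,
        end = picked$start[k] - 1L + params$repeat_unit_length,
        type = "repeat", family = paste0("rep", f), copy = cp,
        identity = 0.99)
    }
  }
  annotations <- if (k > 0) dplyr::bind_rows(ann) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   type = character(), family = character(), copy = integer(),
                   identity = double())

  masked <- genome
  rep_ann <- annotations[annotations$type == "repeat", , drop = FALSE]
  for (i in seq_len(nrow(rep_ann))) {
    idx <- (rep_ann$start[i] + 1L):rep_ann$end[i]
    masked[[rep_ann$chrom[i]]][idx] <- "N"
  }
  to_dss <- function(g) {
    Biostrings::DNAStringSet(vapply(g, paste, character(1), collapse = ""))
  }
  list(reference = to_dss(genome), masked = to_dss(masked),
       annotations = annotations)
}

#' In-silico restriction digest and size selection
#'
#' Scans the reference for the (IUPAC-degenerate) restriction motif —
#' `GCWGC` is its own reverse complement, so a forward scan finds every
#' site — and forms fragments between consecutive motif positions,
#' retaining those whose length falls inside the size-selection window.
#' A fragment spans from one motif start to the base before the next,
#' i.e. motifs at 100 and 350 give the fragment [100, 349], length 250.
#'
#' @param reference `Biostrings::DNAStringSet` (or named character vector).
#' @param motif IUPAC motif (default `"GCWGC"`).
#' @param window length-2 retained size window.
#' @return tibble `chrom`, `start`, `end` (1-based closed), `length`.
#' @export
digest_and_select <- function(reference, motif = "GCWGC",
                              window = c(100L, 400L)) {
  if (is.character(reference)) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  iupac_to_regex(motif)  # validates motif
  m <- Biostrings::vmatchPattern(motif, reference, fixed = FALSE)
  frags <- purrr::map_dfr(seq_along(reference), function(i) {
    starts <- BiocGenerics::start(m[[i]])
    if (length(starts) < 2) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), length = integer()))
    }
    starts <- sort(starts)
    tibble::tibble(chrom = names(reference)[i],
                   start = starts[-length(starts)],
                   end = starts[-1] - 1L,
                   length = diff(starts))
  })
  frags[frags$length >= window[1] & frags$length <= window[2], , drop = FALSE]
}

#' Simulate inbred-line truth genotypes on digest fragments
#'
#' Places polymorphic sites (SNPs and short insertions) on the retained
#' fragments with minor allele frequencies drawn from the configured
#' spectrum. Lines are homozygous at every site except for residual
#' heterozygosity at the stated rate, matching a panel of true-breeding
#' inbred lines.
#'
#' @param params a [sim_params()].
#' @param fragments output of [digest_and_select()].
#' @param reference the reference `DNAStringSet`.
#' @return a [truth_set()] with the `"complete"` convention, carrying the
#'   drawn per-site allele frequency in `attr(, "site_maf")`.
#' @export
simulate_truth <- function(params, fragments, reference) {
  stopifnot(inherits(params, "gbs_sim_params"), nrow(fragments) > 0)
  set.seed(params$seed + 1L)
  ref_chars <- lapply(as.character(reference), function(s)
    strsplit(s, "")[[1]])

  # polymorphic sites avoid the restriction motif itself (a variant there
  # would destroy the cut site and the fragment)
  pos_pool <- tibble::tibble(
    chrom = rep(fragments$chrom, fragments$length - 5L),
    pos = unlist(purrr::map2(fragments$start + 5L, fragments$end, seq),
                 use.names = FALSE))
  n_sites <- min(params$n_sites, nrow(pos_pool))
  if (n_sites < params$n_sites) {
    warning(sprintf("only %d fragment positions available for %d sites",
                    nrow(pos_pool), params$n_sites))
  }
  sel <- pos_pool[sample.int(nrow(pos_pool), n_sites), , drop = FALSE]
  is_indel <- stats::runif(n_sites) < params$indel_fraction
  ref_base <- vapply(seq_len(n_sites), function(i)
    ref_chars[[sel$chrom[i]]][sel$pos[i]], character(1))
  alt <- vapply(seq_len(n_sites), function(i) {
    if (is_indel[i]) paste0(ref_base[i], sample(c("A", "C", "G", "T"), 1))
    else sample(setdiff(c("A", "C", "G", "T"), ref_base[i]), 1)
  }, character(1))
  maf <- stats::runif(n_sites, params$maf_spectrum[1], params$maf_spectrum[2])

  lines <- sprintf("L%02d", seq_len(params$n_lines))
  alt_hom <- matrix(stats::runif(n_sites * params$n_lines) <
                      rep(maf, params$n_lines), nrow = n_sites)
  het <- matrix(stats::runif(n_sites * params$n_lines) <
                  params$residual_het_rate, nrow = n_sites)
  gt <- ifelse(het, "het", ifelse(alt_hom, "hom_alt", "hom_ref"))

  calls <- tibble::tibble(
    chrom = rep(sel$chrom, params$n_lines),
    pos = rep(sel$pos, params$n_lines),
    variant_class = rep(ifelse(is_indel, "indel", "SNP"), params$n_lines),
    ref = rep(ref_base, params$n_lines),
    alt = rep(alt, params$n_lines),
    sample = rep(lines, each = n_sites),
    gt = as.vector(gt),
    dp = NA_integer_)
  calls <- sort_sites(calls)
  ts <- truth_set(new_geno(calls, samples = lines), "complete")
  attr(ts, "site_maf") <- tibble::tibble(
    site = paste(sel$chrom, sel$pos,
                 ifelse(is_indel, "indel", "SNP"), sep = ":"), maf = maf)
  ts
}

#' @keywords internal
flip_state <- function(gt) {
  vapply(gt, function(g) sample(setdiff(c("hom_ref", "het", "hom_alt"), g),
                                1L), character(1), USE.NAMES = FALSE)
}

#' Simulate per-pipeline call matrices with planted error causes
#'
#' For each pipeline profile: true sites enter the catalogue with the
#' profile's sensitivity (indel sites only for indel-calling profiles).
#' Sites inside planted paralog intervals collapse with the profile's
#' paralog-collapse probability — collapsed cells read heterozygous at a
#' per-site intensity, emulating reads pooled across copies; sites inside
#' repeat intervals are mismapped with the repeat-mismap probability —
#' cells are replaced by random states. Remaining sites suffer
#' independent per-cell miscalls at the genotype-error rate. Missingness
#' and negative-binomial depths are applied last. Each erroneous site
#' carries exactly one planted cause label, and read-alignment evidence
#' consistent with the label is emitted (multi-hit, full-coverage,
#' high-identity hits for paralogs; hits that vanish on the hard-masked
#' reference for repeats; unique hits otherwise).
#'
#' @param truth a [simulate_truth()] result.
#' @param params a [sim_params()].
#' @param annotations planted-interval table from [make_reference()].
#' @return list per pipeline name: `calls` (genotype tibbles), `labels`
#'   (tibble `site`, `pipeline`, `label` in clean/caller_error/paralog/
#'   repeat), `evidence` ([alignment_evidence()] tibbles).
#' @export
simulate_pipeline_calls <- function(truth, params, annotations) {
  stopifnot(inherits(truth, "gbs_truth"), inherits(params, "gbs_sim_params"))
  set.seed(params$seed + 2L)
  tg <- truth$genotypes
  sites <- distinct_sites(tg)
  sites$site <- site_keys(sites)
  n_lines <- length(geno_samples(tg))

  in_feature <- function(type) {
    a <- annotations[annotations$type == type, , drop = FALSE]
    hit <- rep(FALSE, nrow(sites))
    fam <- rep(NA_character_, nrow(sites))
    for (i in seq_len(nrow(a))) {
      m <- sites$chrom == a$chrom[i] & sites$pos > a$start[i] &
        sites$pos <= a$end[i]
      hit <- hit | m
      fam[m] <- a$family[i]
    }
    list(hit = hit, family = fam)
  }
  par_f <- in_feature("paralog")
  rep_f <- in_feature("repeat")
  fam_copies <- annotations |>
    dplyr::filter(.data$type == "paralog") |>
    dplyr::count(.data$family, name = "copies")
  fam_identity <- annotations |>
    dplyr::filter(.data$type == "paralog") |>
    dplyr::distinct(.data$family, .data$identity)
  rep_copy_ann <- annotations[annotations$type == "repeat", , drop = FALSE]

  truth_wide <- tg |>
    dplyr::mutate(site = paste(.data$chrom, .data$pos, .data$variant_class,
                               sep = ":"))

  calls <- list(); labels <- list(); evidence <- list()
  for (p in names(params$pipelines)) {
    prof <- params$pipelines[[p]]
    eligible <- prof$calls_indels | sites$variant_class == "SNP"
    discovered <- eligible & stats::runif(nrow(sites)) < prof$sensitivity
    collapse <- discovered & par_f$hit &
      stats::runif(nrow(sites)) < prof$paralog_collapse
    mismap <- discovered & rep_f$hit & !collapse &
      stats::runif(nrow(sites)) < prof$repeat_mismap

    dsites <- sites$site[discovered]
    g <- truth_wide[truth_wide$site %in% dsites, , drop = FALSE]
    g <- g[order(match(g$site, sites$site)), , drop = FALSE]

    status <- rep("clean", nrow(sites))
    status[collapse] <- "paralog"
    status[mismap] <- "repeat"
    site_status <- stats::setNames(status, sites$site)

    cell_status <- site_status[g$site]
    n_cell <- nrow(g)
    gt <- g$gt
    # paralog collapse: cells heterozygous at a per-site intensity
    par_sites <- unique(g$site[cell_status == "paralog"])
    intensity <- stats::setNames(
      stats::runif(length(par_sites), params$paralog_het_intensity[1],
                   params$paralog_het_intensity[2]), par_sites)
    is_par <- cell_status == "paralog"
    make_het <- is_par & stats::runif(n_cell) < intensity[g$site]
    gt[make_het] <- "het"
    # repeat mismap: cells scrambled to random states at rate 0.6
    is_rep <- cell_status == "repeat"
    scramble <- is_rep & stats::runif(n_cell) < 0.6
    gt[scramble] <- sample(c("hom_ref", "het", "hom_alt"), sum(scramble),
                           replace = TRUE)
    # caller error: independent per-cell flips at clean sites
    is_clean <- cell_status == "clean"
    flip <- is_clean & stats::runif(n_cell) < prof$genotype_error
    gt[flip] <- flip_state(g$gt[flip])

    # a clean site with at least one flipped cell is a caller_error site
    err_sites <- unique(g$site[flip & gt != g$gt])
    site_label <- site_status[dsites]
    site_label[site_label == "clean" & dsites %in% err_sites] <- "caller_error"

    # missingness and depth
    miss <- stats::runif(n_cell) < prof$missing_rate
    gt[miss] <- "missing"
    dp <- integer(n_cell)
    dp[!miss] <- 2L + stats::rnbinom(sum(!miss),
                                     mu = max(params$depth_mean - 2, 0.1),
                                     size = params$depth_dispersion)
    dp[miss] <- sample(0:1, sum(miss), replace = TRUE)

    out <- g
    out$gt <- gt
    out$dp <- dp
    out$site <- NULL
    calls[[p]] <- new_geno(tibble::as_tibble(out),
                           samples = geno_samples(tg))
    labels[[p]] <- tibble::tibble(site = dsites, pipeline = p,
                                  label = unname(site_label))
    evidence[[p]] <- build_evidence(dsites, site_status, sites, par_f, rep_f,
                                    fam_copies, fam_identity, rep_copy_ann,
                                    annotations, pipeline = p)
  }
  list(calls = calls,
       labels = dplyr::bind_rows(labels),
       evidence = evidence)
}

#' @keywords internal
build_evidence <- function(dsites, site_status, sites, par_f, rep_f,
                           fam_copies, fam_identity, rep_copy_ann,
                           annotations, pipeline, reads_per_site = 2L) {
  fam_of <- stats::setNames(par_f$family, sites$site)
  repfam_of <- stats::setNames(rep_f$family, sites$site)
  copies_of <- stats::setNames(fam_copies$copies, fam_copies$family)
  ident_of <- stats::setNames(fam_identity$identity, fam_identity$family)
  chrom_of <- stats::setNames(sites$chrom, sites$site)
  pos_of <- stats::setNames(sites$pos, sites$site)
  par_ann <- annotations[annotations$type == "paralog", , drop = FALSE]

  st_all <- site_status[dsites]
  clean <- dsites[st_all == "clean"]
  struct <- dsites[st_all != "clean"]

  # clean sites (the bulk): one unique locus, present on both references
  clean_rows <- NULL
  if (length(clean)) {
    n <- length(clean) * reads_per_site
    site_rep <- rep(clean, each = reads_per_site)
    pos_rep <- pos_of[site_rep]
    base <- tibble::tibble(
      site = site_rep,
      read_id = paste0(site_rep, "|", pipeline, "|r",
                       rep(seq_len(reads_per_site), length(clean))),
      reference = "normal",
      target = chrom_of[site_rep],
      start = pmax(pos_rep - 40L, 1L), end = pos_rep + 60L,
      coverage = 1.0,
      identity = stats::runif(n, 0.98, 1))
    masked <- base
    masked$reference <- "masked"
    clean_rows <- dplyr::bind_rows(base, masked)
  }

  rows <- vector("list", length(struct))
  for (i in seq_along(struct)) {
    s <- struct[i]
    st <- site_status[[s]]
    reads <- paste0(s, "|", pipeline, "|r", seq_len(reads_per_site))
    if (st == "paralog") {
      fam <- fam_of[[s]]
      copies <- par_ann[par_ann$family == fam, , drop = FALSE]
      k <- nrow(copies)
      id <- ident_of[[fam]]
      hit_id <- c(1, stats::runif(k - 1L, id, min(id + 0.01, 1)))
      normal <- tibble::tibble(
        site = s, read_id = rep(reads, each = k),
        reference = "normal",
        target = rep(copies$chrom, reads_per_site),
        start = rep(copies$start + 1L, reads_per_site),
        end = rep(copies$end, reads_per_site),
        coverage = 1.0,
        identity = rep(hit_id, reads_per_site))
      masked <- normal
      masked$reference <- "masked"
      rows[[i]] <- dplyr::bind_rows(normal, masked)
    } else if (st == "repeat") {
      fam <- repfam_of[[s]]
      copies <- rep_copy_ann[rep_copy_ann$family == fam, , drop = FALSE]
      k <- nrow(copies)
      rows[[i]] <- tibble::tibble(
        site = s, read_id = rep(reads, each = k),
        reference = "normal",
        target = rep(copies$chrom, reads_per_site),
        start = rep(copies$start + 1L, reads_per_site),
        end = rep(copies$end, reads_per_site),
        coverage = rep(stats::runif(k, 0.9, 1), reads_per_site),
        identity = rep(stats::runif(k, 0.97, 1), reads_per_site))
    }
  }
  all_rows <- dplyr::bind_rows(c(list(clean_rows), rows))
  if (nrow(all_rows) == 0L) {
    all_rows <- tibble::tibble(
      site = character(), read_id = character(), reference = character(),
      target = character(), start = integer(), end = integer(),
      coverage = double(), identity = double())
  }
  alignment_evidence(all_rows, has_masked = TRUE)
}

#' Simulate barcoded GBS reads
#'
#' Each read is barcode + genomic sequence starting at the cut site (so
#' the ApeKI remnant `CWGC` follows the barcode naturally), carrying the
#' line's SNP alleles, with per-base substitution errors and — in the
#' variable-length profile — occasional single-base indels. Depth per
#' fragment per line is negative-binomial. A configurable fraction of
#' reads gets one barcode substitution, emulating demultiplexer-hostile
#' reads.
#'
#' @param params a [sim_params()].
#' @param fragments output of [digest_and_select()].
#' @param truth a [simulate_truth()] result.
#' @param reference the reference `DNAStringSet`.
#' @param barcodes a [barcode_table()] whose samples match the truth lines.
#' @return list: `reads` (`QualityScaledDNAStringSet`), `origin` (tibble
#'   `read_id`, `sample`, `corrupted`).
#' @export
simulate_reads <- function(params, fragments, truth, reference, barcodes) {
  stopifnot(inherits(params, "gbs_sim_params"),
            inherits(barcodes, "gbs_barcodes"))
  set.seed(params$seed + 3L)
  lines <- geno_samples(truth$genotypes)
  stopifnot(all(lines %in% barcodes$sample))
  bc_of <- stats::setNames(barcodes$barcode, barcodes$sample)

  # per-line genomes: reference with hom_alt/het SNP alleles substituted
  ref_chars <- lapply(as.character(reference), function(s)
    strsplit(s, "")[[1]])
  tg <- truth$genotypes
  snp <- tg[tg$variant_class == "SNP" & tg$gt != "hom_ref", , drop = FALSE]
  line_seq <- list()
  for (ln in lines) {
    g <- ref_chars
    sub <- snp[snp$sample == ln, , drop = FALSE]
    if (nrow(sub)) {
      use_alt <- sub$gt == "hom_alt" |
        (sub$gt == "het" & stats::runif(nrow(sub)) < 0.5)
      sub <- sub[use_alt, , drop = FALSE]
      for (ch in unique(sub$chrom)) {
        rows <- sub$chrom == ch
        g[[ch]][sub$pos[rows]] <- sub$alt[rows]
      }
    }
    line_seq[[ln]] <- lapply(g, paste, collapse = "")
  }

  fixed <- params$read_profile == "fixed_100bp"
  n_frag <- nrow(fragments)
  all_seq <- character(0); all_id <- character(0); all_sample <- character(0)
  all_corrupt <- logical(0)
  counter <- 0L
  for (ln in lines) {
    depth <- stats::rnbinom(n_frag, mu = params$depth_mean,
                            size = params$depth_dispersion)
    idx <- rep.int(seq_len(n_frag), depth)
    if (!length(idx)) next
    n_r <- length(idx)
    bc <- bc_of[[ln]]
    read_len <- if (fixed) rep(100L, n_r) else
      sample(50:135, n_r, replace = TRUE)
    insert_len <- pmax(read_len - nchar(bc), 10L)
    # genomic portion starts just after the motif's G (the cut site), so
    # the CWGC remnant leads every insert
    txt <- unlist(line_seq[[ln]][fragments$chrom[idx]], use.names = FALSE)
    ins <- substring(txt, fragments$start[idx] + 1L,
                     fragments$start[idx] + insert_len)
    # substitution errors: exact per-read Binomial(len, e) error counts,
    # so only reads with at least one error are touched
    n_err <- stats::rbinom(n_r, nchar(ins), params$base_error)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(ins[i], "")[[1]]
      for (p in sample.int(length(chars), n_err[i])) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      ins[i] <- paste(chars, collapse = "")
    }
    if (!fixed && params$read_indel_rate > 0) {
      has_ind <- stats::runif(n_r) < params$read_indel_rate
      if (any(has_ind)) {
        ins[has_ind] <- vapply(ins[has_ind], function(s) {
          p <- sample.int(nchar(s), 1L)
          if (stats::runif(1) < 0.5) {
            paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
          } else {
            paste0(substr(s, 1, p), substr(s, p, nchar(s)))
          }
        }, character(1), USE.NAMES = FALSE)
      }
    }
    corrupt <- stats::runif(n_r) < params$corrupt_barcode_rate
    bc_out <- rep(bc, n_r)
    if (any(corrupt)) {
      bc_out[corrupt] <- vapply(which(corrupt), function(i) {
        p <- sample.int(nchar(bc), 1L)
        ch <- sample(setdiff(c("A", "C", "G", "T"),
                             substr(bc, p, p)), 1L)
        paste0(substr(bc, 1, p - 1), ch, substr(bc, p + 1, nchar(bc)))
      }, character(1))
    }
    ids <- sprintf("read%08d", counter + seq_len(n_r))
    counter <- counter + n_r
    all_seq <- c(all_seq, paste0(bc_out, ins))
    all_id <- c(all_id, ids)
    all_sample <- c(all_sample, rep(ln, n_r))
    all_corrupt <- c(all_corrupt, corrupt)
  }
  dna <- Biostrings::DNAStringSet(all_seq)
  names(dna) <- all_id
  qual <- Biostrings::PhredQuality(
    vapply(nchar(all_seq), function(n) strrep("I", n), character(1)))
  reads <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  list(reads = reads,
       origin = tibble::tibble(read_id = all_id, sample = all_sample,
                               corrupted = all_corrupt))
}

#' Generate a complete labelled synthetic GBS study
#'
#' Composes [make_reference()], [digest_and_select()], [simulate_truth()],
#' [simulate_pipeline_calls()] and (optionally) [simulate_reads()] into a
#' single fully deterministic study object. Identical parameters give
#' byte-identical artifacts.
#'
#' @param params a [sim_params()].
#' @param reads also simulate the FASTQ read set (default FALSE; the call
#'   matrices and evidence do not depend on it).
#' @return a `gbs_study` list: `params`, `reference`, `masked`,
#'   `annotations`, `fragments`, `truth`, `calls`, `labels`, `evidence`,
#'   `barcodes`, and (when requested) `reads`, `read_origin`.
#' @export
simulate_gbs_study <- function(params = sim_params(), reads = FALSE) {
  stopifnot(inherits(params, "gbs_sim_params"))
  ref <- make_reference(params)
  fragments <- digest_and_select(ref$reference, params$motif,
                                 params$fragment_window)
  truth <- simulate_truth(params, fragments, ref$reference)
  pc <- simulate_pipeline_calls(truth, params, ref$annotations)
  set.seed(params$seed + 4L)
  barcodes <- make_barcodes(length(geno_samples(truth$genotypes)),
                            length = params$barcode_length,
                            samples = geno_samples(truth$genotypes))
  study <- list(params = params, reference = ref$reference,
                masked = ref$masked, annotations = ref$annotations,
                fragments = fragments, truth = truth, calls = pc$calls,
                labels = pc$labels, evidence = pc$evidence,
                barcodes = barcodes)
  if (reads) {
    rd <- simulate_reads(params, fragments, truth, ref$reference, barcodes)
    study$reads <- rd$reads
    study$read_origin <- rd$origin
  }
  structure(study, class = "gbs_study")
}

#' Random barcode set with safe pairwise distances
#'
#' Fixed-length barcodes, pairwise Hamming distance at least 2, so that a
#' single sequencing error cannot convert one sample's barcode into
#' another's.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt.
#' @param samples sample names (default `L01..`).
#' @param remnant enzyme remnant (default ApeKI).
#' @return a [barcode_table()].
#' @export
make_barcodes <- function(n, length = 6L, samples = sprintf("L%02d", 1:n),
                          remnant = "CWGC") {
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  out <- character(0)
  guard <- 0L
  while (base::length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot generate a safe barcode set",
                             call. = FALSE)
    cand <- paste(random_dna(length), collapse = "")
    if (all(vapply(out, function(b) hamming(b, cand) >= 2, logical(1)))) {
      out <- c(out, cand)
    }
  }
  barcode_table(samples, out, remnant = remnant)
}

#' @export
print.gbs_study <- function(x, ...) {
  cat("Synthetic GBS study (seed ", x$params$seed, ")\n", sep = "")
  cat(sprintf("  genome: %d chrom, %s bp; fragments retained: %d\n",
              length(x$reference),
              format(sum(Biostrings::width(x$reference)), big.mark = ","),
              nrow(x$fragments)))
  cat(sprintf("  truth: %d sites x %d lines; pipelines: %s\n",
              n_sites(x$truth$genotypes),
              length(geno_samples(x$truth$genotypes)),
              paste(names(x$calls), collapse = ", ")))
  invisible(x)
}
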