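# evidence-table builders
ev_row <- function(site, read, reference, target, start, end,
                   coverage = 1, identity = 0.99) {
  tibble::tibble(site = site, read_id = read, reference = reference,
                 target = target, start = start, end = end,
                 coverage = coverage, identity = identity)
}

test_that("split_accurate: any mismatching compared cell marks a site inaccurate", {
  ps <- tibble::tibble(site = c("s1", "s2", "s3"),
                       n_compared = c(24L, 20L, 0L),
                       n_match = c(24L, 19L, 0L))
  sp <- split_accurate(ps)
  expect_equal(sp$accurate, c("s1", "s3"))  # no compared cells: accurate
  expect_equal(sp$inaccurate, "s2")
  # relaxed threshold
  sp90 <- split_accurate(ps, threshold = 0.9)
  expect_equal(sp90$inaccurate, character(0))
})

test_that("classify_sharing matches a brute-force recount over a random incidence matrix", {
  set.seed(5)
  sites <- sprintf("1:%d:SNP", 1:200)
  pipes <- c("P1", "P2", "P3")
  inc <- matrix(runif(600) < 0.3, nrow = 200,
                dimnames = list(sites, pipes))
  by_pipe <- lapply(pipes, function(p) sites[inc[, p]])
  names(by_pipe) <- pipes
  res <- classify_sharing(by_pipe)
  for (i in seq_len(nrow(res))) {
    n <- sum(inc[res$site[i], ])
    expect_equal(res$n_pipelines_inaccurate[i], n)
    expect_equal(res$sharing[i], if (n == 1) "unique" else "shared")
  }
  # single pipeline: not assessable
  expect_warning(single <- classify_sharing(by_pipe[1]), "single pipeline")
  expect_true(all(single$sharing == "not_applicable"))
})

test_that("mapping multiplicity merges overlapping intervals into one locus", {
  one <- alignment_evidence(
    ev_row("s1", "r1", "normal", "chr1", 100, 200), has_masked = TRUE)
  expect_equal(mapping_multiplicity("s1", one)$multiplicity,
               "unique_position")

  three <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200),
    ev_row("s1", "r1", "normal", "chr1", 5000, 5100),
    ev_row("s1", "r1", "normal", "chr2", 100, 200)), has_masked = TRUE)
  expect_equal(mapping_multiplicity("s1", three)$multiplicity,
               "multiple_positions")

  # two hits overlapping the same interval are one locus
  overlapping <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200),
    ev_row("s1", "r1", "normal", "chr1", 150, 250)), has_masked = TRUE)
  expect_equal(mapping_multiplicity("s1", overlapping)$multiplicity,
               "unique_position")

  # no evidence at all
  expect_equal(mapping_multiplicity("s9", one)$multiplicity,
               "unresolved_no_evidence")
})

test_that("masked remap: vanished loci are repetitive, surviving ones retained, absent remap unresolved", {
  with_masked <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200),
    ev_row("s2", "r2", "normal", "chr1", 500, 600),
    ev_row("s2", "r2", "masked", "chr1", 500, 600)))
  mc <- masked_remap_class(c("s1", "s2"), with_masked)
  expect_equal(mc$masked_class[mc$site == "s1"], "repetitive")
  expect_equal(mc$masked_class[mc$site == "s2"], "retained")

  no_masked <- alignment_evidence(
    ev_row("s1", "r1", "normal", "chr1", 100, 200))
  expect_equal(masked_remap_class("s1", no_masked)$masked_class,
               "unresolved_no_evidence")
})

test_that("paralogy rule thresholds: 2 qualifying hits pass, a 95%-identity hit does not qualify", {
  rule <- paralogy_rule()
  good <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200, 1.00, 0.97),
    ev_row("s1", "r1", "normal", "chr2", 900, 1000, 1.00, 0.99)),
    has_masked = TRUE)
  pt <- paralogy_test("s1", good, rule)
  expect_equal(pt$paralog_class, "paralogous")
  expect_equal(pt$n_hits, 2)

  weak <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200, 1.00, 0.97),
    ev_row("s1", "r1", "normal", "chr2", 900, 1000, 1.00, 0.95)),
    has_masked = TRUE)
  pt2 <- paralogy_test("s1", weak, rule)
  expect_equal(pt2$paralog_class, "unresolved")
  expect_equal(pt2$n_hits, 1)

  # partial coverage also disqualifies a hit
  short <- alignment_evidence(dplyr::bind_rows(
    ev_row("s1", "r1", "normal", "chr1", 100, 200, 0.80, 0.99),
    ev_row("s1", "r1", "normal", "chr2", 900, 1000, 1.00, 0.99)),
    has_masked = TRUE)
  expect_equal(paralogy_test("s1", short, rule)$paralog_class, "unresolved")
})

test_that("loosening min_identity never decreases the paralogous count", {
  set.seed(9)
  rows <- dplyr::bind_rows(lapply(1:100, function(i) {
    k <- sample(2:4, 1)
    ev_row(paste0("s", i), "r1", "normal", paste0("chr", 1:k),
           seq(1000, by = 5000, length.out = k),
           seq(1100, by = 5000, length.out = k),
           coverage = 1, identity = runif(k, 0.90, 1.0))
  }))
  ev <- alignment_evidence(rows, has_masked = TRUE)
  sites <- unique(rows$site)
  counts <- vapply(c(0.99, 0.97, 0.95, 0.92, 0.90), function(mi) {
    sum(paralogy_test(sites, ev,
                      paralogy_rule(min_identity = mi))$paralog_class ==
          "paralogous")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("attribute_errors composes the decision tree into a clean partition", {
  study <- small_study(seed = 23)
  truth <- study$truth
  per_site <- list(); catalogues <- list()
  for (p in names(study$calls)) {
    f <- apply_filters(study$calls[[p]])
    per_site[[p]] <- compare_to_truth(f$genotypes, truth)$per_site
    catalogues[[p]] <- site_keys(catalogue_sites(f$genotypes, "SNP"))
  }
  att <- attribute_errors(catalogues, per_site, study$evidence)
  s <- att$summary
  # partition identities on every pipeline
  expect_equal(s$unique_position + s$multiple_position +
                 s$unresolved_no_evidence, s$unique_inaccurate)
  expect_equal(s$repetitive + s$paralogous + s$unresolved,
               s$multiple_position)
  # every unique site got exactly one terminal label
  uniq <- att$records[att$records$sharing == "unique", ]
  expect_true(all(uniq$cause %in% c("caller_error", "repetitive",
                                    "paralogous", "unresolved",
                                    "unresolved_no_evidence")))
  expect_true(all(att$records$cause[att$records$sharing != "unique"] ==
                    "not_applicable"))
})

test_that("a study without structural errors attributes almost everything to the caller", {
  study <- simulate_gbs_study(sim_params(
    seed = 31, genome_length = 15e4, n_sites = 400,
    paralog_families = 0, repeat_families = 0,
    pipelines = list(
      a = pipeline_profile("a", genotype_error = 0.03, paralog_collapse = 0,
                           repeat_mismap = 0, missing_rate = 0.2),
      b = pipeline_profile("b", genotype_error = 0.001, paralog_collapse = 0,
                           repeat_mismap = 0, missing_rate = 0.2))))
  per_site <- list(); catalogues <- list()
  for (p in names(study$calls)) {
    f <- apply_filters(study$calls[[p]])
    per_site[[p]] <- compare_to_truth(f$genotypes, study$truth)$per_site
    catalogues[[p]] <- site_keys(catalogue_sites(f$genotypes, "SNP"))
  }
  att <- attribute_errors(catalogues, per_site, study$evidence)
  s <- att$summary
  expect_true(all(s$multiple_position == 0))
  expect_equal(sum(s$unique_position), sum(s$unique_inaccurate))
})
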