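test_that("identical parameters give byte-identical artifacts", {
  p <- sim_params(seed = 3, genome_length = 8e4, n_sites = 150,
                  paralog_families = 2, repeat_families = 1)
  a <- simulate_gbs_study(p, reads = TRUE)
  b <- simulate_gbs_study(p, reads = TRUE)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(as.character(a$masked), as.character(b$masked))
  expect_identical(a$fragments, b$fragments)
  expect_identical(tibble::as_tibble(a$truth$genotypes),
                   tibble::as_tibble(b$truth$genotypes))
  expect_identical(lapply(a$calls, tibble::as_tibble),
                   lapply(b$calls, tibble::as_tibble))
  expect_identical(as.character(a$reads), as.character(b$reads))
})

test_that("a genome without planted repeats has an untouched mask; divergence matches identity", {
  p0 <- sim_params(seed = 5, genome_length = 6e4, n_sites = 50,
                   paralog_families = 0, repeat_families = 0)
  r0 <- make_reference(p0)
  expect_identical(as.character(r0$reference), as.character(r0$masked))
  expect_equal(nrow(r0$annotations), 0)

  # one duplication at fixed identity 0.96: divergent positions ~ Binom(L, 0.04)
  p1 <- sim_params(seed = 6, genome_length = 1e5, n_sites = 50,
                   paralog_families = 1, paralog_copy_mean = 2,
                   paralog_identity = c(0.96, 0.96),
                   paralog_length = 10000L, repeat_families = 0)
  r1 <- make_reference(p1)
  ann <- r1$annotations[r1$annotations$type == "paralog", ]
  expect_gte(nrow(ann), 2)
  seqs <- vapply(seq_len(2), function(i) {
    substr(as.character(r1$reference[[ann$chrom[i]]]),
           ann$start[i] + 1, ann$end[i])
  }, character(1))
  mism <- sum(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  expect_gt(mism, 400 - 4 * sqrt(10000 * 0.04 * 0.96))
  expect_lt(mism, 400 + 4 * sqrt(10000 * 0.04 * 0.96))

  # repeats are hard-masked to N in the masked genome only
  p2 <- sim_params(seed = 7, genome_length = 8e4, n_sites = 50,
                   paralog_families = 0, repeat_families = 1)
  r2 <- make_reference(p2)
  rep_ann <- r2$annotations[r2$annotations$type == "repeat", ][1, ]
  masked_piece <- substr(as.character(r2$masked[[rep_ann$chrom]]),
                         rep_ann$start + 1, rep_ann$end)
  expect_equal(unique(strsplit(masked_piece, "")[[1]]), "N")
})

test_that("digest fragments match a brute-force regex scan and the stated coordinates", {
  # explicit construction: all-A background has no GCWGC; plant two motifs
  s <- paste(rep("A", 600), collapse = "")
  substr(s, 100, 104) <- "GCAGC"
  substr(s, 350, 354) <- "GCTGC"
  fr <- digest_and_select(c(chrA = s), window = c(100, 400))
  expect_equal(nrow(fr), 1)
  expect_equal(fr$start, 100)
  expect_equal(fr$end, 349)
  expect_equal(fr$length, 250)

  expect_equal(nrow(digest_and_select(c(x = paste(rep("A", 500),
                                                  collapse = "")))), 0)

  # random sequence: boundaries equal an independent regex scan
  set.seed(11)
  rnd <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
               collapse = "")
  fr2 <- digest_and_select(c(z = rnd), window = c(50, 500))
  hits <- gregexpr("GC[AT]GC", rnd, perl = TRUE)[[1]]
  # regex skips overlapping motifs; use lookahead scan for completeness
  hits2 <- gregexpr("(?=GC[AT]GC)", rnd, perl = TRUE)[[1]]
  starts <- sort(unique(as.integer(hits2)))
  lens <- diff(starts)
  keep <- lens >= 50 & lens <= 500
  expect_equal(fr2$start, starts[-length(starts)][keep])
  expect_equal(fr2$length, lens[keep])
})

test_that("truth genotypes respect homozygosity, residual het rate and the MAF spectrum", {
  p <- sim_params(seed = 13, genome_length = 2e5, n_sites = 800,
                  paralog_families = 0, repeat_families = 0,
                  residual_het_rate = 0)
  st <- simulate_gbs_study(p)
  tg <- st$truth$genotypes
  expect_equal(sum(tg$gt == "het"), 0)
  expect_true(all(attr(st$truth, "site_maf")$maf >= 0.05))
  expect_true(all(attr(st$truth, "site_maf")$maf <= 0.5))
  expect_equal(length(geno_samples(tg)), 24)

  p2 <- sim_params(seed = 13, genome_length = 2e5, n_sites = 800,
                   paralog_families = 0, repeat_families = 0,
                   residual_het_rate = 0.01)
  st2 <- simulate_gbs_study(p2)
  het_rate <- mean(st2$truth$genotypes$gt == "het")
  n <- nrow(st2$truth$genotypes)
  expect_lt(abs(het_rate - 0.01), 4 * sqrt(0.01 * 0.99 / n))
})

test_that("null pipeline model reproduces the truth exactly at discovered sites", {
  p <- sim_params(seed = 19, genome_length = 1e5, n_sites = 300,
                  paralog_families = 2, repeat_families = 1,
                  residual_het_rate = 0,
                  pipelines = list(perfect = pipeline_profile(
                    "perfect", sensitivity = 1, genotype_error = 0,
                    paralog_collapse = 0, repeat_mismap = 0,
                    missing_rate = 0, calls_indels = TRUE)))
  st <- simulate_gbs_study(p)
  calls <- st$calls$perfect
  expect_equal(nrow(catalogue_sites(calls)),
               nrow(catalogue_sites(st$truth$genotypes)))
  r <- glance(compare_to_truth(calls, st$truth))
  expect_equal(r$accuracy_pct, 100)
  expect_true(all(st$labels$label == "clean"))
})

test_that("pipeline catalogue sizes track sensitivity and indel eligibility", {
  p <- sim_params(seed = 29, genome_length = 2e5, n_sites = 1000,
                  paralog_families = 0, repeat_families = 0,
                  indel_fraction = 0.15,
                  pipelines = list(
                    hi = pipeline_profile("hi", sensitivity = 0.9,
                                          calls_indels = TRUE),
                    lo = pipeline_profile("lo", sensitivity = 0.5)))
  st <- simulate_gbs_study(p)
  n_truth_snp <- nrow(catalogue_sites(st$truth$genotypes, "SNP"))
  n_truth_ind <- nrow(catalogue_sites(st$truth$genotypes, "indel"))
  hi <- catalogue_sites(st$calls$hi)
  lo <- catalogue_sites(st$calls$lo)
  # indel-blind pipeline reports none
  expect_equal(sum(lo$variant_class == "indel"), 0)
  expect_gt(sum(hi$variant_class == "indel"), 0)
  # discovered-site counts near sensitivity x truth
  expect_lt(abs(sum(hi$variant_class == "SNP") - 0.9 * n_truth_snp),
            4 * sqrt(n_truth_snp * 0.9 * 0.1) + 1)
  expect_lt(abs(sum(lo$variant_class == "SNP") - 0.5 * n_truth_snp),
            4 * sqrt(n_truth_snp * 0.25) + 1)
})

test_that("fully collapsed paralog sites blow past the het-locus purge", {
  p <- sim_params(seed = 37, genome_length = 2e5, n_sites = 600,
                  paralog_families = 6, repeat_families = 0,
                  paralog_het_intensity = c(0.9, 1.0),
                  pipelines = list(x = pipeline_profile(
                    "x", sensitivity = 1, genotype_error = 0,
                    paralog_collapse = 1, repeat_mismap = 0,
                    missing_rate = 0)))
  st <- simulate_gbs_study(p)
  collapsed <- st$labels$site[st$labels$label == "paralog"]
  expect_gt(length(collapsed), 5)
  n_het_loci <- count_het_loci(st$calls$x, 0.5)
  # nearly every collapsed site exceeds 50% heterozygous calls
  expect_gt(n_het_loci, 0.9 * length(collapsed))
  f <- apply_filters(st$calls$x)
  purged <- site_keys(f$log[f$log$rule == "het_locus", ])
  expect_true(all(purged %in% collapsed))
})

test_that("reads follow the profile contract: lengths, remnant, exact prefixes when error-free", {
  p <- sim_params(seed = 41, genome_length = 6e4, n_sites = 0,
                  paralog_families = 0, repeat_families = 0,
                  base_error = 0)
  ref <- make_reference(p)
  fr <- digest_and_select(ref$reference, p$motif, p$fragment_window)
  truth <- simulate_truth(p, fr, ref$reference)
  bc <- make_barcodes(24)
  rd <- simulate_reads(p, fr, truth, ref$reference, bc)
  seqs <- as.character(rd$reads)
  expect_true(all(nchar(seqs) <= 100))
  # error-free reads: insert is the exact genomic prefix after the cut
  ref_str <- as.character(ref$reference)
  bc_of <- setNames(bc$barcode, bc$sample)
  idx <- sample(seq_along(seqs), 50)
  for (i in idx) {
    ln <- rd$origin$sample[i]
    b <- bc_of[[ln]]
    expect_true(startsWith(seqs[i], b))
    insert <- substr(seqs[i], nchar(b) + 1, nchar(seqs[i]))
    expect_true(grepl("^C[AT]GC", insert))
    found <- any(vapply(ref_str, function(s)
      grepl(insert, s, fixed = TRUE), logical(1)))
    expect_true(found)
  }

  # variable profile: lengths within [50, 135] and elevated error
  pv <- sim_params(seed = 43, genome_length = 6e4, n_sites = 0,
                   paralog_families = 0, repeat_families = 0,
                   read_profile = "variable_50_135bp")
  truth_v <- simulate_truth(pv, fr, ref$reference)
  rv <- simulate_reads(pv, fr, truth_v, ref$reference, bc)
  lens <- nchar(as.character(rv$reads))
  expect_true(all(lens >= 10 & lens <= 135))
})

test_that("planted per-base error rate is recovered by direct recount", {
  p <- sim_params(seed = 47, genome_length = 6e4, n_sites = 0,
                  paralog_families = 0, repeat_families = 0,
                  base_error = 0.005)
  ref <- make_reference(p)
  fr <- digest_and_select(ref$reference, p$motif, p$fragment_window)
  truth <- simulate_truth(p, fr, ref$reference)
  bc <- make_barcodes(4, samples = sprintf("L%02d", 1:4))
  # restrict truth to 4 lines for speed
  tg <- truth$genotypes
  truth4 <- truth_set(tg[tg$sample %in% sprintf("L%02d", 1:4), ])
  attr(truth4$genotypes, "samples") <- sprintf("L%02d", 1:4)
  rd <- simulate_reads(p, fr, truth4, ref$reference, bc)
  seqs <- as.character(rd$reads)
  bc_of <- setNames(bc$barcode, bc$sample)
  ref_str <- as.character(ref$reference)
  # alignment-free recount: each insert against its best-matching fragment
  # prefix (no SNPs were planted, so every mismatch is a planted error)
  ins_all <- vapply(seq_along(seqs), function(i) {
    b <- bc_of[[rd$origin$sample[i]]]
    substr(seqs[i], nchar(b) + 1, nchar(seqs[i]))
  }, character(1))
  frag_seq <- substring(ref_str[fr$chrom], fr$start + 1,
                        fr$start + max(nchar(ins_all)))
  tot_mm <- 0L; tot_bp <- 0L
  for (i in seq_along(ins_all)) {
    b <- utf8ToInt(ins_all[i])
    d <- vapply(substr(frag_seq, 1, nchar(ins_all[i])), function(cs) {
      a <- utf8ToInt(cs)
      if (length(a) != length(b)) return(Inf)
      sum(a != b)
    }, numeric(1))
    if (is.finite(min(d))) {
      tot_mm <- tot_mm + min(d)
      tot_bp <- tot_bp + nchar(ins_all[i])
    }
  }
  expect_lt(abs(tot_mm / tot_bp - 0.005), 0.0015)
})
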