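# build an in-memory FASTQ read set
make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  qual <- Biostrings::PhredQuality(vapply(nchar(seqs), strrep,
                                          character(1), x = "I"))
  Biostrings::QualityScaledDNAStringSet(dna, qual)
}

test_that("IUPAC remnant matching assigns and trims; unknown prefixes stay unassigned", {
  tab <- barcode_table(c("s1", "s2"), c("ACGT", "TTAGGC"))
  insert <- "GATTACAGATTACA"
  reads <- make_reads(c(
    paste0("ACGT", "CAGC", insert),   # W matched by A
    paste0("ACGT", "CTGC", insert),   # W matched by T
    paste0("ACGT", "CCGC", insert),   # remnant violated
    paste0("GGGG", "CAGC", insert)))  # unknown barcode
  out_dir <- tempfile()
  rep <- assign_reads(reads, tab, out_dir = out_dir)
  expect_equal(rep$counts$n_reads[rep$counts$sample == "s1"], 2)
  expect_equal(rep$counts$n_reads[rep$counts$sample == "unassigned"], 2)
  # trimming removed barcode + remnant
  s1 <- Biostrings::readDNAStringSet(file.path(out_dir, "s1.fastq"),
                                     format = "fastq")
  expect_true(all(as.character(s1) == insert))
  # unassigned kept untrimmed
  un <- Biostrings::readDNAStringSet(file.path(out_dir, "unassigned.fastq"),
                                     format = "fastq")
  expect_equal(length(un), 2)
  expect_true(all(nchar(as.character(un)) == nchar(insert) + 8))
})

test_that("read conservation holds and assignment is order-independent", {
  set.seed(4)
  tab <- make_barcodes(6)
  seqs <- unlist(lapply(tab$barcode, function(b)
    paste0(b, "CAGC", vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
            collapse = ""), character(1)))))
  seqs <- c(seqs, replicate(7, paste(
    sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")))
  reads <- make_reads(seqs)
  r1 <- assign_reads(reads, tab)
  expect_equal(sum(r1$counts$n_reads), length(reads))
  # shuffled input gives identical per-sample counts
  perm <- sample(seq_along(reads))
  r2 <- assign_reads(reads[perm], tab)
  expect_equal(r1$counts, r2$counts)
})

test_that("longest matching barcode wins; exact ties are unassigned", {
  tab <- barcode_table(c("short", "long"), c("ACGT", "ACGTACGT"))
  # read matching both barcodes (long one's suffix is CWGC-compatible tail)
  reads <- make_reads(c(
    paste0("ACGTACGT", "CTGC", "AAAACCCC"),  # long wins over short? no:
    paste0("ACGT", "CAGC", "GGGGTTTT")))     # only short matches
  rep <- assign_reads(reads, tab)
  # first read: short's remnant window is "ACGT" -> no match; long matches
  expect_equal(rep$counts$n_reads[rep$counts$sample == "long"], 1)
  expect_equal(rep$counts$n_reads[rep$counts$sample == "short"], 1)

  # a true tie: two equal-length barcodes within 1 mismatch of the read
  tab2 <- barcode_table(c("a", "b"), c("AAAAAA", "AAAAAT"))
  tie <- make_reads(paste0("AAAAAG", "CAGC", "ACGTACGT"))
  rep2 <- assign_reads(tie, tab2, max_mismatch = 1)
  expect_equal(rep2$counts$n_reads[rep2$counts$sample == "unassigned"], 1)
  # at one mismatch with a unique best, assignment succeeds
  one <- make_reads(paste0("AAACAA", "CAGC", "ACGTACGT"))
  rep3 <- assign_reads(one, tab2, max_mismatch = 1)
  expect_equal(rep3$counts$n_reads[rep3$counts$sample == "a"], 1)
})

test_that("ambiguous barcode tables are rejected at load", {
  # barcode + remnant prefix of another barcode: ACGT + CAGC prefixes ACGTCAGCAA
  expect_error(barcode_table(c("x", "y"), c("ACGT", "ACGTCAGCAA")),
               "ambiguous")
  expect_error(barcode_table(c("x", "y"), c("ACGT", "ACGT")), "unique")
})

test_that("planted corrupted barcodes are recovered as the unassigned fraction", {
  p <- sim_params(seed = 17, genome_length = 1e5, n_sites = 100,
                  paralog_families = 0, repeat_families = 0,
                  base_error = 0, corrupt_barcode_rate = 0.05)
  study <- simulate_gbs_study(p, reads = TRUE)
  rep <- assign_reads(study$reads, study$barcodes)
  n <- rep$totals$total_reads
  planted <- mean(study$read_origin$corrupted)
  expect_equal(rep$totals$unassigned_fraction, planted)  # exact recovery
  # and the planted rate is near its parameter
  expect_lt(abs(planted - 0.05), 4 * sqrt(0.05 * 0.95 / n))
  # error-free, exact barcodes: zero loss among uncorrupted reads
  expect_equal(rep$totals$unassigned, sum(study$read_origin$corrupted))
})

test_that("demux_delta reports recovered points between two demultiplexers", {
  fake <- function(per_sample, unassigned) {
    total <- sum(per_sample) + unassigned
    structure(list(
      counts = tibble::tibble(
        sample = c(sprintf("L%02d", seq_along(per_sample)), "unassigned"),
        n_reads = c(per_sample, unassigned)),
      totals = tibble::tibble(total_reads = total,
                              assigned = sum(per_sample),
                              unassigned = unassigned,
                              unassigned_fraction = unassigned / total)),
      class = "gbs_demux")
  }
  a <- fake(rep(803, 24), 4730)   # 19.7% unassigned
  b <- fake(rep(980, 24), 482)    # 2.0% unassigned
  d <- demux_delta(a, b)
  expect_equal(round(d$totals$unassigned_pct_a, 1), 19.7)
  expect_equal(round(d$totals$recovered_points, 1), 17.7)
  # identical reports: all deltas zero
  z <- demux_delta(a, a)
  expect_true(all(z$per_sample$delta == 0))
  # differing totals are an input error
  expect_error(demux_delta(a, fake(rep(1, 24), 0)), "different read totals")
})
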