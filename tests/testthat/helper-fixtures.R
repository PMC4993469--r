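# in-code fixtures shared across test files

# random long-format genotype matrix
random_geno <- function(n_sites = 20, n_samples = 4, seed = 1,
                        with_dp = TRUE, indel_fraction = 0.2,
                        states = c("hom_ref", "het", "hom_alt", "missing")) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n_sites))
  chrom <- sample(c("1", "2"), n_sites, replace = TRUE)
  is_indel <- runif(n_sites) < indel_fraction
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(seq_len(n_sites), function(i) {
    if (is_indel[i]) paste0(ref[i], "T")
    else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  }, character(1))
  samples <- sprintf("S%02d", seq_len(n_samples))
  g <- tibble::tibble(
    chrom = rep(chrom, n_samples),
    pos = rep(pos, n_samples),
    variant_class = rep(ifelse(is_indel, "indel", "SNP"), n_samples),
    ref = rep(ref, n_samples),
    alt = rep(alt, n_samples),
    sample = rep(samples, each = n_sites),
    gt = sample(states, n_sites * n_samples, replace = TRUE),
    dp = if (with_dp) sample(0:20, n_sites * n_samples, replace = TRUE)
         else NA_integer_
  )
  g$dp[g$gt == "missing" & !is.na(g$dp)] <- 0L
  attr(g, "samples") <- samples
  g
}

# a genotype tibble built from explicit per-site call vectors
geno_from_calls <- function(calls_by_site, samples = NULL, dp = NULL) {
  n_samples <- length(calls_by_site[[1]])
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n_samples))
  n <- length(calls_by_site)
  g <- tibble::tibble(
    chrom = rep("1", n * n_samples),
    pos = rep(seq(100, by = 100, length.out = n), n_samples),
    variant_class = "SNP",
    ref = "A", alt = "G",
    sample = rep(samples, each = n),
    gt = as.vector(vapply(seq_along(samples), function(j)
      vapply(calls_by_site, `[`, character(1), j), character(n))),
    dp = if (is.null(dp)) NA_integer_ else
      as.vector(vapply(seq_along(samples), function(j)
        vapply(dp, `[`, numeric(1), j), numeric(n)))
  )
  attr(g, "samples") <- samples
  g
}

# disjoint synthetic catalogues with a prescribed intersection structure
key_sets <- function(total_a, only_a, total_b) {
  common <- total_a - only_a
  stopifnot(common >= 0, total_b >= common)
  shared <- sprintf("1:%d:SNP", seq_len(common))
  a_only <- sprintf("2:%d:SNP", seq_len(only_a))
  b_only <- sprintf("3:%d:SNP", seq_len(total_b - common))
  list(a = c(shared, a_only), b = c(shared, b_only))
}

# write VCF text lines to a temp file
write_vcf_text <- function(body, samples = c("S01", "S02", "S03", "S04"),
                           format = "GT") {
  path <- tempfile(fileext = ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# small synthetic study used by several files
small_study <- function(seed = 11, ...) {
  simulate_gbs_study(sim_params(
    seed = seed, genome_length = 15e4, n_sites = 400,
    paralog_families = 3, repeat_families = 2,
    paralog_identity = c(0.96, 1.0), ...))
}
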