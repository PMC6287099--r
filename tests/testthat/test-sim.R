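test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(N = 30L, L = 100000L, burnin_gens = 120L,
                    split_gens = 30L, breed_gens = 10L, n_genes = 5L,
                    n_qtl = 2L, n_indels = 20L, seed = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, dir = d1)
  s2 <- simulate_cohort(cfg, dir = d2)
  for (f in c("cohort.vcf", "callable.bed", "genes.gff3", "qtl.bed",
              "groups.tsv", "reference.fa", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  s3 <- simulate_cohort(sim_config(N = 30L, L = 100000L,
                                   burnin_gens = 120L, split_gens = 30L,
                                   breed_gens = 10L, n_genes = 5L,
                                   n_qtl = 2L, n_indels = 20L, seed = 6L))
  expect_false(identical(s1$variants$pos, s3$variants$pos))
})

test_that("zero mutation rate emits zero variant sites", {
  cfg <- sim_config(N = 20L, L = 50000L, mu = 0, burnin_gens = 50L,
                    split_gens = 10L, breed_gens = 5L, n_genes = 3L,
                    n_qtl = 1L, n_indels = 0L, seed = 2L)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$variants), 0L)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(N = 10, sample_sizes = c(dairy = 20, cashmere = 5,
                                                   meat = 5, wild = 4)))
  expect_error(sim_config(error_rate = 0.5))
  expect_error(sim_config(breed_gens = 300, split_gens = 200))
})

test_that("neutral diversity approaches 4*N*mu and the SFS is singleton-heavy", {
  # equilibrium check: pi within 30% of theta = 4*N*mu, averaged over seeds
  N <- 100L; L <- 1e6; mu <- 5e-7
  theta <- 4 * N * mu
  n_seeds <- 20
  pis <- numeric(n_seeds)
  p_single <- numeric(n_seeds)
  p_double <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sim <- simulate_cohort(sim_config(
      N = N, L = L, mu = mu, burnin_gens = 600L, split_gens = 0L,
      breed_gens = 0L, n_genes = 2L, n_qtl = 1L, n_indels = 0L,
      depth_mean = 5, seed = 1000L + k))
    h <- sim$truth$haplotypes
    n <- nrow(h)
    p <- colMeans(h)
    pis[k] <- sum(2 * p * (1 - p) * n / (n - 1)) / L
    counts <- colSums(h)
    p_single[k] <- mean(counts == 1)
    p_double[k] <- mean(counts == 2)
  }
  expect_lt(abs(mean(pis) - theta) / theta, 0.30)
  # qualitative 1/i law, seed-averaged: the mean singleton proportion
  # exceeds the mean doubleton proportion
  expect_gt(mean(p_single), mean(p_double))
})

test_that("depth emulation follows Poisson/binomial read models", {
  set.seed(3)
  # epsilon = 0, homozygous: every read supports the single allele
  a_hom <- matrix(1L, 100, 2)
  d <- emulate_depths(a_hom, a_hom, lambda = 20, error_rate = 0)
  expect_true(all(d$ref == 0))
  expect_equal(d$alt, d$depth)

  # lambda = 0: all depths zero
  d0 <- emulate_depths(a_hom, a_hom, lambda = 0, error_rate = 0)
  expect_true(all(d0$depth == 0))

  # heterozygote at lambda 30, eps 0: allele balance is Binomial(depth, 1/2)
  n <- 10000
  a1 <- matrix(0L, n, 1)
  a2 <- matrix(1L, n, 1)
  dh <- emulate_depths(a1, a2, lambda = 30, error_rate = 0)
  expect_equal(dh$ref + dh$alt, dh$depth)
  at30 <- dh$ref[dh$depth == 30]
  expect_gt(length(at30), 500)
  cnt <- tabulate(at30 + 1L, nbins = 31L)
  expected <- length(at30) * stats::dbinom(0:30, 30, 0.5)
  keep <- expected >= 5
  chi <- sum((cnt[keep] - expected[keep])^2 / expected[keep])
  # generous chi-square bound: df ~ sum(keep) - 1
  expect_lt(chi, stats::qchisq(0.999, sum(keep) - 1))
  expect_error(emulate_depths(a1, a2, error_rate = 0.3), "error_rate")
})

test_that("planted genes are clean ORFs with known placement", {
  sim <- tiny_cohort()
  genes <- sim$genes
  expect_equal(nrow(genes), 8L)
  ref_chars <- strsplit(as.character(sim$reference[[1]]), "")[[1]]
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    expect_true(all(cds$start >= genes$start[i] & cds$end <= genes$end[i]))
    gpos <- unlist(purrr::map2(cds$start, cds$end, function(s, e) s:(e - 1)))
    expect_equal(length(gpos) %% 3, 0)
    s <- ref_chars[gpos + 1]
    if (genes$strand[i] == "-") s <- rev(chartr("ACGT", "TGCA", s))
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(s, collapse = ""))))
    # terminal stop only, no internal stops
    expect_equal(substring(prot, nchar(prot)), "*")
    expect_false(grepl("\\*", substring(prot, 1, nchar(prot) - 1)))
  }
  # non-overlapping spans
  ord <- order(genes$start)
  expect_true(all(genes$start[ord][-1] >= genes$end[ord][-length(ord)]))
  # genome too small for the request is a config error
  expect_error(
    simulate_cohort(sim_config(N = 10L, L = 5000L, burnin_gens = 10L,
                               split_gens = 5L, breed_gens = 2L,
                               n_genes = 50L, seed = 1L)),
    "too small")
})

test_that("a planted sweep fixes, lands in its window, and is recorded in truth", {
  cfg <- sim_config(N = 60L, L = 500000L, s = 0.2, burnin_gens = 360L,
                    split_gens = 120L, breed_gens = 100L, n_genes = 10L,
                    n_qtl = 2L, n_indels = 0L, seed = 9L)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$sel_final_freq, 1)
  expect_equal(sim$truth$sweep_breed, "dairy")
  sw <- sim$truth$sweep_window
  expect_true(sim$truth$sel_pos >= sw$start && sim$truth$sel_pos < sw$end)
  # the focal samples are fixed for the selected allele
  foc <- group_samples(sim$groups, "dairy")
  i <- which(sim$variants$pos == sim$truth$sel_pos)
  if (length(i) == 1) {  # segregating in the full sample
    g <- sim$variants$gt[[i]][, foc]
    expect_true(all(g == 1L))
  }
  # a gene was planted inside the sweep window
  expect_gt(length(sim$truth$genes_in_sweep), 0)
  # per-population truth frequencies cover every site and every group
  expect_equal(nrow(sim$truth$pop_freqs), ncol(sim$truth$haplotypes))
  expect_true(all(c("dairy", "cashmere", "meat", "wild") %in%
                    names(sim$truth$pop_freqs)))
  expect_equal(sim$truth$pop_freqs$dairy[
    sim$truth$pop_freqs$pos == sim$truth$sel_pos], 1)
})

test_that("sweeps depress focal diversity at the selected window", {
  # effect-direction check at reduced scale; the full-scale power study is
  # exercised in the acceptance suite
  n_rep <- 5
  low <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    sim <- simulate_cohort(sim_config(
      N = 100L, L = 1000000L, s = 0.2, burnin_gens = 600L,
      split_gens = 150L, breed_gens = 120L, n_genes = 5L, n_qtl = 1L,
      n_indels = 0L, seed = 2000L + k))
    foc <- group_samples(sim$groups, sim$truth$sweep_breed)
    bi <- vt_is_biallelic_snp(sim$variants)
    dos <- allele_dosage(sim$variants[bi, ], foc)
    pos <- sim$variants$pos[bi]
    p <- rowSums(dos) / (2 * length(foc))
    het <- tapply(2 * p * (1 - p), pos %/% 1e5, sum)
    swi <- as.character(sim$truth$sweep_window$start %/% 1e5)
    low[k] <- !is.na(het[swi]) && het[swi] < stats::median(het)
  }
  expect_gte(mean(low), 0.8)
})
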