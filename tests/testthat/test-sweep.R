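one_window <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L)

test_that("pooled heterozygosity evaluates the printed formula", {
  smp <- c("a", "b")
  # one SNP, pooled depths 15/15 -> Hp = 0.5
  vt1 <- make_vt(list(list(pos = 10, gt = gt2(c(0, 0), c(1, 1)),
                           ad = rbind(c(7, 8), c(7, 8)))), smp)
  hp1 <- pooled_heterozygosity(vt1, smp, one_window)
  expect_equal(hp1$hp, 0.5)

  # monomorphic pooled depths -> Hp = 0
  vt2 <- make_vt(list(list(pos = 10, gt = gt2(c(0, 0), c(0, 0)),
                           ad = rbind(c(15, 15), c(0, 0)))), smp)
  expect_equal(pooled_heterozygosity(vt2, smp, one_window)$hp, 0)

  # two SNPs (30,10) and (30,10): Hp = 2*60*20/80^2 = 0.375
  vt3 <- make_vt(list(
    list(pos = 10, gt = gt2(c(0, 0), c(1, 1)), ad = rbind(c(15, 15), c(5, 5))),
    list(pos = 20, gt = gt2(c(0, 0), c(1, 1)), ad = rbind(c(15, 15), c(5, 5)))
  ), smp)
  expect_equal(pooled_heterozygosity(vt3, smp, one_window)$hp, 0.375)

  # windows with no SNPs carry NA; empty window list is an error
  w2 <- dplyr::bind_rows(one_window,
                         tibble::tibble(chrom = "chr1", start = 100000L,
                                        end = 200000L))
  expect_true(is.na(pooled_heterozygosity(vt3, smp, w2)$hp[2]))
  expect_error(pooled_heterozygosity(vt3, smp, one_window[0, ]), "window")
})

test_that("Hp lies in [0, 0.5] and is invariant to allele relabeling", {
  set.seed(41)
  smp <- c("a", "b", "c")
  spec <- purrr::map(1:50, function(i) {
    ad <- matrix(rpois(6, 10), 2)
    list(pos = i * 100, gt = gt2(c(0, 0, 0), c(1, 1, 1)), ad = ad)
  })
  vt <- make_vt(spec, smp)
  hp <- pooled_heterozygosity(vt, smp, one_window)$hp
  expect_true(hp >= 0 && hp <= 0.5)
  # swap ref/alt depth rows
  vt_sw <- vt
  vt_sw$ad <- purrr::map(vt$ad, function(d) d[2:1, , drop = FALSE])
  expect_equal(pooled_heterozygosity(vt_sw, smp, one_window)$hp, hp)
})

test_that("Hp falls back to genotype counts when depths are absent", {
  smp <- c("a", "b")
  vt <- make_vt(list(list(pos = 10, gt = gt2(c(0, 1), c(0, 1)))), smp)
  expect_message(hp <- pooled_heterozygosity(vt, smp, one_window),
                 "genotype allele counts")
  expect_equal(hp$hp, 0.5)  # 2 ref + 2 alt alleles
})

test_that("Fst closed forms: fixed difference gives 1, equal frequencies 0", {
  smp <- c(paste0("a", 1:3), paste0("b", 1:3))
  ga <- paste0("a", 1:3)
  gb <- paste0("b", 1:3)
  fixed <- make_vt(purrr::map(1:5, function(i) {
    list(pos = i * 10, gt = gt2(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1)))
  }), smp)
  expect_equal(fst_windows(fixed, ga, gb, one_window)$fst, 1)

  equal <- make_vt(purrr::map(1:5, function(i) {
    list(pos = i * 10, gt = gt2(c(0, 1, 0, 0, 1, 0), c(1, 0, 0, 1, 0, 0)))
  }), smp)
  expect_equal(fst_windows(equal, ga, gb, one_window)$fst, 0)

  expect_error(fst_windows(fixed, c(ga, "zz"), gb, one_window), "not in table")
})

test_that("windowed Fst matches an independent per-site Hudson oracle", {
  set.seed(51)
  n_a <- 5L; n_b <- 7L
  smp <- c(paste0("a", 1:n_a), paste0("b", 1:n_b))
  spec <- purrr::map(1:200, function(i) {
    p <- runif(1, 0.05, 0.95)
    list(pos = i * 100,
         gt = matrix(rbinom(2 * (n_a + n_b), 1, p), nrow = 2))
  })
  vt <- make_vt(spec, smp)
  wins <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                         end = c(10000L, 20000L))
  got <- fst_windows(vt, paste0("a", 1:n_a), paste0("b", 1:n_b), wins)

  # independent oracle: plug-in Hudson ratio of averages from raw genotypes
  oracle <- function(rows) {
    num <- 0; den <- 0
    for (s in rows) {
      g <- vt$gt[[s]]
      p1 <- mean(g[, paste0("a", 1:n_a)])
      p2 <- mean(g[, paste0("b", 1:n_b)])
      if (p1 %in% c(0, 1) && p2 == p1) next
      num <- num + (p1 - p2)^2
      den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    }
    num / den
  }
  expect_equal(got$fst[1], oracle(which(vt$pos < 10000)), tolerance = 1e-12)
  expect_equal(got$fst[2], oracle(which(vt$pos >= 10000 & vt$pos < 20000)),
               tolerance = 1e-12)
})

test_that("Weir-Cockerham estimator hits the closed forms too", {
  smp <- c(paste0("a", 1:3), paste0("b", 1:3))
  fixed <- make_vt(purrr::map(1:5, function(i) {
    list(pos = i * 10, gt = gt2(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1)))
  }), smp)
  expect_equal(fst_windows(fixed, paste0("a", 1:3), paste0("b", 1:3),
                           one_window, estimator = "wc")$fst, 1)
})

test_that("z_transform matches the sample-sd convention and its oracle", {
  expect_equal(z_transform(c(-1, 1)), c(-1, 1) / sqrt(2))
  set.seed(61)
  x <- rnorm(1e4, 5, 3)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # independent two-pass oracle
  expect_equal(z, (x - sum(x) / length(x)) /
                 sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
  # NA passthrough
  z2 <- z_transform(c(1, NA, 3))
  expect_true(is.na(z2[2]))
  expect_error(z_transform(c(1)), "two finite")
  expect_error(z_transform(c(2, 2, 2)), "zero variance")
})

test_that("DAG windows follow the inclusive OR rule and map to genes", {
  stats <- tibble::tibble(
    chrom = "chr1",
    start = seq(0L, by = 100000L, length.out = 5),
    end = seq(100000L, by = 100000L, length.out = 5),
    zhp = c(-3.5, 0, -2.9, -3, 0),
    zfst = c(1, 3.2, 2.9, 0, 3)
  )
  genes <- tibble::tibble(
    gene_id = c("g1", "g3", "g5"), chrom = "chr1",
    start = c(10000L, 250000L, 490000L), end = c(20000L, 260000L, 510000L),
    strand = "+",
    cds = list(tibble::tibble(start = integer(), end = integer()))[rep(1, 3)]
  )
  calls <- classify_dags(stats, genes)
  # windows 1 (hp arm), 2 (fst arm), 4 (hp boundary), 5 (fst boundary)
  expect_equal(calls$windows$start, c(0L, 100000L, 300000L, 400000L))
  expect_equal(calls$windows$rule[1], "low_hp")
  expect_equal(calls$windows$rule[2], "high_fst")
  expect_setequal(tidy(calls)$gene_id, c("g1", "g5"))
  g <- glance(calls)
  expect_equal(g$n_windows, 4L)
  expect_equal(g$kind, "DAG")

  # monotonicity: lowering the Fst cut never removes a flagged window
  lower <- classify_dags(stats, genes, zfst_cut = 2.5)
  expect_true(all(calls$windows$start %in% lower$windows$start))
})

test_that("TAG windows need both the Fst arm and top-1% XP-EHH membership", {
  n <- 200
  stats <- tibble::tibble(
    chrom = "chr1",
    start = seq(0L, by = 100000L, length.out = n),
    end = seq(100000L, by = 100000L, length.out = n),
    zfst = c(4.2, 4.2, rep(0, n - 2)),
    xpehh = c(5, 0.1, seq(0.2, 3, length.out = n - 2))
  )
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 1000L, end = 5000L,
    strand = "+",
    cds = list(tibble::tibble(start = integer(), end = integer())))
  calls <- classify_tags(stats, genes)
  # window 1: zfst 4.2 and top xpehh -> flagged; window 2: zfst passes but
  # xpehh low -> not flagged
  expect_equal(calls$windows$start, 0L)
  expect_equal(tidy(calls)$gene_id, "g1")

  # flagged count bounded by the top-set size on any input
  set.seed(71)
  for (rep in 1:10) {
    stats2 <- stats
    stats2$zfst <- rnorm(n, 3, 2)
    stats2$xpehh <- rnorm(n)
    calls2 <- classify_tags(stats2, genes)
    expect_lte(nrow(calls2$windows), ceiling(0.01 * n))
  }

  # absent XP-EHH directs the user to the haplotype stage
  stats3 <- stats
  stats3$xpehh <- NA_real_
  expect_error(classify_tags(stats3, genes), "xpehh_scan")
})

test_that("QTL cross-referencing matches a quadratic brute-force oracle", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
    start = c(100L, 100L), end = c(200L, 200L), strand = "+",
    cds = list(tibble::tibble(start = integer(), end = integer()))[rep(1, 2)]
  )
  qtl <- tibble::tibble(chrom = "chr1", start = 150L, end = 400L,
                        name = "q1")
  hits <- crossref_qtl(genes, qtl)
  expect_equal(hits$gene_id, "g1")   # g2 is on another chromosome

  set.seed(81)
  n_g <- 100; n_q <- 30
  genes2 <- tibble::tibble(
    gene_id = sprintf("g%d", 1:n_g),
    chrom = sample(c("c1", "c2"), n_g, TRUE),
    start = sample.int(10000, n_g), strand = "+",
    cds = list(tibble::tibble(start = integer(), end = integer()))[rep(1, n_g)]
  )
  genes2$end <- genes2$start + sample.int(500, n_g)
  qtl2 <- tibble::tibble(chrom = sample(c("c1", "c2"), n_q, TRUE),
                         start = sample.int(10000, n_q))
  qtl2$end <- qtl2$start + sample.int(2000, n_q)
  qtl2$name <- sprintf("q%d", 1:n_q)
  hits2 <- crossref_qtl(genes2, qtl2)
  oracle <- 0L
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_q)) {
      if (genes2$chrom[i] == qtl2$chrom[j] &&
          genes2$start[i] < qtl2$end[j] && genes2$end[i] > qtl2$start[j]) {
        oracle <- oracle + 1L
        expect_true(any(hits2$gene_id == genes2$gene_id[i] &
                          hits2$qtl_id == qtl2$name[j]))
      }
    }
  }
  expect_equal(nrow(hits2), oracle)
})
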