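test_that("depth filter removes low-depth sites and demotes weak het calls", {
  smp <- c("s1", "s2")
  vt <- make_vt(list(
    # total depth 7 in s1 -> site removed
    list(pos = 10, gt = gt2(c(0, 0), c(0, 1)),
         ad = rbind(c(4, 10), c(3, 2))),
    # het AD (4,4): kept as het
    list(pos = 20, gt = gt2(c(0, 0), c(1, 0)),
         ad = rbind(c(4, 10), c(4, 0))),
    # het AD (5,3): genotype demoted, site still polymorphic via s2
    list(pos = 30, gt = gt2(c(0, 0), c(1, 1)),
         ad = rbind(c(5, 4), c(3, 4))),
    # het AD (5,3), other sample hom-ref: demotion leaves monomorphic site
    list(pos = 40, gt = gt2(c(0, 0), c(1, 0)),
         ad = rbind(c(5, 10), c(3, 0)))
  ), smp)
  out <- filter_snps_by_depth(vt)
  expect_equal(out$pos, c(20L, 30L))
  expect_equal(unname(out$gt[[1]][, "s1"]), c(0L, 1L))   # het retained
  expect_true(all(is.na(out$gt[[2]][, "s1"])))           # demoted
  rep <- qc_report(out)
  expect_equal(rep$count[rep$criterion == "snp_low_depth_removed"], 1)
  expect_equal(rep$count[rep$criterion == "het_calls_demoted"], 2)
  expect_equal(
    rep$count[rep$criterion == "snp_monomorphic_after_demotion_removed"], 1)

  # missing AD names the position
  vt_na <- make_vt(list(list(pos = 5, gt = gt2(0, 1))), "s1")
  expect_error(filter_snps_by_depth(vt_na), "AD absent")
})

test_that("joint depth+het rule matches a literal-rule oracle over AD pairs", {
  # single-sample sites with every AD pair summing to 8..12
  smp <- "s1"
  pairs <- expand.grid(a = 0:12, b = 0:12)
  pairs <- pairs[pairs$a + pairs$b >= 8 & pairs$a + pairs$b <= 12, ]
  spec <- purrr::pmap(list(seq_len(nrow(pairs)), pairs$a, pairs$b),
                      function(i, a, b) {
                        list(pos = i * 10, gt = gt2(0, 1),
                             ad = rbind(a, b))
                      })
  vt <- make_vt(spec, smp)
  out <- filter_snps_by_depth(vt)
  # literal rule: depth >= 8 (all are); het call valid iff both alleles have
  # >= 4 reads; a demoted lone het leaves the site monomorphic -> dropped
  keep_oracle <- pairs$a >= 4 & pairs$b >= 4
  expect_equal(out$pos, (seq_len(nrow(pairs)) * 10L)[keep_oracle])

  # idempotence
  again <- filter_snps_by_depth(out)
  expect_equal(again$pos, out$pos)
  expect_equal(again$gt, out$gt)
})

test_that("the permissive all-below reading only drops all-low sites", {
  smp <- c("s1", "s2")
  vt <- make_vt(list(
    # s1 hom-alt at depth 5, s2 hom-ref at depth 20
    list(pos = 1, gt = gt2(c(1, 0), c(1, 0)), ad = rbind(c(3, 20), c(2, 0))),
    # both samples below depth 8
    list(pos = 2, gt = gt2(c(1, 0), c(1, 0)), ad = rbind(c(3, 3), c(2, 2)))
  ), smp)
  strict <- filter_snps_by_depth(vt)
  permissive <- filter_snps_by_depth(vt, mode = "all_below")
  expect_equal(nrow(strict), 0L)
  expect_equal(permissive$pos, 1L)
})

test_that("indel filters apply quality, homopolymer and length boundaries", {
  smp <- "s1"
  vt <- make_vt(list(
    list(pos = 10, ref = "A", alt = "AT", kind = "insertion", qual = 19,
         hom_len = 2),                                   # quality below 20
    list(pos = 20, ref = "ATTTTTTT", alt = "AT", kind = "deletion",
         qual = 30, hom_len = 2),                        # 6-bp deletion
    list(pos = 30, ref = "A", alt = "ACGT", kind = "insertion", qual = 30,
         hom_len = 10),                                  # boundary: retained
    list(pos = 40, ref = "A", alt = "AC", kind = "insertion", qual = 20,
         hom_len = 11),                                  # homopolymer > 10
    list(pos = 50, gt = gt2(0, 1), qual = 5)             # SNP: untouched
  ), smp)
  out <- suppressWarnings(filter_indels(vt))
  expect_equal(out$pos, c(30L, 50L))
  rep <- qc_report(out)
  expect_equal(rep$count[rep$criterion == "indel_low_quality_removed"], 1)
  expect_equal(rep$count[rep$criterion == "indel_too_long_removed"], 1)
  expect_equal(rep$count[rep$criterion == "indel_homopolymer_removed"], 1)
  expect_equal(rep$count[rep$criterion == "indel_retained"], 1)
  # removed + retained = input, per kind
  n_indel_in <- sum(vt$kind != "SNP")
  expect_equal(sum(rep$count[rep$criterion != "indel_retained"]) +
                 rep$count[rep$criterion == "indel_retained"], n_indel_in)
  # idempotent
  expect_equal(suppressWarnings(filter_indels(out))$pos, out$pos)
})

test_that("site summaries: MAF, allele-label invariance, per-individual het", {
  smp <- c("a", "b", "c")
  vt <- make_vt(list(
    list(pos = 1, gt = matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 2)),  # p_alt = 3/6
    list(pos = 2, gt = matrix(c(0L, 0L, 0L, 0L, 0L, 0L), 2)),  # monomorphic
    list(pos = 3, gt = matrix(c(0L, 1L, NA, NA, 1L, 1L), 2))   # missing
  ), smp)
  s <- site_summaries(vt)
  expect_equal(s$sites$maf, c(0.5, 0, 0.25))  # site 3: alt 3 of 4 calls
  expect_true(all(s$sites$maf >= 0 & s$sites$maf <= 0.5))
  expect_true(s$sites$monomorphic[2])

  # allele relabeling leaves MAF unchanged
  vt_swapped <- vt
  vt_swapped$gt <- purrr::map(vt$gt, function(g) {
    g2 <- 1L - g
    colnames(g2) <- colnames(g)
    g2
  })
  s2 <- site_summaries(vt_swapped)
  expect_equal(s2$sites$maf, s$sites$maf)

  # per-individual heterozygosity equals a brute-force per-genotype count
  set.seed(7)
  spec <- purrr::map(1:100, function(i) {
    list(pos = i, gt = matrix(sample(0:1, 6, replace = TRUE), 2))
  })
  vt_big <- make_vt(spec, smp)
  s3 <- site_summaries(vt_big)
  for (j in seq_along(smp)) {
    hets <- vapply(vt_big$gt, function(g) g[1, j] != g[2, j], logical(1))
    expect_equal(s3$individuals$n_het[j], sum(hets))
    expect_equal(s3$individuals$het_rate[j], mean(hets))
  }
})

test_that("CNV merging unions strict overlaps and reports support", {
  reg <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0L, 500L, 3000L, 0L),
    end = c(1000L, 1500L, 4000L, 100L),
    sample = c("A", "B", "A", "C"),
    state = c("gain", "loss", "gain", "gain")
  )
  m <- merge_cnv_regions(reg, cohort_size = 4)
  first <- m[m$chrom == "chr1" & m$start == 0, ]
  expect_equal(first$end, 1500L)
  expect_equal(first$samples, "A,B")
  expect_equal(first$states, "gain,loss")
  expect_equal(first$frequency, 0.5)
  expect_equal(nrow(m), 3L)

  # adjacent-but-not-overlapping intervals stay separate
  adj <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                        end = c(100L, 200L), sample = c("A", "B"),
                        state = "gain")
  expect_equal(nrow(merge_cnv_regions(adj)), 2L)

  # 500 random intervals: merged cover equals per-base brute force
  set.seed(11)
  n <- 500
  st <- sample.int(10000, n, replace = TRUE) - 1L
  reg2 <- tibble::tibble(chrom = "chr1", start = st,
                         end = st + sample.int(100, n, replace = TRUE),
                         sample = sample(LETTERS[1:6], n, replace = TRUE),
                         state = sample(c("gain", "loss"), n, TRUE))
  m2 <- merge_cnv_regions(reg2)
  covered <- logical(20000)
  for (i in seq_len(n)) covered[(reg2$start[i] + 1):reg2$end[i]] <- TRUE
  expect_equal(sum(m2$end - m2$start), sum(covered))
})
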