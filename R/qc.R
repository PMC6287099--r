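#' Depth-based SNP filtering
#'
#' Applies the study-style read-depth rules to SNP records:
#'
#' 1. a SNP site is removed when any individual's total read depth at the
#'    site is below `min_total_depth` (default 8); set
#'    `mode = "all_below"` for the permissive reading that removes a site
#'    only when *every* individual is below the cutoff;
#' 2. a heterozygous genotype call is demoted to missing unless both of its
#'    alleles are supported by at least `min_het_allele_reads` reads
#'    (default 4); the site is kept if it stays polymorphic across samples.
#'
#' Indel records pass through untouched (see [filter_indels()]).
#'
#' @param vt A [variant_table()]; every genotyped SNP sample must carry `AD`.
#' @param min_total_depth Minimum per-individual summed depth.
#' @param min_het_allele_reads Minimum reads per allele of a het call.
#' @param mode `"any_below"` (default) or `"all_below"` site-removal rule.
#' @return Filtered `variant_table` with a `filter_report` attribute (tibble
#'   of criterion/count; retrieve with [qc_report()]).
#' @export
filter_snps_by_depth <- function(vt, min_total_depth = 8,
                                 min_het_allele_reads = 4,
                                 mode = c("any_below", "all_below")) {
  mode <- match.arg(mode)
  smp <- vt_samples(vt)
  is_snp <- vt$kind == "SNP"
  no_ad <- is_snp & purrr::map_lgl(vt$ad, is.null)
  if (any(no_ad)) {
    stop("AD absent for SNP record(s), first at ",
         vt$chrom[which(no_ad)[1]], ":", vt$pos[which(no_ad)[1]] + 1L,
         call. = FALSE)
  }

  n_removed_depth <- 0L
  n_het_demoted <- 0L
  n_removed_monomorphic <- 0L
  keep <- rep(TRUE, nrow(vt))
  vt2 <- vt
  for (i in which(is_snp)) {
    d <- vt$ad[[i]]
    g <- vt$gt[[i]]
    called <- !is.na(g[1, ]) & !is.na(g[2, ])
    tot <- colSums(d)
    low <- tot[called] < min_total_depth
    fail_site <- if (mode == "any_below") any(low) else all(low) && any(called)
    if (fail_site) {
      keep[i] <- FALSE
      n_removed_depth <- n_removed_depth + 1L
      next
    }
    het <- called & g[1, ] != g[2, ]
    for (s in which(het)) {
      support <- d[c(g[1, s], g[2, s]) + 1L, s]
      if (any(support < min_het_allele_reads)) {
        g[, s] <- NA_integer_
        n_het_demoted <- n_het_demoted + 1L
      }
    }
    vt2$gt[[i]] <- g
    a <- g[!is.na(g)]
    if (length(unique(a)) < 2L) {
      keep[i] <- FALSE
      n_removed_monomorphic <- n_removed_monomorphic + 1L
    }
  }
  out <- new_variant_table(vt2[keep, ], smp)
  attr(out, "filter_report") <- tibble::tibble(
    criterion = c("snp_low_depth_removed", "het_calls_demoted",
                  "snp_monomorphic_after_demotion_removed", "snp_retained"),
    count = c(n_removed_depth, n_het_demoted, n_removed_monomorphic,
              sum(keep & is_snp))
  )
  out
}

#' Indel filtering
#'
#' Removes indel records failing any of: caller quality below `min_quality`,
#' reference homopolymer context longer than `max_homopolymer`, or indel
#' length (|len(alt) - len(ref)|, longest alt) above `max_len`. A
#' strand-support rule (at least `min_strand_reads` reads per strand) is
#' applied when per-strand counts are available in an `adf`/`adr` pair of
#' list-columns; otherwise it is skipped with a warning. SNP records pass
#' through untouched.
#'
#' @param vt A [variant_table()].
#' @param max_len Maximum indel length retained (boundary inclusive).
#' @param min_quality Minimum caller quality retained (boundary inclusive).
#' @param max_homopolymer Maximum homopolymer context retained (inclusive:
#'   "longer than 10 bp" removes).
#' @param min_strand_reads Strand-support minimum.
#' @return Filtered `variant_table` with a `filter_report` attribute.
#' @export
filter_indels <- function(vt, max_len = 5, min_quality = 20,
                          max_homopolymer = 10, min_strand_reads = 2) {
  is_indel <- vt$kind %in% c("insertion", "deletion")
  len <- purrr::map2_int(vt$ref, vt$alt, function(r, a) {
    if (!length(a)) return(0L)
    as.integer(max(abs(nchar(a) - nchar(r))))
  })
  fail_qual <- is_indel & !is.na(vt$qual) & vt$qual < min_quality
  fail_hom <- is_indel & !is.na(vt$hom_len) & vt$hom_len > max_homopolymer
  fail_len <- is_indel & len > max_len
  has_strand <- all(c("adf", "adr") %in% names(vt))
  fail_strand <- rep(FALSE, nrow(vt))
  if (has_strand) {
    fail_strand <- is_indel & purrr::map2_lgl(vt$adf, vt$adr, function(f, r) {
      if (is.null(f) || is.null(r)) return(FALSE)
      # non-reference allele must be seen min_strand_reads times per strand
      any_alt_f <- max(f[-1, , drop = FALSE] %*% rep(1, ncol(f)))
      any_alt_r <- max(r[-1, , drop = FALSE] %*% rep(1, ncol(r)))
      any_alt_f < min_strand_reads || any_alt_r < min_strand_reads
    })
  } else if (any(is_indel)) {
    warning("per-strand depths unavailable; strand-support rule skipped",
            call. = FALSE)
  }
  drop <- fail_qual | fail_hom | fail_len | fail_strand
  out <- new_variant_table(vt[!drop, ], vt_samples(vt))
  attr(out, "filter_report") <- tibble::tibble(
    criterion = c("indel_low_quality_removed", "indel_homopolymer_removed",
                  "indel_too_long_removed", "indel_strand_support_removed",
                  "indel_retained"),
    count = c(sum(fail_qual), sum(fail_hom), sum(fail_len), sum(fail_strand),
              sum(is_indel & !drop))
  )
  out
}

#' Retrieve the filter report of a QC step
#' @param vt Output of [filter_snps_by_depth()] or [filter_indels()].
#' @return Tibble of criterion/count.
#' @export
qc_report <- function(vt) {
  attr(vt, "filter_report") %||%
    tibble::tibble(criterion = character(), count = integer())
}

#' Per-site and per-individual cohort summaries
#'
#' For biallelic sites: minor allele frequency (over non-missing calls),
#' per-group alternate-allele counts, and per-individual heterozygosity
#' (fraction of that individual's non-missing biallelic SNP calls that are
#' heterozygous). Sites with all genotypes missing are excluded and tallied.
#'
#' @param vt A [variant_table()] (biallelic sites used; others skipped).
#' @param groups Group tibble from [read_group_table()] (optional).
#' @return List with `sites` (tibble: chrom, pos, maf, n_called, monomorphic,
#'   per-group `ac_<group>`/`an_<group>` columns), `individuals` (tibble:
#'   sample, n_called, n_het, het_rate) and `n_all_missing`.
#' @export
site_summaries <- function(vt, groups = NULL) {
  smp <- vt_samples(vt)
  bi <- vt_is_biallelic_snp(vt)
  sub <- vt[bi, ]
  dos <- allele_dosage(new_variant_table(sub, smp))
  n_called <- rowSums(!is.na(dos))
  all_missing <- n_called == 0L
  p_alt <- rowSums(dos, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p_alt, 1 - p_alt)
  sites <- tibble::tibble(
    chrom = sub$chrom, pos = sub$pos,
    maf = maf, n_called = as.integer(n_called),
    monomorphic = maf == 0
  )
  if (!is.null(groups)) {
    for (grp in unique(groups$group)) {
      gs <- group_samples(groups, grp)
      gd <- dos[, gs, drop = FALSE]
      sites[[paste0("ac_", grp)]] <- as.integer(rowSums(gd, na.rm = TRUE))
      sites[[paste0("an_", grp)]] <- as.integer(2 * rowSums(!is.na(gd)))
    }
  }
  sites <- sites[!all_missing, ]

  het <- !is.na(dos) & dos == 1L
  individuals <- tibble::tibble(
    sample = smp,
    n_called = as.integer(colSums(!is.na(dos))),
    n_het = as.integer(colSums(het, na.rm = TRUE))
  )
  individuals$het_rate <- ifelse(individuals$n_called > 0,
                                 individuals$n_het / individuals$n_called,
                                 NA_real_)
  list(sites = sites, individuals = individuals,
       n_all_missing = sum(all_missing))
}

#' Merge copy-number-variant regions across samples
#'
#' Unions strictly overlapping CNV intervals from different samples into
#' merged regions, each annotated with the supporting samples, their states,
#' and the supporting-sample frequency. Adjacent-but-not-overlapping
#' intervals are not merged.
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `sample`, `state`
#'   (`"gain"`/`"loss"`).
#' @param cohort_size Denominator for the frequency (default: number of
#'   distinct samples in `regions`).
#' @return Tibble of merged regions with `samples` (comma-joined), `states`,
#'   `n_samples`, `frequency`.
#' @export
merge_cnv_regions <- function(regions, cohort_size = NULL) {
  stopifnot(all(c("chrom", "start", "end", "sample", "state") %in%
                  names(regions)))
  if (any(regions$start >= regions$end)) {
    stop("empty CNV interval", call. = FALSE)
  }
  if (is.null(cohort_size)) cohort_size <- dplyr::n_distinct(regions$sample)
  if (nrow(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), samples = character(),
                          states = character(), n_samples = integer(),
                          frequency = double()))
  }
  gr <- intervals_to_granges(regions)
  # min.gapwidth = 0: strictly overlapping intervals union, bookended do not
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged)
  )
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  out$samples <- vapply(seq_len(nrow(out)), function(i) {
    paste(sort(unique(regions$sample[sh[qh == i]])), collapse = ",")
  }, character(1))
  out$states <- vapply(seq_len(nrow(out)), function(i) {
    paste(sort(unique(regions$state[sh[qh == i]])), collapse = ",")
  }, character(1))
  out$n_samples <- vapply(seq_len(nrow(out)), function(i) {
    length(unique(regions$sample[sh[qh == i]]))
  }, integer(1))
  out$frequency <- out$n_samples / cohort_size
  dplyr::arrange(out, chrom, start)
}
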