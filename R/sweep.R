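#' Windowed pooled heterozygosity (Hp)
#'
#' For each window, sums the read counts of the most and least abundant
#' allele (nMAJ, nMIN) over the biallelic SNPs inside, pooling allelic
#' depths across `samples`, and evaluates
#' \deqn{Hp = 2 \sum n_{MAJ} \sum n_{MIN} / (\sum n_{MAJ} + \sum n_{MIN})^2.}
#' When a site has no allelic depths, pooled allele counts derived from the
#' genotypes stand in (reported once via a message).
#'
#' @param vt A [variant_table()] (biallelic SNPs used).
#' @param samples Samples pooled (default: all).
#' @param windows Window tibble (`chrom`, `start`, `end`), e.g. from
#'   [tile_windows()].
#' @return `windows` with `n_snps` and `hp` columns appended; windows with
#'   no SNPs carry `NA`.
#' @export
pooled_heterozygosity <- function(vt, samples = vt_samples(vt), windows) {
  if (nrow(windows) == 0) stop("empty window list", call. = FALSE)
  bi <- vt_is_biallelic_snp(vt)
  sub <- vt[bi, ]
  nmaj <- numeric(nrow(sub))
  nmin <- numeric(nrow(sub))
  used_gt_fallback <- FALSE
  ad <- pooled_allele_depth(new_variant_table(sub, vt_samples(vt)), samples)
  dos <- allele_dosage(new_variant_table(sub, vt_samples(vt)), samples)
  for (i in seq_len(nrow(sub))) {
    d <- ad[[i]]
    if (is.null(d)) {
      used_gt_fallback <- TRUE
      n_alt <- sum(dos[i, ], na.rm = TRUE)
      n_tot <- 2 * sum(!is.na(dos[i, ]))
      d <- c(n_tot - n_alt, n_alt)
    }
    nmaj[i] <- max(d)
    nmin[i] <- min(d)
  }
  if (used_gt_fallback) {
    message("allelic depths absent at some sites; ",
            "genotype allele counts used as read-count proxy")
  }
  assign_and_summarise(sub, windows, function(idx) {
    smaj <- sum(nmaj[idx]); smin <- sum(nmin[idx])
    if (smaj + smin == 0) return(NA_real_)
    2 * smaj * smin / (smaj + smin)^2
  }, value_name = "hp")
}

# Shared helper: map sites of `sub` into `windows`, apply `f` to per-window
# site indices, return windows + n_snps + value column.
assign_and_summarise <- function(sub, windows, f, value_name) {
  win_gr <- intervals_to_granges(windows)
  value <- rep(NA_real_, nrow(windows))
  n_snps <- rep(0L, nrow(windows))
  if (nrow(sub) > 0) {
    site_gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$pos + 1L, sub$pos + 1L))
    ov <- GenomicRanges::findOverlaps(win_gr, site_gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (w in unique(qh)) {
      idx <- sh[qh == w]
      n_snps[w] <- length(idx)
      value[w] <- f(idx)
    }
  }
  out <- windows
  out$n_snps <- n_snps
  out[[value_name]] <- value
  out
}

#' Windowed Fst between two sample groups
#'
#' Per-site estimator components are accumulated over each window as a ratio
#' of averages. The default is the Hudson-style plug-in estimator
#' \deqn{N = (p_1-p_2)^2, \quad D = p_1(1-p_2) + p_2(1-p_1),}
#' whose window value is exactly 1 for fixed differences and exactly 0 for
#' identical allele frequencies; the Weir–Cockerham two-population
#' estimator (which corrects for sample size and can go slightly negative)
#' is available via `estimator = "wc"`. Sites monomorphic across both
#' groups or with fewer than two called diploids in either group are
#' skipped.
#'
#' @param vt A [variant_table()] (biallelic SNPs used).
#' @param samples_a,samples_b The two sample groups.
#' @param windows Window tibble.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return `windows` with `n_snps` and `fst` appended (`NA` where no usable
#'   sites fall in the window).
#' @export
fst_windows <- function(vt, samples_a, samples_b, windows,
                        estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  miss <- setdiff(c(samples_a, samples_b), vt_samples(vt))
  if (length(miss)) {
    stop("sample(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bi <- vt_is_biallelic_snp(vt)
  sub <- vt[bi, ]
  da <- allele_dosage(new_variant_table(sub, vt_samples(vt)), samples_a)
  db <- allele_dosage(new_variant_table(sub, vt_samples(vt)), samples_b)
  comp <- fst_site_components(da, db, estimator)
  usable <- comp$usable
  sub2 <- sub[usable, ]
  num <- comp$num[usable]
  den <- comp$den[usable]
  assign_and_summarise(sub2, windows, function(idx) {
    d <- sum(den[idx])
    if (d == 0) return(NA_real_)
    sum(num[idx]) / d
  }, value_name = "fst")
}

# Per-site numerator/denominator for ratio-of-averages Fst.
fst_site_components <- function(da, db, estimator) {
  na_dip <- rowSums(!is.na(da))
  nb_dip <- rowSums(!is.na(db))
  n1 <- 2 * na_dip
  n2 <- 2 * nb_dip
  p1 <- rowSums(da, na.rm = TRUE) / n1
  p2 <- rowSums(db, na.rm = TRUE) / n2
  usable <- na_dip >= 2 & nb_dip >= 2 &
    !(p1 %in% c(0, 1) & p2 == p1)          # skip monomorphic-in-both
  if (estimator == "hudson") {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir & Cockerham (1984), two populations, no inbreeding correction:
    # variance components from allele frequencies only
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    num <- s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1)
    den <- pbar * (1 - pbar) + s2 / r
  }
  list(num = num, den = den, usable = usable)
}

#' Z-transform a vector of window statistics
#'
#' Centers and scales by the sample (n-1) standard deviation over the finite
#' values; `NA`s pass through. At least two finite values and positive
#' variance are required.
#'
#' @param x Numeric vector.
#' @return Numeric vector of z-scores, same length as `x`.
#' @export
z_transform <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 2) {
    stop("z_transform() needs at least two finite values", call. = FALSE)
  }
  s <- stats::sd(v)
  if (s == 0) stop("zero variance in z_transform()", call. = FALSE)
  (x - mean(v)) / s
}

#' Classify domestication-associated gene (DAG) windows and genes
#'
#' A window is a sweep candidate when `zhp <= zhp_cut` OR
#' `zfst >= zfst_cut` (thresholds inclusive). A DAG is any gene overlapping
#' at least one flagged window.
#'
#' @param stats Window tibble with `chrom`, `start`, `end`, `zhp`, `zfst`.
#' @param genes Gene-model tibble.
#' @param zhp_cut,zfst_cut Thresholds (defaults -3 and 3).
#' @return A `sweep_calls` object: list with `windows` (flagged windows and
#'   triggering `rule`), `genes` (gene ids with rules), `kind = "DAG"` and
#'   `params`. Methods: [tidy()][generics::tidy],
#'   [glance()][generics::glance], [autoplot()][ggplot2::autoplot].
#' @export
classify_dags <- function(stats, genes, zhp_cut = -3, zfst_cut = 3) {
  hp_arm <- !is.na(stats$zhp) & stats$zhp <= zhp_cut
  fst_arm <- !is.na(stats$zfst) & stats$zfst >= zfst_cut
  flagged <- stats[hp_arm | fst_arm, , drop = FALSE]
  flagged$rule <- dplyr::case_when(
    hp_arm[hp_arm | fst_arm] & fst_arm[hp_arm | fst_arm] ~ "low_hp,high_fst",
    hp_arm[hp_arm | fst_arm] ~ "low_hp",
    TRUE ~ "high_fst"
  )
  new_sweep_calls(flagged, genes, kind = "DAG",
                  params = list(zhp_cut = zhp_cut, zfst_cut = zfst_cut))
}

#' Classify trait-associated gene (TAG) windows and genes for one breed
#'
#' A window is a breed sweep candidate when its breed-vs-pooled-others
#' `zfst >= zfst_cut` AND its windowed XP-EHH value lies in the top
#' `xpehh_top_frac` of windows that carry a score (the focal breed is the
#' XP-EHH numerator population). The top set is the `ceiling(frac * n)`
#' highest-scoring windows, ties broken by genomic order, so at most that
#' many windows can ever be flagged. A TAG is any gene overlapping a
#' flagged window.
#'
#' @param stats Window tibble with `chrom`, `start`, `end`, `zfst`,
#'   `xpehh`.
#' @param genes Gene-model tibble.
#' @param zfst_cut Fst arm threshold (default 4, inclusive).
#' @param xpehh_top_frac Fraction of scored windows forming the XP-EHH top
#'   set (default 0.01).
#' @return A `sweep_calls` object with `kind = "TAG"`.
#' @export
classify_tags <- function(stats, genes, zfst_cut = 4, xpehh_top_frac = 0.01) {
  if (!"xpehh" %in% names(stats) || all(is.na(stats$xpehh))) {
    stop("window XP-EHH values are required; compute them with ",
         "xpehh_scan() + window_xpehh() first", call. = FALSE)
  }
  scored <- which(!is.na(stats$xpehh))
  k <- as.integer(ceiling(xpehh_top_frac * length(scored)))
  top_idx <- scored[order(-stats$xpehh[scored], scored)][seq_len(k)]
  in_top <- seq_len(nrow(stats)) %in% top_idx
  fst_arm <- !is.na(stats$zfst) & stats$zfst >= zfst_cut
  flagged <- stats[fst_arm & in_top, , drop = FALSE]
  if (nrow(flagged)) flagged$rule <- "high_fst,top_xpehh"
  else flagged$rule <- character(0)
  new_sweep_calls(flagged, genes, kind = "TAG",
                  params = list(zfst_cut = zfst_cut,
                                xpehh_top_frac = xpehh_top_frac))
}

new_sweep_calls <- function(flagged, genes, kind, params) {
  gene_calls <- tibble::tibble(gene_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               n_windows = integer(), rules = character())
  if (nrow(flagged) > 0 && nrow(genes) > 0) {
    gene_gr <- intervals_to_granges(genes)
    win_gr <- intervals_to_granges(flagged)
    ov <- GenomicRanges::findOverlaps(gene_gr, win_gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(ov)) {
      gene_calls <- purrr::map_dfr(unique(qh), function(g) {
        tibble::tibble(
          gene_id = genes$gene_id[g], chrom = genes$chrom[g],
          start = genes$start[g], end = genes$end[g],
          n_windows = sum(qh == g),
          rules = paste(sort(unique(flagged$rule[sh[qh == g]])),
                        collapse = ";")
        )
      })
    }
  }
  structure(list(windows = tibble::as_tibble(flagged), genes = gene_calls,
                 kind = kind, params = params),
            class = "sweep_calls")
}

#' @export
print.sweep_calls <- function(x, ...) {
  cat(sprintf("<sweep_calls: %s>  %d flagged window(s), %d gene(s)\n",
              x$kind, nrow(x$windows), nrow(x$genes)))
  if (nrow(x$genes)) print(x$genes, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sweep-calls object into its gene table
#' @param x A `sweep_calls` object.
#' @param ... Unused.
#' @return Tibble of classified genes.
#' @export
tidy.sweep_calls <- function(x, ...) x$genes

#' One-row summary of a sweep-calls object
#' @param x A `sweep_calls` object.
#' @param ... Unused.
#' @return One-row tibble: kind, window and gene counts, thresholds.
#' @export
glance.sweep_calls <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_windows = nrow(x$windows),
                 n_genes = nrow(x$genes),
                 !!!x$params)
}

#' Cross-reference genes against QTL intervals
#'
#' @param genes Gene-model tibble (or any tibble with `gene_id`, `chrom`,
#'   `start`, `end`).
#' @param qtl QTL tibble (`chrom`, `start`, `end`, optional `name`).
#' @return Tibble of overlapping `gene_id` / `qtl_id` pairs.
#' @export
crossref_qtl <- function(genes, qtl) {
  if (!"name" %in% names(qtl)) {
    qtl$name <- sprintf("QTL%03d", seq_len(nrow(qtl)))
  }
  out <- tibble::tibble(gene_id = character(), qtl_id = character())
  if (nrow(genes) == 0 || nrow(qtl) == 0) return(out)
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(genes),
                                    intervals_to_granges(qtl))
  tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::queryHits(ov)],
    qtl_id = qtl$name[S4Vectors::subjectHits(ov)]
  ) |> dplyr::distinct()
}
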