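#' Domestication scan: pooled heterozygosity and Fst with Z-scores
#'
#' Computes, on 100-kb windows (by default), the pooled heterozygosity of
#' the domestic samples and the Fst between the domestic pool and the wild
#' outgroup, then Z-transforms both over the windows that carry SNPs. This
#' is the window table [classify_dags()] consumes.
#'
#' @param vt A filtered [variant_table()].
#' @param groups Group tibble (`sample`, `group`).
#' @param wild_group Label of the wild outgroup (default `"wild"`).
#' @param chrom_lengths Named chromosome lengths.
#' @param window,step Window geometry (default 100-kb tiles).
#' @param estimator Fst estimator, see [fst_windows()].
#' @return Window tibble with `n_snps`, `hp`, `zhp`, `fst`, `zfst`.
#' @export
scan_domestication <- function(vt, groups, wild_group = "wild",
                               chrom_lengths, window = 100000L,
                               step = window,
                               estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  wild <- group_samples(groups, wild_group)
  domestic <- setdiff(groups$sample, wild)
  wins <- tile_windows(chrom_lengths, window, step)
  hp <- pooled_heterozygosity(vt, domestic, wins)
  fst <- fst_windows(vt, domestic, wild, wins, estimator)
  out <- hp
  out$fst <- fst$fst
  out$zhp <- z_transform(out$hp)
  out$zfst <- z_transform(out$fst)
  class(out) <- unique(c("sweep_windows", class(out)))
  out
}

#' Breed scan: breed-vs-others Fst plus windowed XP-EHH
#'
#' For one focal breed, computes the windowed Fst of the breed against the
#' pooled other domestic breeds, Z-transforms it, runs the XP-EHH scan
#' (focal breed as numerator) on phased haplotypes, and aggregates
#' normalized scores per window. This is the window table
#' [classify_tags()] consumes.
#'
#' @param vt A filtered, phased [variant_table()].
#' @param groups Group tibble.
#' @param focal Focal breed label.
#' @param wild_group Wild outgroup label (excluded from the reference
#'   pool).
#' @param chrom_lengths Named chromosome lengths.
#' @param window,step Window geometry (default 100-kb tiles).
#' @param estimator Fst estimator.
#' @param max_cores Core-site thinning cap per chromosome for the XP-EHH
#'   scan (default 2000; evenly spaced, deterministic — ample core density
#'   for 100-kb windows).
#' @param min_ehh,max_extension_bp EHH truncation, see [ehh_profile()].
#' @param aggregate Window aggregation of XP-EHH scores (`"max"` default).
#' @return Window tibble with `n_snps`, `fst`, `zfst`, `n_cores`, `xpehh`.
#' @export
scan_breed <- function(vt, groups, focal, wild_group = "wild",
                       chrom_lengths, window = 100000L, step = window,
                       estimator = c("hudson", "wc"), max_cores = 2000L,
                       min_ehh = 0.05, max_extension_bp = 1e6,
                       aggregate = c("max", "mean")) {
  estimator <- match.arg(estimator)
  aggregate <- match.arg(aggregate)
  focal_samples <- group_samples(groups, focal)
  others <- setdiff(groups$sample,
                    c(focal_samples, group_samples(groups, wild_group)))
  wins <- tile_windows(chrom_lengths, window, step)
  out <- fst_windows(vt, focal_samples, others, wins, estimator)
  out$zfst <- z_transform(out$fst)
  out$n_cores <- 0L
  out$xpehh <- NA_real_
  for (chr in names(chrom_lengths)) {
    pf <- try(haplotype_panel_from_table(vt, focal_samples, chr,
                                         pop = focal), silent = TRUE)
    pr <- try(haplotype_panel_from_table(vt, others, chr, pop = "others"),
              silent = TRUE)
    if (inherits(pf, "try-error") || inherits(pr, "try-error")) next
    shared <- intersect(pf$positions, pr$positions)
    if (length(shared) < 2) next
    pf <- subset_panel(pf, match(shared, pf$positions))
    pr <- subset_panel(pr, match(shared, pr$positions))
    sc <- try(xpehh_scan(pf, pr, max_cores = max_cores, min_ehh = min_ehh,
                         max_extension_bp = max_extension_bp),
              silent = TRUE)
    if (inherits(sc, "try-error")) next
    wchr <- out$chrom == chr
    agg <- window_xpehh(sc, out[wchr, c("chrom", "start", "end")],
                        chrom = chr, aggregate = aggregate)
    out$n_cores[wchr] <- agg$n_cores
    out$xpehh[wchr] <- agg$xpehh
  }
  class(out) <- unique(c("sweep_windows", class(out)))
  out
}

#' Restrict a haplotype panel to a subset of site columns
#' @param panel A [haplotype_panel()].
#' @param idx Column indices (increasing).
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(panel, idx) {
  haplotype_panel(panel$h[, idx, drop = FALSE], panel$positions[idx],
                  pop = panel$pop)
}
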