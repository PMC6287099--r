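#' Construct a phased haplotype panel
#'
#' A haplotype panel is the substrate of the EHH/XP-EHH statistics: a binary
#' haplotype-by-site matrix over strictly increasing physical positions,
#' with no missing alleles and at least four haplotypes.
#'
#' @param h Integer/numeric 0-1 matrix, haplotypes in rows, sites in
#'   columns.
#' @param positions 0-based physical positions, strictly increasing, one per
#'   column.
#' @param pop Population label.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(h, positions, pop = "pop") {
  h <- as.matrix(h)
  storage.mode(h) <- "integer"
  if (nrow(h) < 4) stop("a haplotype panel needs >= 4 haplotypes",
                        call. = FALSE)
  if (anyNA(h)) stop("missing alleles are not allowed in a panel",
                     call. = FALSE)
  if (!all(h %in% c(0L, 1L))) stop("panel alleles must be 0/1",
                                   call. = FALSE)
  if (ncol(h) != length(positions)) {
    stop("one position per site column required", call. = FALSE)
  }
  if (ncol(h) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  structure(list(h = h, positions = as.numeric(positions), pop = pop),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel '%s'> %d haplotypes x %d sites\n",
              x$pop, nrow(x$h), ncol(x$h)))
  invisible(x)
}

#' Build a haplotype panel from a phased variant table
#'
#' Uses biallelic SNPs on one chromosome with fully phased, non-missing
#' genotypes in the chosen samples; other sites are dropped (they are
#' excluded upstream by contract).
#'
#' @param vt A [variant_table()].
#' @param samples Samples contributing two haplotypes each.
#' @param chrom Chromosome to use (default: the single chromosome present).
#' @param pop Population label.
#' @return A `haplotype_panel`.
#' @export
haplotype_panel_from_table <- function(vt, samples, chrom = NULL,
                                       pop = "pop") {
  if (is.null(chrom)) {
    chrom <- unique(vt$chrom)
    if (length(chrom) != 1) {
      stop("specify `chrom` for a multi-chromosome table", call. = FALSE)
    }
  }
  sub <- vt[vt$chrom == chrom & vt_is_biallelic_snp(vt), ]
  ok <- purrr::map2_lgl(sub$gt, sub$phased, function(g, p) {
    gs <- g[, samples, drop = FALSE]
    !anyNA(gs) && all(p[samples] | gs[1, ] == gs[2, ])
  })
  if (!all(ok)) {
    if (sum(!ok) == nrow(sub)) {
      stop("no phased, fully called biallelic SNPs for these samples",
           call. = FALSE)
    }
  }
  sub <- sub[ok, ]
  h <- do.call(cbind, purrr::map(sub$gt, function(g) {
    as.vector(g[, samples, drop = FALSE])
  }))
  rownames(h) <- paste0(rep(samples, each = 2), c(".1", ".2"))
  haplotype_panel(h, sub$pos, pop = pop)
}

#' Extended haplotype homozygosity profile at a core site
#'
#' EHH at a flanking site x is the probability that two randomly drawn
#' haplotypes are identical over all panel sites strictly between the core
#' and x inclusive of x (the core site itself does not split haplotypes, so
#' EHH at the core is 1):
#' \deqn{EHH(x) = \sum_h \binom{n_h}{2} / \binom{n}{2}}
#' over haplotype-identity groups h. The profile extends outward in both
#' directions until EHH drops below `min_ehh`, the physical extension
#' exceeds `max_extension_bp`, or the panel edge is reached. iHH is the
#' trapezoidal integral of the EHH curve against physical distance (with
#' EHH = 1 at distance 0), left plus right.
#'
#' @param panel A [haplotype_panel()].
#' @param core_index Column index of the core site.
#' @param min_ehh Truncation threshold (default 0.05).
#' @param max_extension_bp Maximum extension per direction (default 1 Mb).
#' @return An `ehh_profile` object: list with per-direction tibbles
#'   (`pos`, `ehh`), `ihh_left`, `ihh_right`, `ihh`, and per-direction
#'   `decayed` / `hit_edge` flags.
#' @export
ehh_profile <- function(panel, core_index, min_ehh = 0.05,
                        max_extension_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_sites <- ncol(panel$h)
  if (core_index < 1 || core_index > n_sites) {
    stop("core_index out of range", call. = FALSE)
  }
  left <- ehh_direction(panel, core_index, -1L, min_ehh, max_extension_bp)
  right <- ehh_direction(panel, core_index, +1L, min_ehh, max_extension_bp)
  structure(list(
    core_index = core_index,
    core_pos = panel$positions[core_index],
    left = left$curve, right = right$curve,
    ihh_left = left$ihh, ihh_right = right$ihh,
    ihh = left$ihh + right$ihh,
    decayed_left = left$decayed, decayed_right = right$decayed,
    hit_edge_left = left$hit_edge, hit_edge_right = right$hit_edge
  ), class = "ehh_profile")
}

ehh_direction <- function(panel, core_index, dir, min_ehh, max_extension_bp) {
  w <- ehh_walk_cpp(panel$h, panel$positions, core_index, dir, min_ehh,
                    max_extension_bp)
  list(curve = tibble::tibble(pos = w$pos, ehh = w$ehh),
       ihh = w$ihh, decayed = w$decayed, hit_edge = w$hit_edge)
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat(sprintf(
    "<ehh_profile> core %d @ %d | iHH = %.1f (L %.1f + R %.1f)\n",
    x$core_index, as.integer(x$core_pos), x$ihh, x$ihh_left, x$ihh_right))
  invisible(x)
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For each core site, computes iHH in the focal and reference panels (which
#' must share the same site positions) and scores
#' `raw = ln(iHH_focal / iHH_reference)`; raw scores are normalized to mean
#' 0, sd 1 over all scored cores. Cores where either iHH is 0 are skipped
#' and tallied, as are cores whose EHH fails to decay below `min_ehh`
#' before a panel edge in either population (edge bias), unless
#' `skip_undecayed_edges = FALSE`.
#'
#' @param panel_focal,panel_reference Two [haplotype_panel()]s over the same
#'   positions.
#' @param cores Core column indices (default: all sites polymorphic in the
#'   pooled panels).
#' @param max_cores Deterministic even thinning cap on the number of cores
#'   (default `Inf` = all).
#' @param min_ehh,max_extension_bp Passed to [ehh_profile()].
#' @param skip_undecayed_edges Skip edge-truncated, undecayed cores?
#' @return Tibble with `core_index`, `pos`, `ihh_focal`, `ihh_reference`,
#'   `raw`, `xpehh` (normalized); attributes `n_skipped_zero_ihh`,
#'   `n_skipped_edge`.
#' @export
xpehh_scan <- function(panel_focal, panel_reference, cores = NULL,
                       max_cores = Inf, min_ehh = 0.05,
                       max_extension_bp = 1e6,
                       skip_undecayed_edges = TRUE) {
  stopifnot(inherits(panel_focal, "haplotype_panel"),
            inherits(panel_reference, "haplotype_panel"))
  if (!identical(panel_focal$positions, panel_reference$positions)) {
    stop("panels must share identical site positions", call. = FALSE)
  }
  if (is.null(cores)) {
    pooled <- rbind(panel_focal$h, panel_reference$h)
    f <- colSums(pooled)
    cores <- which(f > 0 & f < nrow(pooled))
  }
  if (length(cores) > max_cores) {
    cores <- cores[unique(round(seq(1, length(cores),
                                    length.out = max_cores)))]
  }
  if (!length(cores)) stop("no usable core sites", call. = FALSE)

  n_core <- length(cores)
  ihh_f <- numeric(n_core)
  ihh_r <- numeric(n_core)
  edge <- logical(n_core)
  for (j in seq_len(n_core)) {
    pf <- ihh_cpp(panel_focal$h, panel_focal$positions, cores[j], min_ehh,
                  max_extension_bp)
    pr <- ihh_cpp(panel_reference$h, panel_reference$positions, cores[j],
                  min_ehh, max_extension_bp)
    ihh_f[j] <- pf$ihh
    ihh_r[j] <- pr$ihh
    edge[j] <- pf$undecayed_edge || pr$undecayed_edge
  }
  tb <- tibble::tibble(core_index = cores,
                       pos = panel_focal$positions[cores],
                       ihh_focal = ihh_f, ihh_reference = ihh_r,
                       edge = edge)
  n_edge <- 0L
  if (skip_undecayed_edges) {
    n_edge <- sum(tb$edge)
    tb <- tb[!tb$edge, ]
  }
  zero <- tb$ihh_focal == 0 | tb$ihh_reference == 0
  n_zero <- sum(zero)
  tb <- tb[!zero, ]
  if (nrow(tb) == 0) stop("no usable core sites after skipping", call. = FALSE)
  tb$raw <- log(tb$ihh_focal / tb$ihh_reference)
  tb$xpehh <- if (nrow(tb) >= 2 && stats::sd(tb$raw) > 0) {
    z_transform(tb$raw)
  } else {
    rep(0, nrow(tb))
  }
  tb$edge <- NULL
  attr(tb, "n_skipped_zero_ihh") <- n_zero
  attr(tb, "n_skipped_edge") <- n_edge
  tb
}

#' Aggregate XP-EHH scores into windows
#'
#' @param scores Tibble from [xpehh_scan()] (normalized scores in `xpehh`),
#'   plus a `chrom` column or a single-chromosome assumption.
#' @param windows Window tibble (`chrom`, `start`, `end`).
#' @param chrom Chromosome of the scores when `scores` lacks a `chrom`
#'   column.
#' @param aggregate `"max"` (default) or `"mean"` over cores inside each
#'   window.
#' @return `windows` with `n_cores` and `xpehh` appended (`NA` for windows
#'   without cores).
#' @export
window_xpehh <- function(scores, windows, chrom = NULL,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!"chrom" %in% names(scores)) {
    if (is.null(chrom)) {
      chrom <- unique(windows$chrom)
      if (length(chrom) != 1) {
        stop("supply `chrom` for multi-chromosome windows", call. = FALSE)
      }
    }
    scores$chrom <- chrom
  }
  win_gr <- intervals_to_granges(windows)
  sc_gr <- GenomicRanges::GRanges(
    scores$chrom, IRanges::IRanges(scores$pos + 1L, scores$pos + 1L))
  ov <- GenomicRanges::findOverlaps(win_gr, sc_gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- windows
  out$n_cores <- 0L
  out$xpehh <- NA_real_
  agg_fun <- if (aggregate == "max") max else mean
  for (w in unique(qh)) {
    vals <- scores$xpehh[sh[qh == w]]
    out$n_cores[w] <- length(vals)
    out$xpehh[w] <- agg_fun(vals)
  }
  out
}
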