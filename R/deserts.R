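#' Tile a genome into fixed windows
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window Window span in bp.
#' @param step Step between window starts (default `window`:
#'   non-overlapping tiles).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_lengths, window = 10000L, step = window) {
  if (window <= 0 || step <= 0) {
    stop("window and step must be positive", call. = FALSE)
  }
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chr) {
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    tibble::tibble(chrom = chr, start = as.integer(starts),
                   end = as.integer(pmin(starts + window, len)))
  })
}

#' Windowed SNP rates normalized by callable length
#'
#' Counts SNPs per window and normalizes by the callable bases (the part of
#' the window covered by the \eqn{\ge}8-fold-depth mask) rather than the
#' window span. Windows with fewer than `min_callable` callable bases fail
#' QC and carry no rate.
#'
#' @param vt A [variant_table()] (only `kind == "SNP"` rows are counted).
#' @param mask Callable-mask tibble (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()].
#' @param window,step Window geometry in bp (default 10-kb tiles).
#' @param chrom_lengths Named lengths; default inferred from the mask
#'   (maximum end per chromosome).
#' @param min_callable QC cutoff on callable bases (default 1000).
#' @return Tibble with `chrom`, `start`, `end`, `callable_bp`, `n_snps`,
#'   `snp_rate`, `qc_pass`.
#' @export
snp_rate_windows <- function(vt, mask, window = 10000L, step = window,
                             chrom_lengths = NULL, min_callable = 1000L) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(mask$end, mask$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  wins <- tile_windows(chrom_lengths, window, step)
  win_gr <- intervals_to_granges(wins)
  mask_gr <- intervals_to_granges(mask)
  ov <- GenomicRanges::findOverlaps(win_gr, mask_gr)
  pieces <- IRanges::pintersect(win_gr[S4Vectors::queryHits(ov)],
                                mask_gr[S4Vectors::subjectHits(ov)])
  callable <- rep(0L, nrow(wins))
  if (length(ov)) {
    agg <- tapply(GenomicRanges::width(pieces), S4Vectors::queryHits(ov), sum)
    callable[as.integer(names(agg))] <- as.integer(agg)
  }
  snps <- vt[vt$kind == "SNP", ]
  n_snps <- rep(0L, nrow(wins))
  if (nrow(snps)) {
    site_gr <- GenomicRanges::GRanges(
      snps$chrom, IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
    cnt <- GenomicRanges::countOverlaps(win_gr, site_gr)
    n_snps <- as.integer(cnt)
  }
  wins$callable_bp <- callable
  wins$n_snps <- n_snps
  wins$qc_pass <- callable >= min_callable
  wins$snp_rate <- ifelse(wins$qc_pass, n_snps / callable, NA_real_)
  wins
}

#' Call SNP deserts from windowed rates
#'
#' Seeds are QC-passing windows whose SNP rate falls at or below the
#' empirical lower `quantile` of QC-passing rates (sorted-rank selection with
#' ceiling rank; ties included). Seeds on the same chromosome are joined
#' into one desert when the gap between them is at most `join_gap`; a
#' desert's interval spans from the first to the last member window (gaps
#' included), so desert length can exceed the summed seed spans.
#'
#' @param windows Tibble from [snp_rate_windows()].
#' @param quantile Lower-tail fraction defining seeds (default 0.10).
#' @param join_gap Maximum gap joined, bp (default 10 kb, inclusive).
#' @return Tibble with `chrom`, `start`, `end`, `length`, `n_windows`,
#'   `mean_rate`.
#' @export
call_deserts <- function(windows, quantile = 0.10, join_gap = 10000L) {
  ok <- windows[windows$qc_pass & !is.na(windows$snp_rate), ]
  if (nrow(ok) == 0) {
    warning("no QC-passing windows; empty desert set", call. = FALSE)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length = integer(),
                          n_windows = integer(), mean_rate = double()))
  }
  cutoff <- desert_rate_cutoff(ok$snp_rate, quantile)
  seeds <- ok[ok$snp_rate <= cutoff, ]
  seeds <- dplyr::arrange(seeds, chrom, start)
  grp <- integer(nrow(seeds))
  gid <- 0L
  for (i in seq_len(nrow(seeds))) {
    new_region <- i == 1L ||
      seeds$chrom[i] != seeds$chrom[i - 1L] ||
      (seeds$start[i] - seeds$end[i - 1L]) > join_gap
    if (new_region) gid <- gid + 1L
    grp[i] <- gid
  }
  seeds$.grp <- grp
  seeds |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      mean_rate = mean(.data$snp_rate),
      .groups = "drop"
    ) |>
    dplyr::mutate(length = .data$end - .data$start) |>
    dplyr::select("chrom", "start", "end", "length", "n_windows",
                  "mean_rate") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Lowest-`quantile` rate cutoff by ceiling-rank selection on sorted rates.
desert_rate_cutoff <- function(rates, quantile) {
  r <- sort(rates)
  r[max(1L, ceiling(quantile * length(r)))]
}

#' Classify SNP-desert-associated genes (SAGs)
#'
#' A gene is a SAG when strictly more than `min_overlap_frac` of its genomic
#' span (introns included) is covered by deserts.
#'
#' @param deserts Desert tibble from [call_deserts()].
#' @param genes Gene-model tibble.
#' @param min_overlap_frac Strict lower bound on the covered fraction
#'   (default 0.30).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `desert_bp`,
#'   `overlap_frac`, `sag`.
#' @export
classify_sags <- function(deserts, genes, min_overlap_frac = 0.30) {
  out <- tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start, end = genes$end,
    desert_bp = 0L
  )
  if (nrow(deserts) > 0 && nrow(genes) > 0) {
    gene_gr <- intervals_to_granges(genes)
    des_gr <- GenomicRanges::reduce(intervals_to_granges(deserts))
    ov <- GenomicRanges::findOverlaps(gene_gr, des_gr)
    pieces <- IRanges::pintersect(gene_gr[S4Vectors::queryHits(ov)],
                                  des_gr[S4Vectors::subjectHits(ov)])
    if (length(ov)) {
      agg <- tapply(GenomicRanges::width(pieces),
                    S4Vectors::queryHits(ov), sum)
      out$desert_bp[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  out$overlap_frac <- out$desert_bp / (out$end - out$start)
  out$sag <- out$overlap_frac > min_overlap_frac
  out
}

#' Deserts longer than a minimum length
#' @param deserts Desert tibble.
#' @param min_length Strict lower bound in bp (default 100 kb).
#' @return Filtered desert tibble.
#' @export
large_deserts <- function(deserts, min_length = 100000L) {
  deserts[deserts$length > min_length, ]
}

#' The top-k largest deserts
#' @param deserts Desert tibble.
#' @param k Number to keep (default 10).
#' @return Desert tibble sorted by decreasing length, at most `k` rows.
#' @export
top_deserts <- function(deserts, k = 10L) {
  deserts |>
    dplyr::arrange(dplyr::desc(.data$length), .data$chrom, .data$start) |>
    utils::head(k)
}
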