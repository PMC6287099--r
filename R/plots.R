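#' Manhattan-style track plot of windowed sweep statistics
#'
#' Plots ZHp (sign-flipped axis so sweeps point up) and/or ZFst against
#' window midpoint, one facet per statistic, with threshold lines — the
#' standard two-track genome-scan figure.
#'
#' @param stats Window tibble from [scan_domestication()] /
#'   [scan_breed()] (uses whichever of `zhp`, `zfst`, `xpehh` exist).
#' @param zhp_cut,zfst_cut Threshold lines (defaults -3 and 3; pass `NA`
#'   to omit).
#' @return A ggplot object.
#' @export
plot_sweep_tracks <- function(stats, zhp_cut = -3, zfst_cut = 3) {
  tracks <- intersect(c("zhp", "zfst", "xpehh"), names(stats))
  long <- stats |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    tidyr::pivot_longer(dplyr::all_of(tracks), names_to = "stat",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  cuts <- tibble::tibble(
    stat = c("zhp", "zfst"),
    cut = c(zhp_cut, zfst_cut)
  ) |> dplyr::filter(.data$stat %in% tracks, !is.na(.data$cut))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value,
                                     colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cut),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$stat),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free", space = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' SNP-rate distribution plot
#'
#' Histogram of windowed SNP rates (QC-passing windows), the figure used to
#' compare the rate distributions of breeds; the lowest-decile desert
#' cutoff is marked.
#'
#' @param windows Tibble from [snp_rate_windows()], or a named list of them
#'   (one per breed).
#' @param quantile Desert quantile to mark (default 0.10).
#' @return A ggplot object.
#' @export
plot_snp_rate <- function(windows, quantile = 0.10) {
  if (!is.data.frame(windows)) {
    windows <- purrr::imap_dfr(windows, function(w, nm) {
      w$group <- nm
      w
    })
  } else if (!"group" %in% names(windows)) {
    windows$group <- "all"
  }
  ok <- windows[windows$qc_pass & !is.na(windows$snp_rate), ]
  cuts <- ok |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cut = desert_rate_cutoff(.data$snp_rate, quantile),
                     .groups = "drop")
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$snp_rate)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$cut),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "SNP rate (per callable bp)", y = "windows") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a sweep-calls object
#'
#' Draws the flagged windows as genomic segments coloured by triggering
#' rule.
#'
#' @param object A `sweep_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_calls <- function(object, ...) {
  w <- object$windows
  if (nrow(w) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no flagged windows") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(w) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$chrom, yend = .data$chrom,
                                       colour = .data$rule),
                          linewidth = 4) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("%s candidate windows", object$kind)) +
    ggplot2::theme_minimal()
}
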