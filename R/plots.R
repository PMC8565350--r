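#' Plot condition-level colocalization ratios
#'
#' Point-and-error-bar plot of mean C_R +/- SD per condition, with a dashed
#' reference line at C_R = 1 (the no-enrichment expectation for DNA
#' distributed independently of the liposomes).
#'
#' @param summary Condition summary tibble from [summarize_coloc()].
#' @return A ggplot object.
#' @export
plot_coloc_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$condition_id, y = .data$mean_C_R
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_C_R - .data$sd_C_R,
      ymax = .data$mean_C_R + .data$sd_C_R
    )) +
    ggplot2::labs(x = NULL, y = expression(C[R] ~ "(mean ± SD)")) +
    ggplot2::theme_minimal()
}

#' Plot metric-vs-coverage bias diagnostics
#'
#' Scatter of each colocalization metric against liposome coverage with the
#' fitted regression line; the companion numbers live in the
#' [area_bias_check()] report.
#'
#' @param results Per-image colocalization tibble (needs `coverage`, `C_R`,
#'   `pearson_r`).
#' @return A ggplot object, facetted by metric.
#' @export
plot_area_bias <- function(results) {
  long <- results |>
    dplyr::select(dplyr::all_of(c("coverage", "C_R", "pearson_r"))) |>
    tidyr::pivot_longer(-"coverage", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$coverage, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "liposome coverage (fraction of pixels)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_area_bias
#' @param object A `coloc_bias_report` from [area_bias_check()].
#' @param ... Unused.
#' @export
autoplot.coloc_bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ci_low, ymax = .data$ci_high
    )) +
    ggplot2::labs(x = NULL, y = "slope of metric vs coverage (95% CI)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot lane intensity profiles of a gel image
#'
#' Column-summed intensity along the migration axis for each annotated
#' lane, with the band box shaded; the standard visual check that boxes
#' sit on the band.
#'
#' @param image Numeric gel matrix.
#' @param lanes Lane annotation tibble (see [measure_gel()]).
#' @return A ggplot object, facetted by lane.
#' @export
plot_lane_profiles <- function(image, lanes) {
  prof <- purrr::map(seq_len(nrow(lanes)), function(i) {
    ln <- lanes[i, ]
    cols <- (ln$x0 + 1):(ln$x0 + ln$w)
    tibble(
      lane_id = ln$lane_id, y = seq_len(nrow(image)),
      intensity = rowSums(image[, cols, drop = FALSE]),
      band_lo = ln$y0, band_hi = ln$y0 + ln$h
    )
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$y, y = .data$intensity)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$band_lo, xmax = .data$band_hi,
      ymin = -Inf, ymax = Inf
    ), fill = "grey90") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~lane_id) +
    ggplot2::labs(x = "migration axis (px, well at 0)",
                  y = "lane-summed intensity") +
    ggplot2::theme_minimal()
}

#' Show the two channels of a field of view
#'
#' Raster rendering of the lipid and DNA channels side by side, each scaled
#' to its own intensity range.
#'
#' @param img A [two_channel_image()].
#' @param downsample Keep every k-th pixel for speed (default 1 = all).
#' @return A ggplot object.
#' @export
plot_two_channel <- function(img, downsample = 1) {
  stopifnot(inherits(img, "two_channel_image"))
  idx_r <- seq(1, nrow(img$lipid), by = downsample)
  idx_c <- seq(1, ncol(img$lipid), by = downsample)
  to_long <- function(m, ch) {
    tibble(
      row = rep(idx_r, times = length(idx_c)),
      col = rep(idx_c, each = length(idx_r)),
      intensity = as.vector(m[idx_r, idx_c]),
      channel = ch
    )
  }
  long <- dplyr::bind_rows(to_long(img$lipid, "lipid"),
                           to_long(img$dna, "dna"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$intensity
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = img$image_id) +
    ggplot2::theme_minimal()
}
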