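#' Integrate a gel band with flanking-box background correction
#'
#' Sums pixel intensities over a band box and subtracts a per-pixel
#' background estimated as the median intensity of two flanking boxes of
#' equal size directly above and below the band box (same columns). The
#' corrected integral is floored at zero; a negative value before flooring
#' is reported with a warning since it usually signals a mis-drawn box or
#' an unusually noisy lane.
#'
#' @param image Numeric matrix (rows = migration axis).
#' @param lane One-row data frame (or list) with box fields `x0`, `y0`, `w`,
#'   `h` (0-based, half-open) and optionally `lane_id`, `gel_id`, `pair`,
#'   `role` which are carried through.
#' @return A one-row tibble with `raw_integral`, `background_per_pixel`,
#'   `integrated_intensity` (corrected, floored at 0) and `flagged_negative`.
#' @export
#' @examples
#' img <- matrix(5, 60, 20)
#' img[25:35, 6:15] <- 105
#' integrate_band(img, list(x0 = 5, y0 = 24, w = 10, h = 12))
integrate_band <- function(image, lane) {
  x0 <- lane$x0
  y0 <- lane$y0
  w <- lane$w
  h <- lane$h
  if (any(!vapply(list(x0, y0, w, h), is_number, TRUE)) || w < 1 || h < 1) {
    abort("lane box needs numeric `x0`, `y0` and positive `w`, `h`.")
  }
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image)) {
    abort("lane box lies outside the image.")
  }
  if (y0 - h < 0 || y0 + 2 * h > nrow(image)) {
    abort("flanking background boxes lie outside the image.")
  }
  rows <- (y0 + 1):(y0 + h)
  cols <- (x0 + 1):(x0 + w)
  box <- image[rows, cols]
  above <- image[(y0 - h + 1):y0, cols]
  below <- image[(y0 + h + 1):(y0 + 2 * h), cols]
  bg <- median(c(above, below))
  raw <- sum(box)
  corrected <- raw - bg * length(box)
  flagged <- corrected < 0
  if (flagged) {
    warn(sprintf(
      "background-corrected band integral is negative (%.4g); floored to 0.",
      corrected
    ))
  }
  tibble(
    gel_id = lane$gel_id %||% NA_character_,
    lane_id = lane$lane_id %||% NA_character_,
    pair = lane$pair %||% NA_character_,
    role = lane$role %||% NA_character_,
    raw_integral = raw,
    background_per_pixel = bg,
    integrated_intensity = max(corrected, 0),
    flagged_negative = flagged
  )
}

#' Measure every annotated lane of a gel image
#'
#' @param image Numeric gel matrix.
#' @param lanes Lane annotation tibble, one row per band box (as produced by
#'   [simulate_gel_image()] or read from an annotation CSV with columns
#'   `gel_id`, `lane_id`, `pair`, `role`, `x0`, `y0`, `w`, `h`).
#' @return One tibble row per lane, see [integrate_band()].
#' @export
measure_gel <- function(image, lanes) {
  if (nrow(lanes) == 0) abort("no lanes to measure.")
  purrr::map(seq_len(nrow(lanes)),
             function(i) integrate_band(image, lanes[i, ])) |>
    dplyr::bind_rows()
}

#' Bound fraction from paired band intensities
#'
#' The gel-shift estimate of the membrane-bound percentage,
#' `T = (1 - B/U) * 100`, where `B` is the tile-band intensity in the lane
#' run with liposomes and `U` the intensity in the matching lane without.
#' Values are vectorized. `B > U` yields a negative percentage, reported
#' as-is with a warning: replicate loading noise can legitimately produce
#' it and hiding it would bias replicate means.
#'
#' @param B,U Background-corrected band integrals (sample and control).
#' @return Bound percentage(s) in `(-Inf, 100]`.
#' @export
#' @examples
#' bound_fraction(40, 100) # 60% bound
bound_fraction <- function(B, U) {
  if (any(!is.finite(B)) || any(!is.finite(U))) abort("B and U must be finite.")
  if (any(B < 0)) abort("B must be >= 0.")
  if (any(U <= 0)) abort("U must be > 0.")
  t_pct <- (1 - B / U) * 100
  if (any(t_pct < 0)) {
    warn("B > U for at least one pair: negative bound percentage reported.")
  }
  t_pct
}

#' Bound fractions for all sample/control pairs of one or more gels
#'
#' Pairs lanes by `gel_id` and `pair`, always within a gel: comparisons
#' across gels are refused because exposure and loading are only comparable
#' within a single gel.
#'
#' @param measurements Band measurement tibble from [measure_gel()] (rows
#'   from several gels may be concatenated); must contain `gel_id`, `pair`,
#'   `role` (`"sample"`/`"control"`) and `integrated_intensity`.
#' @return Tibble with one row per (`gel_id`, `pair`): `B`, `U` and the
#'   bound percentage `T_pct`.
#' @export
bound_fraction_table <- function(measurements) {
  req <- c("gel_id", "pair", "role", "integrated_intensity")
  if (!all(req %in% names(measurements))) {
    abort(paste("measurements must contain:", paste(req, collapse = ", ")))
  }
  wide <- measurements |>
    dplyr::select(dplyr::all_of(req)) |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = "integrated_intensity")
  if (!all(c("sample", "control") %in% names(wide)) ||
      any(is.na(wide$sample)) || any(is.na(wide$control))) {
    abort("every pair needs one sample and one control lane on the same gel.")
  }
  wide |>
    dplyr::mutate(B = .data$sample, U = .data$control,
                  T_pct = bound_fraction(.data$B, .data$U)) |>
    dplyr::select(dplyr::all_of(c("gel_id", "pair", "B", "U", "T_pct")))
}

#' Summarize bound fractions across replicate gels
#'
#' Bound percentages are computed per gel and then averaged across replicate
#' gels (mean +/- SD), mirroring how gel-shift replicates are reported;
#' cross-gel ratios are never formed.
#'
#' @param bound_tbl Output of [bound_fraction_table()] covering >= 1 gel.
#' @return Tibble with one row per `pair`: `mean_T_pct`, `sd_T_pct`,
#'   `n_gels`.
#' @export
summarize_bound_fraction <- function(bound_tbl) {
  if (nrow(bound_tbl) == 0) abort("empty bound-fraction table.")
  bound_tbl |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      mean_T_pct = mean(.data$T_pct),
      sd_T_pct = if (dplyr::n() > 1) sd(.data$T_pct) else 0,
      n_gels = dplyr::n_distinct(.data$gel_id),
      .groups = "drop"
    )
}

#' Stain-normalized band intensity
#'
#' Ratio of a band's fluorophore-channel integral (e.g. Cy5 on the tile) to
#' the same lane's total-DNA stain integral, removing loading differences.
#'
#' @param fluor,stain Background-corrected band integrals for the reporter
#'   fluorophore and the DNA stain channel of the same lane. Either numbers
#'   or one-row tibbles from [integrate_band()].
#' @return Dimensionless ratio(s).
#' @export
normalized_band_intensity <- function(fluor, stain) {
  fv <- if (is.data.frame(fluor)) fluor$integrated_intensity else fluor
  sv <- if (is.data.frame(stain)) stain$integrated_intensity else stain
  if (any(sv <= 0)) abort("stain band integral must be > 0.")
  fv / sv
}

#' Estimate anchor occupancy by inverse regression
#'
#' Fluorophore signal per attachment handle is assumed linear at low handle
#' counts. An ordinary least-squares line is fitted to the low-count
#' measurements (default handle counts 0--4), and the observed signal of the
#' nominal high-count design is mapped back through the line to estimate how
#' many handles were actually occupied. The 95% confidence interval uses the
#' classical calibration (inverse prediction) standard error with a
#' t quantile on the fit's residual degrees of freedom:
#' `SE(n_hat) = s/|b| * sqrt(1/m_obs + 1/m_fit + (n_hat - n_bar)^2 / S_nn)`.
#'
#' @param data Data frame with columns `handle_count` and `intensity`
#'   (stain-normalized band intensities; replicates allowed).
#' @param nominal_n Designed handle count of the sample whose occupancy is
#'   estimated (its measurements must be present in `data`).
#' @param max_fit_n Largest handle count included in the linear fit
#'   (default 4).
#' @return An object of class `occupancy_fit` with the fitted slope and
#'   intercept, `estimated_cholesterols` (may exceed `nominal_n` at the CI
#'   edge), `estimated_occupancy_fraction`, and `ci95` on the count scale.
#'   [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' d <- data.frame(handle_count = c(0, 1, 2, 4, 16),
#'                 intensity = c(0, 3, 6, 12, 33))
#' occupancy_regression(d, nominal_n = 16)
occupancy_regression <- function(data, nominal_n, max_fit_n = 4) {
  if (!all(c("handle_count", "intensity") %in% names(data))) {
    abort("`data` needs columns `handle_count` and `intensity`.")
  }
  if (!is_count(nominal_n) || nominal_n <= max_fit_n) {
    abort("`nominal_n` must be an integer above `max_fit_n`.")
  }
  fit_pts <- data[data$handle_count <= max_fit_n, , drop = FALSE]
  obs_pts <- data[data$handle_count == nominal_n, , drop = FALSE]
  if (length(unique(fit_pts$handle_count)) < 3) {
    abort("need measurements at >= 3 distinct low handle counts.")
  }
  if (nrow(obs_pts) == 0) {
    abort(sprintf("no measurement at nominal handle count %d.", nominal_n))
  }
  fit <- lm(intensity ~ handle_count, data = fit_pts)
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  if (!is.finite(b) || b <= 0) {
    abort("fitted slope is not positive; occupancy is undefined.")
  }
  y_star <- mean(obs_pts$intensity)
  n_hat <- (y_star - a) / b

  m_fit <- nrow(fit_pts)
  m_obs <- nrow(obs_pts)
  s <- suppressWarnings(summary(fit)$sigma)
  n_bar <- mean(fit_pts$handle_count)
  s_nn <- sum((fit_pts$handle_count - n_bar)^2)
  se <- (s / abs(b)) * sqrt(1 / m_obs + 1 / m_fit + (n_hat - n_bar)^2 / s_nn)
  tq <- qt(0.975, df = m_fit - 2)
  ci <- n_hat + c(-1, 1) * tq * se

  structure(
    list(
      slope_per_handle = b, intercept = a,
      estimated_cholesterols = n_hat,
      estimated_occupancy_fraction = n_hat / nominal_n,
      ci95 = ci, se = se, nominal_n = nominal_n,
      n_fit_points = m_fit, n_obs_points = m_obs,
      residual_sd = s, fit = fit
    ),
    class = "occupancy_fit"
  )
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("<occupancy_fit>\n")
  cat(sprintf(
    "  slope %.4g per handle; nominal n = %d -> %.2f occupied (%.1f%%)\n",
    x$slope_per_handle, x$nominal_n, x$estimated_cholesterols,
    100 * x$estimated_occupancy_fraction
  ))
  cat(sprintf("  95%% CI on the count: [%.2f, %.2f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @rdname occupancy_regression
#' @param x An `occupancy_fit` object.
#' @param ... Unused.
#' @export
tidy.occupancy_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope_per_handle", "estimated_cholesterols"),
    estimate = c(x$intercept, x$slope_per_handle, x$estimated_cholesterols),
    conf.low = c(NA, NA, x$ci95[1]),
    conf.high = c(NA, NA, x$ci95[2])
  )
}

#' @rdname occupancy_regression
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble(
    nominal_n = x$nominal_n,
    estimated_cholesterols = x$estimated_cholesterols,
    estimated_occupancy_fraction = x$estimated_occupancy_fraction,
    ci95_low = x$ci95[1], ci95_high = x$ci95[2],
    residual_sd = x$residual_sd,
    n_fit_points = x$n_fit_points
  )
}
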