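#' Render a synthetic gel-shift image with known ground truth
#'
#' Draws one gel image from a [gel_scenario()]. Rows are the migration axis
#' (row 1 = top of the gel, where the wells sit); each lane pair consists of
#' a sample lane (tiles incubated with liposomes) followed by a control lane
#' (tiles only). The control lane carries the full Gaussian tile band; the
#' sample lane's band is depleted by the true bound fraction and the bound
#' signal is deposited in the well region instead, reflecting that tiles
#' migrate through the gel matrix while liposome-bound material stays in the
#' well. Each lane receives an independent lognormal loading factor
#' (mean 1, CV `loading_cv`) on its signal, then flat background and
#' additive Gaussian noise.
#'
#' @param scenario A [gel_scenario()].
#' @return A list with components:
#'   \describe{
#'     \item{image}{numeric matrix of intensities (not quantized; use
#'       [write_gel_tiff()] to store on a bit grid)}
#'     \item{lanes}{tibble of lane/band boxes (columns `gel_id`, `lane_id`,
#'       `pair`, `role`, `x0`, `y0`, `w`, `h`; 0-based, half-open) suitable
#'       for [measure_gel()]}
#'     \item{truth}{`bound_fraction_true`, per-lane loading factors and
#'       expected band integrals before noise}
#'   }
#' @details The band annotation box spans the band center +/- 3 SD; since
#'   sample and control boxes truncate the same Gaussian profile, the
#'   truncation cancels in the ratio B/U and the noiseless bound fraction is
#'   recovered exactly. The layout is validated so that the band box and its
#'   two flanking background boxes fit inside the image without touching the
#'   well signal; violations raise an error.
#' @export
simulate_gel_image <- function(scenario) {
  stopifnot(inherits(scenario, "gel_scenario"))
  sc <- scenario
  set.seed(sc$seed)

  h <- sc$image_height
  margin <- 10L
  pair_w <- 2L * sc$lane_width + sc$lane_gap
  w <- 2L * margin + sc$n_lane_pairs * pair_w +
    (sc$n_lane_pairs - 1L) * sc$lane_gap

  band_y0 <- floor(sc$band_center - 3 * sc$band_sigma)
  band_h <- ceiling(sc$band_center + 3 * sc$band_sigma) - band_y0 + 1L
  if (band_y0 - 2 * band_h < 0 || band_y0 + 2 * band_h > h) {
    abort("band box (with flanking background boxes) exceeds image bounds.")
  }
  if (sc$well_center + 3 * sc$well_sigma >= band_y0 - band_h) {
    abort("well signal would bleed into the band's upper flanking box.")
  }

  y <- seq_len(h)
  band_profile <- exp(-(y - sc$band_center)^2 / (2 * sc$band_sigma^2))
  well_profile <- exp(-(y - sc$well_center)^2 / (2 * sc$well_sigma^2))
  f <- sc$bound_fraction_true

  img <- matrix(sc$background_mean, h, w)
  lanes <- vector("list", 2L * sc$n_lane_pairs)
  loading <- numeric(2L * sc$n_lane_pairs)
  expected <- numeric(2L * sc$n_lane_pairs)

  sdlog <- sqrt(log(1 + sc$loading_cv^2))
  for (p in seq_len(sc$n_lane_pairs)) {
    for (j in 1:2) {
      role <- if (j == 1) "sample" else "control"
      idx <- 2L * (p - 1L) + j
      x0 <- margin + (p - 1L) * (pair_w + sc$lane_gap) +
        (j - 1L) * (sc$lane_width + sc$lane_gap)
      cols <- (x0 + 1L):(x0 + sc$lane_width)
      L <- if (sc$loading_cv > 0) {
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        1
      }
      amp <- if (role == "sample") (1 - f) * sc$unbound_band_amplitude else
        sc$unbound_band_amplitude
      profile <- amp * band_profile
      if (role == "sample" && f > 0) {
        profile <- profile + f * sc$well_retained_amplitude * well_profile
      }
      img[, cols] <- img[, cols] + L * profile
      loading[idx] <- L
      expected[idx] <- L * amp *
        sum(band_profile[(band_y0 + 1L):(band_y0 + band_h)]) * sc$lane_width
      lanes[[idx]] <- tibble(
        gel_id = sc$gel_id,
        lane_id = sprintf("%s_p%d_%s", sc$gel_id, p, role),
        pair = sprintf("pair_%d", p), role = role,
        x0 = x0, y0 = band_y0, w = sc$lane_width, h = band_h
      )
    }
  }
  if (sc$noise_sd > 0) {
    img <- img + rnorm(length(img), sd = sc$noise_sd)
  }

  list(
    image = img,
    lanes = dplyr::bind_rows(lanes),
    truth = list(
      bound_fraction_true = f,
      loading = loading,
      expected_band_integral = expected,
      well_region = c(y0 = 0, h = ceiling(sc$well_center + 3 * sc$well_sigma)),
      scenario = sc
    )
  )
}
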