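#' Describe a synthetic two-channel imaging condition
#'
#' An imaging scenario fixes everything needed to render a reproducible set
#' of surface-tethered liposome fields of view: bright compact disks in the
#' liposome (lipid) channel over a flat noisy background, and a DNA channel
#' whose mean intensity on true liposome pixels is `enrichment_rho` times
#' the DNA background mean. `enrichment_rho = 1` means the DNA channel is
#' statistically independent of liposome positions and is the ground truth
#' against which the colocalization ratio C_R is checked; values above 1
#' emulate membrane-bound DNA.
#'
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param n_images Number of fields of view in the condition.
#' @param n_liposomes Number of liposome disks per image (may be 0 for a
#'   pure-background condition). Surface density is not a measured quantity
#'   here; it is a free parameter.
#' @param radius_mean,radius_sd Mean and SD (pixels) of the per-disk radius,
#'   drawn from a normal distribution truncated at zero.
#' @param lipid_fg_mean,lipid_bg_mean Liposome-channel mean intensity on the
#'   disks and on the background (arbitrary units on the stored bit grid).
#' @param dna_bg_mean DNA-channel background mean intensity.
#' @param enrichment_rho True ratio of mean DNA intensity on liposome pixels
#'   to the DNA background mean; must be >= 0.
#' @param noise_model `"gaussian"` (additive, SD `noise_sd`) or `"poisson"`
#'   (per-pixel shot noise with the rendered mean).
#' @param noise_sd Gaussian noise SD; `NULL` defaults to 5% of each
#'   channel's background mean, an EMCCD-like regime.
#' @param blur_sigma SD (pixels) of the Gaussian blur applied to the rendered
#'   liposome disks to mimic diffraction; the DNA enrichment itself is a
#'   sharp step on the true mask. Default 1.
#' @param bit_depth 8 or 16 (default); pixel values are clipped to the
#'   representable range and rounded.
#' @param seed Integer seed; the whole condition is a pure function of the
#'   scenario, including placement.
#' @param condition_id,variable_name,variable_value Metadata describing what
#'   experimental variable the condition represents (e.g. NaCl in mM).
#'
#' @return An object of class `imaging_scenario`.
#' @seealso [simulate_imaging_condition()]
#' @export
#' @examples
#' sc <- imaging_scenario(n_images = 2, enrichment_rho = 2, seed = 7)
#' sc$enrichment_rho
imaging_scenario <- function(image_shape = c(256L, 256L),
                             n_images = 10,
                             n_liposomes = 30,
                             radius_mean = 8,
                             radius_sd = 2,
                             lipid_fg_mean = 12000,
                             lipid_bg_mean = 1000,
                             dna_bg_mean = 1000,
                             enrichment_rho = 1,
                             noise_model = c("gaussian", "poisson"),
                             noise_sd = NULL,
                             blur_sigma = 1,
                             bit_depth = 16,
                             seed = 1,
                             condition_id = "condition_1",
                             variable_name = "none",
                             variable_value = NA) {
  noise_model <- match.arg(noise_model)
  if (length(image_shape) != 2 || !all(vapply(image_shape, is_count, TRUE))) {
    abort("`image_shape` must be two positive integers (height, width).")
  }
  if (!is_count(n_images)) abort("`n_images` must be a positive integer.")
  if (!is_count(n_liposomes, min = 0)) {
    abort("`n_liposomes` must be a non-negative integer.")
  }
  if (!is_number(radius_mean, min = 0) || radius_mean <= 0) {
    abort("`radius_mean` must be positive.")
  }
  if (!is_number(radius_sd, min = 0)) abort("`radius_sd` must be >= 0.")
  if (!is_number(enrichment_rho, min = 0)) {
    abort("`enrichment_rho` must be a number >= 0.")
  }
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  for (nm in c("lipid_fg_mean", "lipid_bg_mean", "dna_bg_mean")) {
    if (!is_number(get(nm), min = 0)) abort(paste0("`", nm, "` must be >= 0."))
  }
  if (!is.null(noise_sd) && !is_number(noise_sd, min = 0)) {
    abort("`noise_sd` must be NULL or a number >= 0.")
  }
  if (!is_number(blur_sigma, min = 0)) abort("`blur_sigma` must be >= 0.")
  if (!is_count(seed, min = 0)) abort("`seed` must be a non-negative integer.")
  structure(
    list(
      image_shape = as.integer(image_shape), n_images = as.integer(n_images),
      n_liposomes = as.integer(n_liposomes),
      radius_mean = radius_mean, radius_sd = radius_sd,
      lipid_fg_mean = lipid_fg_mean, lipid_bg_mean = lipid_bg_mean,
      dna_bg_mean = dna_bg_mean, enrichment_rho = enrichment_rho,
      noise_model = noise_model, noise_sd = noise_sd,
      blur_sigma = blur_sigma, bit_depth = as.integer(bit_depth),
      seed = as.integer(seed), condition_id = condition_id,
      variable_name = variable_name, variable_value = variable_value
    ),
    class = "imaging_scenario"
  )
}

#' Describe a synthetic gel-shift image
#'
#' A gel scenario renders paired electrophoresis lanes for a membrane-binding
#' gel shift assay: for each pair, a control lane (tiles only, no liposomes)
#' carries the full migrating tile band, while the sample lane (tiles +
#' liposomes) carries a tile band depleted by the true bound fraction, with
#' the bound signal retained in the well region near the top of the gel --
#' tiles migrate through the matrix, liposome-bound material stays in the
#' well. Band profiles are Gaussian along the migration axis and flat across
#' the lane width.
#'
#' @param n_lane_pairs Number of sample/control lane pairs.
#' @param bound_fraction_true True membrane-bound fraction in `[0, 1]`;
#'   the expected sample-lane tile-band integral is
#'   `(1 - bound_fraction_true)` times the control-lane integral before
#'   loading noise.
#' @param image_height Gel image height (pixels, migration axis).
#' @param band_center,band_sigma Center and SD (pixels, along migration) of
#'   the tile band.
#' @param lane_width,lane_gap Lane width and inter-lane gap in pixels.
#' @param unbound_band_amplitude Peak intensity of the control-lane tile band.
#' @param well_retained_amplitude Peak intensity scale of the signal retained
#'   in the well of the sample lane (multiplied by the bound fraction).
#' @param well_center,well_sigma Center and SD of the well signal along the
#'   migration axis.
#' @param loading_cv Coefficient of variation of the per-lane loading factor
#'   (lognormal, mean 1); emulates pipetting variation between lanes.
#' @param background_mean Flat background intensity.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param gel_id Identifier recorded in the lane annotation.
#'
#' @return An object of class `gel_scenario`.
#' @seealso [simulate_gel_image()]
#' @export
gel_scenario <- function(n_lane_pairs = 1,
                         bound_fraction_true = 0.5,
                         image_height = 300L,
                         band_center = 210,
                         band_sigma = 8,
                         lane_width = 40L,
                         lane_gap = 12L,
                         unbound_band_amplitude = 8000,
                         well_retained_amplitude = 8000,
                         well_center = 25,
                         well_sigma = 4,
                         loading_cv = 0.02,
                         background_mean = 500,
                         noise_sd = 25,
                         seed = 1,
                         gel_id = "gel_1") {
  if (!is_count(n_lane_pairs)) abort("`n_lane_pairs` must be >= 1.")
  if (!is_number(bound_fraction_true) || bound_fraction_true < 0 ||
      bound_fraction_true > 1) {
    abort("`bound_fraction_true` must lie in [0, 1].")
  }
  for (nm in c("band_sigma", "well_sigma")) {
    if (!is_number(get(nm), min = 0) || get(nm) <= 0) {
      abort(paste0("`", nm, "` must be positive."))
    }
  }
  for (nm in c("unbound_band_amplitude", "well_retained_amplitude",
               "background_mean", "noise_sd", "loading_cv")) {
    if (!is_number(get(nm), min = 0)) abort(paste0("`", nm, "` must be >= 0."))
  }
  if (!is_count(image_height, min = 8)) abort("`image_height` too small.")
  if (!is_count(lane_width)) abort("`lane_width` must be >= 1.")
  if (!is_count(lane_gap, min = 0)) abort("`lane_gap` must be >= 0.")
  if (!is_count(seed, min = 0)) abort("`seed` must be a non-negative integer.")
  structure(
    list(
      n_lane_pairs = as.integer(n_lane_pairs),
      bound_fraction_true = bound_fraction_true,
      image_height = as.integer(image_height),
      band_center = band_center, band_sigma = band_sigma,
      lane_width = as.integer(lane_width), lane_gap = as.integer(lane_gap),
      unbound_band_amplitude = unbound_band_amplitude,
      well_retained_amplitude = well_retained_amplitude,
      well_center = well_center, well_sigma = well_sigma,
      loading_cv = loading_cv, background_mean = background_mean,
      noise_sd = noise_sd, seed = as.integer(seed), gel_id = gel_id
    ),
    class = "gel_scenario"
  )
}

#' @export
print.imaging_scenario <- function(x, ...) {
  cat("<imaging_scenario>", x$condition_id, "\n")
  cat(sprintf(
    "  %d images %dx%d, %d liposomes (r ~ %g +/- %g px), rho = %g, %s noise, seed %d\n",
    x$n_images, x$image_shape[1], x$image_shape[2], x$n_liposomes,
    x$radius_mean, x$radius_sd, x$enrichment_rho, x$noise_model, x$seed
  ))
  invisible(x)
}

#' @export
print.gel_scenario <- function(x, ...) {
  cat("<gel_scenario>", x$gel_id, "\n")
  cat(sprintf(
    "  %d lane pair(s), true bound fraction %g, band at %g (sigma %g), seed %d\n",
    x$n_lane_pairs, x$bound_fraction_true, x$band_center, x$band_sigma, x$seed
  ))
  invisible(x)
}
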