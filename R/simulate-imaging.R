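#' Render a synthetic imaging condition with known ground truth
#'
#' Draws `n_images` two-channel fields of view from an [imaging_scenario()].
#' Liposomes are non-overlapping hard disks (rejection-sampled placement,
#' fully inside the image) rendered in the lipid channel at
#' `lipid_fg_mean` over a `lipid_bg_mean` background and softened by a
#' Gaussian blur to mimic diffraction. The DNA channel is a sharp step on
#' the true disk mask: mean `dna_bg_mean` outside and
#' `enrichment_rho * dna_bg_mean` inside, so the generator's enrichment is
#' defined on mean intensity exactly as the colocalization ratio is. Noise
#' is then added per the scenario's noise model and pixels are clipped and
#' rounded onto the bit-depth grid.
#'
#' @param scenario An [imaging_scenario()].
#' @return A list with components:
#'   \describe{
#'     \item{condition}{a [condition_set()] of rendered images}
#'     \item{truth}{per-image true logical masks, disk centers/radii,
#'       the scenario's `enrichment_rho`, and the clipping fraction}
#'   }
#' @details Placement uses rejection sampling with a one-pixel gap between
#'   disk rims; if 10,000 candidate draws are exhausted before all disks are
#'   placed the packing is declared infeasible and an error is raised.
#'   The same scenario (including seed) always yields bit-identical output.
#' @export
#' @examples
#' sim <- simulate_imaging_condition(
#'   imaging_scenario(image_shape = c(64, 64), n_images = 1,
#'                    n_liposomes = 4, radius_mean = 5, seed = 2)
#' )
#' sim$truth$enrichment_rho
simulate_imaging_condition <- function(scenario) {
  stopifnot(inherits(scenario, "imaging_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  h <- sc$image_shape[1]
  w <- sc$image_shape[2]
  lipid_sd <- sc$noise_sd %||% (0.05 * sc$lipid_bg_mean)
  dna_sd <- sc$noise_sd %||% (0.05 * sc$dna_bg_mean)

  images <- vector("list", sc$n_images)
  masks <- vector("list", sc$n_images)
  disks <- vector("list", sc$n_images)
  clipped <- 0
  total_px <- 0

  for (i in seq_len(sc$n_images)) {
    placement <- place_disks(h, w, sc$n_liposomes, sc$radius_mean, sc$radius_sd)
    mask <- disks_to_mask(h, w, placement)

    lipid_mean <- sc$lipid_bg_mean +
      (sc$lipid_fg_mean - sc$lipid_bg_mean) *
        gaussian_blur(mask + 0, sc$blur_sigma)
    dna_mean <- sc$dna_bg_mean * (1 + (sc$enrichment_rho - 1) * (mask + 0))

    if (sc$noise_model == "gaussian") {
      lipid <- lipid_mean + rnorm(h * w, sd = lipid_sd)
      dna <- dna_mean + rnorm(h * w, sd = dna_sd)
    } else {
      lipid <- matrix(rpois(h * w, lambda = lipid_mean), h, w)
      dna <- matrix(rpois(h * w, lambda = dna_mean), h, w)
    }

    ql <- quantize_to_bit_depth(lipid, sc$bit_depth)
    qd <- quantize_to_bit_depth(dna, sc$bit_depth)
    clipped <- clipped + (ql$clip_fraction + qd$clip_fraction) * h * w
    total_px <- total_px + 2 * h * w

    images[[i]] <- two_channel_image(
      lipid = matrix(ql$pixels, h, w), dna = matrix(qd$pixels, h, w),
      bit_depth = sc$bit_depth,
      image_id = sprintf("%s_img%02d", sc$condition_id, i),
      condition_id = sc$condition_id
    )
    masks[[i]] <- mask
    disks[[i]] <- placement
  }

  list(
    condition = condition_set(images, condition_id = sc$condition_id,
                              variable_name = sc$variable_name,
                              variable_value = sc$variable_value),
    truth = list(
      masks = masks, disks = disks,
      enrichment_rho = sc$enrichment_rho,
      clip_fraction = clipped / total_px,
      scenario = sc
    )
  )
}

#' Render a coverage-spanning suite for the area-bias diagnostic
#'
#' Generates one pooled condition whose images differ only in liposome
#' count, spanning a wide range of coverage fractions at a fixed DNA
#' enrichment. Analyzed as a single condition (one shared threshold, as
#' thresholds are defined per condition), it is the standard input for
#' [area_bias_check()]: the ratio C_R should show no coverage trend while
#' whole-image Pearson correlation does.
#'
#' @param counts Integer vector of liposome counts, one image per entry.
#' @param enrichment_rho True DNA enrichment ratio shared by all images.
#' @param seed Master seed; each image derives its own stream from it.
#' @param image_shape,radius_mean,radius_sd Geometry shared by all images;
#'   the default small radius keeps even the densest image well below the
#'   coverage regime where a pooled mean + 2 SD threshold degenerates.
#' @param ... Further arguments passed to [imaging_scenario()].
#' @return As [simulate_imaging_condition()]: a `condition` pooling all
#'   images and a `truth` list (per-image masks, counts, enrichment).
#' @export
simulate_bias_suite <- function(counts = seq(5L, 80L, by = 5L),
                                enrichment_rho = 2,
                                seed = 1,
                                image_shape = c(256L, 256L),
                                radius_mean = 4,
                                radius_sd = 1,
                                ...) {
  if (length(counts) < 2) abort("need at least two liposome counts.")
  sims <- purrr::map(seq_along(counts), function(i) {
    simulate_imaging_condition(imaging_scenario(
      image_shape = image_shape, n_images = 1,
      n_liposomes = counts[i],
      radius_mean = radius_mean, radius_sd = radius_sd,
      enrichment_rho = enrichment_rho,
      seed = derive_seed(seed, paste0("bias_count_", i)),
      condition_id = "bias_suite",
      variable_name = "n_liposomes", variable_value = counts[i],
      ...
    ))
  })
  images <- purrr::map(sims, function(s) {
    img <- s$condition$images[[1]]
    img$image_id <- sprintf("bias_suite_n%02d", s$truth$scenario$n_liposomes)
    img
  })
  list(
    condition = condition_set(images, condition_id = "bias_suite",
                              variable_name = "n_liposomes",
                              variable_value = NA),
    truth = list(
      masks = purrr::map(sims, function(s) s$truth$masks[[1]]),
      counts = as.integer(counts),
      enrichment_rho = enrichment_rho
    )
  )
}

# Rejection-sample non-overlapping disk centers and radii, disks fully
# inside the image and rims separated by >= 1 px. Errors after 10,000
# failed candidate draws (infeasible packing).
place_disks <- function(h, w, n, radius_mean, radius_sd, max_attempts = 10000L) {
  if (n == 0) {
    return(tibble(cx = numeric(), cy = numeric(), r = numeric()))
  }
  cx <- numeric(n)
  cy <- numeric(n)
  r <- numeric(n)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "infeasible packing: placed %d of %d liposomes in %d attempts.",
        placed, n, max_attempts
      ))
    }
    ri <- 0
    while (ri <= 0) ri <- rnorm(1, radius_mean, radius_sd)
    if (2 * ri + 2 > min(h, w)) next
    x <- runif(1, ri + 1, w - ri)
    y <- runif(1, ri + 1, h - ri)
    if (placed > 0L) {
      d2 <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
      if (any(d2 < (r[seq_len(placed)] + ri + 1)^2)) next
    }
    placed <- placed + 1L
    cx[placed] <- x
    cy[placed] <- y
    r[placed] <- ri
  }
  tibble(cx = cx, cy = cy, r = r)
}

# Pixel-center-in-disk rasterization of the placed disks.
disks_to_mask <- function(h, w, disks) {
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(disks))) {
    cx <- disks$cx[k]
    cy <- disks$cy[k]
    r <- disks$r[k]
    rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    local <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
    mask[rows, cols] <- mask[rows, cols] | local
  }
  mask
}
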