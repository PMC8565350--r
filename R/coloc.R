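#' Colocalization ratio of one image
#'
#' The ratiometric colocalization score
#' `C_R = F_dna_lipid / F_dna_background`: the arithmetic mean of raw
#' DNA-channel intensities over liposome-mask pixels divided by the mean
#' over the remaining (background) pixels. A value of 1 means the DNA is
#' distributed independently of the liposomes; values above 1 indicate
#' membrane enrichment. No background subtraction or flat-field correction
#' is applied -- the ratio between liposome-bound and background dye is the
#' statistic itself, which makes it invariant to multiplicative exposure
#' changes (but not to additive offsets).
#'
#' Manders overlap coefficients are reported alongside as auxiliary
#' diagnostics: `manders_m1` is the fraction of total DNA-channel intensity
#' falling on mask pixels, `manders_m2` the same for the lipid channel.
#'
#' @param img A [two_channel_image()].
#' @param mask A `liposome_mask` from [binarize()] for the same image shape
#'   and condition.
#' @return One-row tibble: `image_id`, `condition_id`, `C_R`,
#'   `F_dna_lipid`, `F_dna_background`, `coverage`, `pearson_r`,
#'   `manders_m1`, `manders_m2`.
#' @export
#' @examples
#' lip <- matrix(0, 4, 4); lip[1:2, 1:2] <- 100
#' dna <- matrix(100, 4, 4); dna[1:2, 1:2] <- 200
#' img <- two_channel_image(lip, dna)
#' msk <- binarize(img, condition_threshold(condition_set(list(img))))
#' colocalization_ratio(img, msk)$C_R  # 2 (mask = the bright quadrant)
colocalization_ratio <- function(img, mask) {
  if (!inherits(img, "two_channel_image")) {
    abort("`img` must be a two_channel_image.")
  }
  if (!inherits(mask, "liposome_mask")) {
    abort("`mask` must be a liposome_mask.")
  }
  if (!identical(dim(mask$mask), dim(img$dna))) {
    abort("mask shape does not match the image.")
  }
  if (!identical(mask$condition_id, img$condition_id)) {
    abort("mask and image come from different conditions.")
  }
  n_fg <- sum(mask$mask)
  n_bg <- length(mask$mask) - n_fg
  if (n_fg == 0) abort("empty liposome region: C_R is undefined.")
  if (n_bg == 0) abort("empty background region: C_R is undefined.")
  f_lip <- mean(img$dna[mask$mask])
  f_bg <- mean(img$dna[!mask$mask])
  if (f_bg == 0) abort("background DNA mean is zero: C_R is undefined.")
  tot_dna <- sum(img$dna)
  tot_lip <- sum(img$lipid)
  tibble(
    image_id = img$image_id,
    condition_id = img$condition_id,
    C_R = f_lip / f_bg,
    F_dna_lipid = f_lip,
    F_dna_background = f_bg,
    coverage = mask$coverage,
    pearson_r = if (sd(img$lipid) > 0 && sd(img$dna) > 0) {
      pearson_coloc(img)
    } else {
      NA_real_
    },
    manders_m1 = if (tot_dna > 0) sum(img$dna[mask$mask]) / tot_dna else NA_real_,
    manders_m2 = if (tot_lip > 0) sum(img$lipid[mask$mask]) / tot_lip else NA_real_
  )
}

#' Pixel-wise Pearson correlation between the two channels
#'
#' Pearson's r over all pixel pairs (lipid_i, dna_i) of one image, the
#' classical whole-image colocalization coefficient that the ratio C_R is
#' compared against; unlike C_R it is sensitive to how much of the image
#' the liposomes cover.
#'
#' @param img A [two_channel_image()].
#' @return Pearson correlation in `[-1, 1]`.
#' @export
pearson_coloc <- function(img) {
  if (!inherits(img, "two_channel_image")) {
    abort("`img` must be a two_channel_image.")
  }
  if (sd(img$lipid) == 0 || sd(img$dna) == 0) {
    abort("Pearson correlation undefined: a channel has zero variance.")
  }
  cor(as.vector(img$lipid), as.vector(img$dna))
}

#' Full colocalization analysis of a condition
#'
#' Computes the condition threshold, masks every image, and returns the
#' per-image colocalization table.
#'
#' @param cond A [condition_set()].
#' @param min_size Optional minimum mask object size, see [binarize()].
#' @return Tibble with one row per image (see [colocalization_ratio()]),
#'   plus the condition's `variable_name`/`variable_value` columns.
#' @export
coloc_condition <- function(cond, min_size = 0) {
  seg <- segment_condition(cond, min_size = min_size)
  res <- purrr::map2(cond$images, seg$masks, colocalization_ratio) |>
    dplyr::bind_rows()
  res$variable_name <- cond$variable_name
  res$variable_value <- cond$variable_value
  res
}

#' Condition-level summary of per-image colocalization ratios
#'
#' @param results Per-image tibble from [coloc_condition()] (rows from
#'   several conditions may be concatenated).
#' @return Tibble with one row per condition: `mean_C_R`, `sd_C_R`
#'   (0 when a condition has a single image) and `n_images`.
#' @export
summarize_coloc <- function(results) {
  if (nrow(results) == 0) abort("no colocalization results to summarize.")
  results |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      mean_C_R = mean(.data$C_R),
      sd_C_R = if (dplyr::n() > 1) sd(.data$C_R) else 0,
      n_images = dplyr::n(),
      .groups = "drop"
    )
}

#' Does a colocalization metric drift with liposome coverage?
#'
#' Regresses each metric (`C_R` and `pearson_r`) on the per-image liposome
#' coverage fraction and reports the slope with its t-based 95% confidence
#' interval and the plain correlation between metric and coverage. A metric
#' fit for comparing conditions with different liposome densities should
#' show a slope CI containing zero; whole-image Pearson correlation is the
#' canonical example of a metric that fails this check.
#'
#' @param results Per-image tibble with columns `coverage`, `C_R` and
#'   `pearson_r`, spanning at least 10 images and a non-degenerate range of
#'   coverages.
#' @return Tibble of class `coloc_bias_report`, one row per metric:
#'   `slope`, `ci_low`, `ci_high`, `correlation`, `n`.
#' @export
area_bias_check <- function(results) {
  if (nrow(results) < 10) {
    abort("need >= 10 images spanning a coverage range for the bias check.")
  }
  if (length(unique(results$coverage)) < 2) {
    abort("degenerate coverage range: all coverages are equal.")
  }
  one_metric <- function(metric) {
    y <- results[[metric]]
    if (length(unique(y)) == 1) {
      # constant metric: slope 0 with a degenerate CI
      return(tibble(metric = metric, slope = 0, ci_low = 0, ci_high = 0,
                    correlation = NA_real_, n = nrow(results)))
    }
    fit <- lm(y ~ coverage, data = results)
    ci <- suppressWarnings(confint(fit, "coverage", level = 0.95))
    tibble(
      metric = metric,
      slope = unname(coef(fit)["coverage"]),
      ci_low = ci[1], ci_high = ci[2],
      correlation = cor(results$coverage, y),
      n = nrow(results)
    )
  }
  out <- dplyr::bind_rows(one_metric("C_R"), one_metric("pearson_r"))
  class(out) <- c("coloc_bias_report", class(out))
  out
}
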