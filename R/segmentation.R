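#' Condition-level liposome-channel threshold
#'
#' The liposome-identification rule: a single intensity threshold per
#' experimental condition, set two standard deviations above the mean pixel
#' intensity of the liposome channel pooled over every image in the
#' condition. The SD is the population SD (denominator N) of the pooled
#' pixel sample, so the threshold is invariant under reordering images or
#' splitting an image into tiles. A zero-variance condition is legal (the
#' threshold equals the mean and, with the strict inequality used by
#' [binarize()], selects nothing).
#'
#' @param cond A [condition_set()].
#' @return A one-row tibble with `condition_id`, `value`
#'   (`mean + 2 * sd`), `mean`, `sd` and `n_pixels`.
#' @export
#' @examples
#' img <- two_channel_image(matrix(c(0, 10), 2, 2), matrix(0, 2, 2))
#' condition_threshold(condition_set(list(img)))  # mean 5, sd 5, value 15
condition_threshold <- function(cond) {
  if (!inherits(cond, "condition_set")) abort("`cond` must be a condition_set.")
  stats <- pooled_pixel_stats(purrr::map(cond$images, "lipid"))
  tibble(
    condition_id = cond$condition_id,
    value = stats$mean + 2 * stats$sd,
    mean = stats$mean,
    sd = stats$sd,
    n_pixels = stats$n
  )
}

#' Binarize the liposome channel of one image
#'
#' A pixel is classified as liposome iff its lipid-channel intensity is
#' strictly above the condition threshold; ties go to background, which
#' makes a uniform image at exactly the threshold value come out empty.
#' No morphological post-processing is applied by default; an optional
#' minimum-object-size filter can drop specks below `min_size` pixels
#' (4-connectivity).
#'
#' @param img A [two_channel_image()].
#' @param thr A threshold row from [condition_threshold()]; its
#'   `condition_id` must match the image's.
#' @param min_size Optional minimum connected-component size in pixels;
#'   `0` (default) disables filtering.
#' @return An object of class `liposome_mask`: list with the logical
#'   `mask`, `coverage` (fraction of true pixels), `image_id` and
#'   `condition_id`.
#' @export
binarize <- function(img, thr, min_size = 0) {
  if (!inherits(img, "two_channel_image")) {
    abort("`img` must be a two_channel_image.")
  }
  if (!is.data.frame(thr) || !all(c("condition_id", "value") %in% names(thr))) {
    abort("`thr` must be a condition_threshold row.")
  }
  if (!identical(img$condition_id, thr$condition_id[[1]])) {
    abort(sprintf(
      "condition mismatch: image is from '%s' but threshold is for '%s'.",
      img$condition_id, thr$condition_id[[1]]
    ))
  }
  mask <- img$lipid > thr$value[[1]]
  if (min_size > 0) {
    mask <- drop_small_components(mask, min_size)
  }
  structure(
    list(mask = mask, coverage = mean(mask),
         image_id = img$image_id, condition_id = img$condition_id),
    class = "liposome_mask"
  )
}

#' @export
print.liposome_mask <- function(x, ...) {
  cat(sprintf("<liposome_mask> %s: %.2f%% coverage (%d of %d px)\n",
              x$image_id, 100 * x$coverage, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Threshold and masks for every image of a condition
#'
#' @param cond A [condition_set()].
#' @param min_size Passed to [binarize()].
#' @return List with the `threshold` row and a list of `masks`.
#' @export
segment_condition <- function(cond, min_size = 0) {
  thr <- condition_threshold(cond)
  masks <- purrr::map(cond$images, binarize, thr = thr, min_size = min_size)
  list(threshold = thr, masks = masks)
}

# 4-connected component labelling via iterative flood fill; adequate for
# the small object counts typical of these fields of view.
drop_small_components <- function(mask, min_size) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((px - 1L) %% h) + 1L
      cc <- ((px - 1L) %/% h) + 1L
      nbr <- c(
        if (r > 1L) px - 1L, if (r < h) px + 1L,
        if (cc > 1L) px - h, if (cc < w) px + h
      )
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- current
      queue <- c(queue, nbr)
    }
  }
  if (current == 0L) {
    return(mask)
  }
  sizes <- tabulate(labels, nbins = current)
  keep <- which(sizes >= min_size)
  labels %in% keep & mask
}
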