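#' Construct a two-channel field of view
#'
#' Bundles one liposome-channel and one DNA-channel intensity matrix with
#' their bit depth and identifiers. Channels must have identical shape and
#' values must be representable at the stated bit depth.
#'
#' @param lipid,dna Numeric matrices of pixel intensities (liposome and DNA
#'   channel respectively).
#' @param bit_depth 8 or 16.
#' @param image_id,condition_id Identifiers.
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(lipid, dna, bit_depth = 16,
                              image_id = "img_1",
                              condition_id = "condition_1") {
  if (!is.matrix(lipid) || !is.matrix(dna)) {
    abort("`lipid` and `dna` must be matrices.")
  }
  if (!identical(dim(lipid), dim(dna))) {
    abort("channel shape mismatch: `lipid` and `dna` differ in dimensions.")
  }
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  hi <- 2^bit_depth - 1
  if (min(lipid) < 0 || max(lipid) > hi || min(dna) < 0 || max(dna) > hi) {
    abort(sprintf("pixel values outside [0, %d] for bit depth %d.", hi, bit_depth))
  }
  structure(
    list(lipid = lipid, dna = dna, bit_depth = as.integer(bit_depth),
         image_id = image_id, condition_id = condition_id),
    class = "two_channel_image"
  )
}

#' Group images into an experimental condition
#'
#' A condition set is the unit over which the liposome-channel threshold is
#' pooled and over which colocalization summaries are reported. All images
#' must share the condition id and bit depth; mixed bit depths are rejected
#' rather than rescaled because the threshold pools raw intensities.
#'
#' @param images List of [two_channel_image()] objects (at least one).
#' @param condition_id Condition identifier; defaults to the first image's.
#' @param variable_name,variable_value The experimental variable this
#'   condition represents (e.g. `"NaCl_mM"`, `100`).
#' @return An object of class `condition_set`.
#' @export
condition_set <- function(images, condition_id = NULL,
                          variable_name = "none", variable_value = NA) {
  if (!is.list(images) || length(images) == 0) {
    abort("a condition needs at least one image.")
  }
  ok <- vapply(images, inherits, TRUE, what = "two_channel_image")
  if (!all(ok)) abort("`images` must all be two_channel_image objects.")
  condition_id <- condition_id %||% images[[1]]$condition_id
  ids <- vapply(images, function(i) i$condition_id, "")
  if (!all(ids == condition_id)) {
    abort("all images must share the condition id.")
  }
  depths <- vapply(images, function(i) i$bit_depth, 1L)
  if (length(unique(depths)) != 1) {
    abort("mixed bit depths within a condition are not allowed.")
  }
  structure(
    list(condition_id = condition_id, variable_name = variable_name,
         variable_value = variable_value, images = images),
    class = "condition_set"
  )
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %s (%s): %dx%d px, %d-bit\n",
              x$image_id, x$condition_id, nrow(x$lipid), ncol(x$lipid),
              x$bit_depth))
  invisible(x)
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("<condition_set> %s: %d image(s), %s = %s\n",
              x$condition_id, length(x$images), x$variable_name,
              format(x$variable_value)))
  invisible(x)
}

#' @export
length.condition_set <- function(x) length(x$images)
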