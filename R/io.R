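#' Write a condition to a multi-page TIFF with manifest row and sidecar
#'
#' One grayscale multi-page TIFF per condition: pages are ordered by image
#' index with the two channels of each image as consecutive pages in the
#' order named by `channel_order`. If ground truth is supplied (from
#' [simulate_imaging_condition()]) a JSON sidecar records the enrichment
#' ratio, disk placements and clipping fraction so the condition remains
#' fully reconstructable.
#'
#' @param cond A [condition_set()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth` component of a simulated condition.
#' @param channel_order Page order of the channels, default `"lipid,dna"`.
#' @return Invisibly, the one-row manifest tibble describing the file
#'   (columns `condition_id`, `variable_name`, `variable_value`, `path`,
#'   `channel_order`, `n_images`, `bit_depth`).
#' @export
write_condition_tiff <- function(cond, dir, truth = NULL,
                                 channel_order = "lipid,dna") {
  stopifnot(inherits(cond, "condition_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- strsplit(channel_order, ",")[[1]]
  if (!setequal(channels, c("lipid", "dna"))) {
    abort("`channel_order` must name the channels 'lipid' and 'dna'.")
  }
  depth <- cond$images[[1]]$bit_depth
  hi <- 2^depth - 1
  pages <- list()
  for (img in cond$images) {
    for (ch in channels) {
      pages[[length(pages) + 1]] <- img[[ch]] / hi
    }
  }
  path <- file.path(dir, paste0(cond$condition_id, ".tif"))
  tiff::writeTIFF(pages, path, bits.per.sample = depth, compression = "none")
  if (!is.null(truth)) {
    sidecar <- list(
      condition_id = cond$condition_id,
      enrichment_rho = truth$enrichment_rho,
      clip_fraction = truth$clip_fraction,
      disks = purrr::map(truth$disks, function(d) as.list(as.data.frame(d)))
    )
    jsonlite::write_json(sidecar,
                         file.path(dir, paste0(cond$condition_id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tibble(
    condition_id = cond$condition_id,
    variable_name = cond$variable_name,
    variable_value = as.character(cond$variable_value),
    path = path,
    channel_order = channel_order,
    n_images = length(cond$images),
    bit_depth = depth
  ))
}

#' Write / read a condition manifest
#'
#' The manifest is a flat CSV with one row per condition file: columns
#' `condition_id`, `variable_name`, `variable_value`, `path`,
#' `channel_order`, `n_images`, `bit_depth`.
#'
#' @param manifest Tibble of manifest rows.
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Load one condition from a manifest row
#'
#' Reads the multi-page TIFF named by the row, assigns channels according
#' to its `channel_order` (so a reversed order swaps lipid and DNA), and
#' validates page count, channel shapes and bit depth.
#'
#' @param manifest Manifest tibble (or a single row of one).
#' @param condition_id Condition to load when `manifest` has several rows.
#' @return A [condition_set()].
#' @export
load_condition <- function(manifest, condition_id = NULL) {
  row <- manifest
  if (nrow(row) > 1) {
    if (is.null(condition_id)) {
      abort("several manifest rows: say which `condition_id` to load.")
    }
    row <- manifest[manifest$condition_id == condition_id, , drop = FALSE]
    if (nrow(row) != 1) {
      abort(sprintf("condition '%s' not found in manifest.", condition_id))
    }
  }
  if (!file.exists(row$path)) {
    abort(sprintf("image file not found: %s", row$path))
  }
  channels <- strsplit(row$channel_order, ",")[[1]]
  if (!setequal(channels, c("lipid", "dna"))) {
    abort(sprintf("unknown channel label(s) in '%s'.", row$channel_order))
  }
  pages <- tryCatch(
    tiff::readTIFF(row$path, all = TRUE, as.is = TRUE),
    error = function(e) {
      abort(sprintf("failed to read TIFF '%s': %s", row$path,
                    conditionMessage(e)))
    }
  )
  if (length(pages) != 2 * row$n_images) {
    abort(sprintf("'%s' has %d pages; expected %d (2 per image).",
                  row$path, length(pages), 2 * row$n_images))
  }
  images <- vector("list", row$n_images)
  for (i in seq_len(row$n_images)) {
    page_pair <- pages[(2 * i - 1):(2 * i)]
    names(page_pair) <- channels
    if (!identical(dim(page_pair$lipid), dim(page_pair$dna))) {
      abort(sprintf("channel shape mismatch in image %d of '%s'.",
                    i, row$path))
    }
    images[[i]] <- two_channel_image(
      lipid = page_pair$lipid + 0, dna = page_pair$dna + 0,
      bit_depth = row$bit_depth,
      image_id = sprintf("%s_img%02d", row$condition_id, i),
      condition_id = row$condition_id
    )
  }
  condition_set(images, condition_id = row$condition_id,
                variable_name = row$variable_name,
                variable_value = row$variable_value)
}

#' Write per-image and condition-summary colocalization tables
#'
#' @param results Per-image tibble from [coloc_condition()]; must be
#'   non-empty.
#' @param detail_path CSV path for the per-image table.
#' @param summary_path CSV path for the condition-level summary
#'   ([summarize_coloc()]).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_coloc_results <- function(results, detail_path, summary_path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("refusing to write an empty results table.")
  }
  write.csv(results, detail_path, row.names = FALSE)
  write.csv(summarize_coloc(results), summary_path, row.names = FALSE)
  invisible(c(detail_path, summary_path))
}

#' Write a gel image to TIFF
#'
#' Quantizes the floating-point gel matrix onto the bit grid and writes a
#' single-page grayscale TIFF.
#'
#' @param image Numeric gel matrix (e.g. from [simulate_gel_image()]).
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16 (default).
#' @return Invisibly, the clipping fraction incurred by quantization.
#' @export
write_gel_tiff <- function(image, path, bit_depth = 16) {
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  q <- quantize_to_bit_depth(image, bit_depth)
  tiff::writeTIFF(q$pixels / (2^bit_depth - 1), path,
                  bits.per.sample = bit_depth, compression = "none")
  invisible(q$clip_fraction)
}

#' Read a grayscale gel image from TIFF or PNG
#'
#' @param path Image path (`.tif`/`.tiff`).
#' @return Numeric matrix of raw integer intensities.
#' @export
read_gel_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("gel image not found: %s", path))
  m <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE),
    error = function(e) {
      abort(sprintf("failed to read gel image '%s': %s", path,
                    conditionMessage(e)))
    }
  )
  m + 0
}
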