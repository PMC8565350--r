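# Small scenarios and independent brute-force oracles used across tests.

tiny_imaging <- function(enrichment_rho = 1, seed = 1, n_images = 2,
                         n_liposomes = 6, condition_id = "tiny", ...) {
  imaging_scenario(
    image_shape = c(96L, 96L), n_images = n_images,
    n_liposomes = n_liposomes,
    radius_mean = 6, radius_sd = 1, enrichment_rho = enrichment_rho,
    seed = seed, condition_id = condition_id, ...
  )
}

# Pooled population mean/SD/threshold by an explicit loop over every pixel,
# independent of the vectorized implementation.
oracle_threshold <- function(cond) {
  vals <- numeric(0)
  for (img in cond$images) {
    for (j in seq_len(ncol(img$lipid))) {
      for (i in seq_len(nrow(img$lipid))) {
        vals <- c(vals, img$lipid[i, j])
      }
    }
  }
  n <- length(vals)
  mu <- sum(vals) / n
  sdev <- sqrt(sum((vals - mu)^2) / n)
  list(mean = mu, sd = sdev, value = mu + 2 * sdev, n = n)
}

# Colocalization ratio by an explicit per-pixel loop.
oracle_cr <- function(img, mask) {
  s_fg <- 0
  n_fg <- 0
  s_bg <- 0
  n_bg <- 0
  for (j in seq_len(ncol(img$dna))) {
    for (i in seq_len(nrow(img$dna))) {
      if (mask[i, j]) {
        s_fg <- s_fg + img$dna[i, j]
        n_fg <- n_fg + 1
      } else {
        s_bg <- s_bg + img$dna[i, j]
        n_bg <- n_bg + 1
      }
    }
  }
  (s_fg / n_fg) / (s_bg / n_bg)
}

# Build a two-channel image directly from matrices with matching metadata.
make_img <- function(lipid, dna, condition_id = "manual", image_id = "m1") {
  two_channel_image(lipid, dna, bit_depth = 16,
                    image_id = image_id, condition_id = condition_id)
}

make_mask <- function(mask, img) {
  structure(
    list(mask = mask, coverage = mean(mask),
         image_id = img$image_id, condition_id = img$condition_id),
    class = "liposome_mask"
  )
}
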