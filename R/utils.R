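# Internal numerical helpers shared by the generators and quantifiers.

# Separable Gaussian convolution with replicate (edge-clamp) boundary.
# Used to soften rendered liposome disks so that thresholding has a real
# edge to cut through; sigma is in pixels.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) {
    return(x)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(m) {
    # convolve each column; pad by replicating first/last rows
    n <- nrow(m)
    mp <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

# Clip to the representable range of the bit depth and report how many
# pixels were clipped; values are then rounded onto the integer grid.
quantize_to_bit_depth <- function(x, bit_depth) {
  hi <- 2^bit_depth - 1
  n_clip <- sum(x < 0 | x > hi)
  x <- pmin(pmax(x, 0), hi)
  list(pixels = round(x), clip_fraction = n_clip / length(x))
}

# Population (denominator N) mean and SD of a pooled pixel sample,
# accumulated from a list of matrices without concatenating them.
pooled_pixel_stats <- function(mats) {
  n <- 0
  s1 <- 0
  s2 <- 0
  for (m in mats) {
    n <- n + length(m)
    s1 <- s1 + sum(as.numeric(m))
    s2 <- s2 + sum(as.numeric(m)^2)
  }
  mu <- s1 / n
  list(mean = mu, sd = sqrt(max(s2 / n - mu^2, 0)), n = n)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min
}

# Deterministic per-stage seed derivation: keeps independent stages on
# independent streams while remaining a pure function of (master, stage).
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 10007 + h * 31) %% 2147483647)
}
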