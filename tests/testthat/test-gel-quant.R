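test_that("a uniform image integrates to zero after background correction", {
  img <- matrix(700, 120, 40)
  m <- integrate_band(img, list(x0 = 5, y0 = 40, w = 20, h = 20))
  expect_equal(m$integrated_intensity, 0)
  expect_equal(m$background_per_pixel, 700)
})

test_that("a rendered band integrates to its closed-form value", {
  sim <- simulate_gel_image(
    gel_scenario(bound_fraction_true = 0, noise_sd = 0, loading_cv = 0)
  )
  meas <- measure_gel(sim$image, sim$lanes)
  # flank boxes see the faint >3-sigma band tails, so agreement is to the
  # tail magnitude, not machine precision
  expect_equal(meas$integrated_intensity,
               sim$truth$expected_band_integral, tolerance = 1e-6)
  # analytic Gaussian integral amp * sigma * sqrt(2*pi) * width, up to
  # the +/- 3 sigma box truncation (99.73%) and pixel discretization
  sc <- sim$truth$scenario
  analytic <- sc$unbound_band_amplitude * sc$band_sigma * sqrt(2 * pi) *
    sc$lane_width
  expect_equal(meas$integrated_intensity[2], analytic, tolerance = 0.01)
})

test_that("negative corrected integrals are floored and flagged", {
  img <- matrix(100, 120, 40)
  img[41:60, 6:25] <- 0 # darker than the flanks
  expect_warning(
    m <- integrate_band(img, list(x0 = 5, y0 = 40, w = 20, h = 20)),
    "floored"
  )
  expect_equal(m$integrated_intensity, 0)
  expect_true(m$flagged_negative)
})

test_that("boxes whose flanks leave the image are rejected", {
  img <- matrix(0, 60, 40)
  expect_error(integrate_band(img, list(x0 = 5, y0 = 5, w = 20, h = 20)),
               "flanking")
  expect_error(integrate_band(img, list(x0 = 30, y0 = 20, w = 20, h = 10)),
               "outside the image")
})

test_that("bound_fraction implements T = (1 - B/U) x 100", {
  expect_equal(bound_fraction(100, 100), 0)
  expect_equal(bound_fraction(0, 100), 100)
  expect_equal(bound_fraction(40, 100), 60)
  expect_error(bound_fraction(10, 0), "U must be > 0")
  expect_error(bound_fraction(-1, 10), "B must be >= 0")
  expect_warning(t_neg <- bound_fraction(120, 100), "negative")
  expect_equal(t_neg, -20)
  # invariance under global exposure scaling
  expect_equal(bound_fraction(3 * 40, 3 * 100), bound_fraction(40, 100))
})

test_that("a noiseless synthetic gel recovers the true bound fraction exactly", {
  sim <- simulate_gel_image(
    gel_scenario(bound_fraction_true = 0.6, noise_sd = 0, loading_cv = 0)
  )
  bt <- bound_fraction_table(measure_gel(sim$image, sim$lanes))
  expect_equal(bt$T_pct, 60, tolerance = 1e-9)
})

test_that("default-noise gels recover the truth within 5 percentage points", {
  for (f in c(0, 0.5)) {
    # at f = 0 loading noise can push B slightly above U; the negative
    # percentage is reported (with a warning) rather than censored
    t_reps <- vapply(1:2, function(g) {
      sim <- simulate_gel_image(
        gel_scenario(bound_fraction_true = f, seed = 200 + g,
                     gel_id = sprintf("g%d", g))
      )
      suppressWarnings(
        bound_fraction_table(measure_gel(sim$image, sim$lanes))$T_pct
      )
    }, 0)
    expect_lt(abs(mean(t_reps) - 100 * f), 5)
  }
})

test_that("bound fractions are only formed within a gel", {
  sim <- simulate_gel_image(gel_scenario(n_lane_pairs = 2, seed = 2))
  meas <- measure_gel(sim$image, sim$lanes)
  bt <- bound_fraction_table(meas)
  expect_equal(nrow(bt), 2)
  # dropping a control lane breaks the pairing and must error
  expect_error(bound_fraction_table(meas[meas$role == "sample", ]),
               "control lane")
  s <- summarize_bound_fraction(bt)
  expect_equal(s$n_gels, c(1, 1))
})

test_that("stain normalization is a plain background-corrected ratio", {
  expect_equal(normalized_band_intensity(50, 50), 1)
  expect_equal(normalized_band_intensity(0, 50), 0)
  expect_equal(normalized_band_intensity(100, 50), 2)
  expect_error(normalized_band_intensity(10, 0), "stain")
})

test_that("occupancy inverse regression solves the noiseless fixture analytically", {
  k <- 3
  d <- data.frame(handle_count = c(0, 1, 2, 4, 16),
                  intensity = c(0, k, 2 * k, 4 * k, 11 * k))
  fit <- occupancy_regression(d, nominal_n = 16)
  expect_equal(fit$estimated_cholesterols, 11, tolerance = 1e-9)
  expect_equal(fit$estimated_occupancy_fraction, 0.6875, tolerance = 1e-9)
  expect_equal(fit$slope_per_handle, k, tolerance = 1e-9)
  expect_equal(fit$ci95, c(11, 11), tolerance = 1e-6)

  # full occupancy fixture
  d2 <- data.frame(handle_count = c(0, 1, 2, 4, 16),
                   intensity = c(0, k, 2 * k, 4 * k, 16 * k))
  fit2 <- occupancy_regression(d2, nominal_n = 16)
  expect_equal(fit2$estimated_cholesterols, 16, tolerance = 1e-9)
  expect_equal(fit2$estimated_occupancy_fraction, 1, tolerance = 1e-9)
})

test_that("occupancy regression guards its preconditions", {
  d <- data.frame(handle_count = c(0, 2, 4, 16), intensity = c(10, 6, 2, 5))
  expect_error(occupancy_regression(d, nominal_n = 16), "not positive")
  d2 <- data.frame(handle_count = c(0, 4, 16), intensity = c(0, 12, 33))
  expect_error(occupancy_regression(d2, nominal_n = 16), "distinct low")
  d3 <- data.frame(handle_count = c(0, 1, 2, 4), intensity = c(0, 3, 6, 12))
  expect_error(occupancy_regression(d3, nominal_n = 16), "no measurement")
})

test_that("tidy and glance expose the occupancy fit as tibbles", {
  d <- data.frame(handle_count = c(0, 1, 2, 4, 16),
                  intensity = c(0.1, 3.2, 5.9, 12.1, 33))
  fit <- occupancy_regression(d, nominal_n = 16)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true("estimated_cholesterols" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nominal_n, 16)
  expect_true(gl$ci95_low < gl$estimated_cholesterols &&
                gl$estimated_cholesterols < gl$ci95_high)
})
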