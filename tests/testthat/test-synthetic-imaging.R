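test_that("the same scenario renders bit-identical images and masks", {
  sc <- tiny_imaging(enrichment_rho = 2, seed = 42)
  a <- simulate_imaging_condition(sc)
  b <- simulate_imaging_condition(sc)
  expect_identical(a$condition$images, b$condition$images)
  expect_identical(a$truth$masks, b$truth$masks)
  # a different seed must change the rendering
  c <- simulate_imaging_condition(tiny_imaging(enrichment_rho = 2, seed = 43))
  expect_false(identical(a$condition$images[[1]]$lipid,
                         c$condition$images[[1]]$lipid))
})

test_that("DNA-channel means match the scenario inside and outside the true mask", {
  sim <- simulate_imaging_condition(
    imaging_scenario(image_shape = c(128L, 128L), n_images = 3,
                     n_liposomes = 10, radius_mean = 7,
                     dna_bg_mean = 1000, enrichment_rho = 2, seed = 7,
                     condition_id = "rho2")
  )
  inside <- unlist(purrr::map2(
    sim$condition$images, sim$truth$masks,
    function(img, m) img$dna[m]
  ))
  outside <- unlist(purrr::map2(
    sim$condition$images, sim$truth$masks,
    function(img, m) img$dna[!m]
  ))
  # 3-SE Monte-Carlo bands around the generative means
  expect_lt(abs(mean(inside) - 2000), 3 * sd(inside) / sqrt(length(inside)))
  expect_lt(abs(mean(outside) - 1000), 3 * sd(outside) / sqrt(length(outside)))
})

test_that("enrichment_rho = 1 makes the DNA channel independent of liposome positions", {
  sim <- simulate_imaging_condition(
    tiny_imaging(enrichment_rho = 1, seed = 3, n_images = 3)
  )
  inside <- unlist(purrr::map2(sim$condition$images, sim$truth$masks,
                               function(img, m) img$dna[m]))
  outside <- unlist(purrr::map2(sim$condition$images, sim$truth$masks,
                                function(img, m) img$dna[!m]))
  se <- sqrt(sd(inside)^2 / length(inside) + sd(outside)^2 / length(outside))
  expect_lt(abs(mean(inside) - mean(outside)), 4 * se)
})

test_that("the lipid channel renders disks at the foreground mean", {
  sim <- simulate_imaging_condition(
    imaging_scenario(image_shape = c(128L, 128L), n_images = 2,
                     n_liposomes = 8, radius_mean = 8, radius_sd = 0.5,
                     seed = 9, condition_id = "fg")
  )
  # blur spreads the edge, so probe pixels well inside each disk
  vals <- numeric(0)
  for (i in seq_along(sim$condition$images)) {
    d <- sim$truth$disks[[i]]
    img <- sim$condition$images[[i]]$lipid
    for (k in seq_len(nrow(d))) {
      rows <- round(d$cy[k] + (-1:1))
      cols <- round(d$cx[k] + (-1:1))
      vals <- c(vals, img[rows, cols])
    }
  }
  expect_lt(abs(mean(vals) - 12000), 3 * sd(vals) / sqrt(length(vals)) + 1)
})

test_that("poisson noise preserves the channel means", {
  sim <- simulate_imaging_condition(
    tiny_imaging(enrichment_rho = 2, seed = 5, n_images = 3,
                 noise_model = "poisson")
  )
  inside <- unlist(purrr::map2(sim$condition$images, sim$truth$masks,
                               function(img, m) img$dna[m]))
  expect_lt(abs(mean(inside) - 2000), 3 * sd(inside) / sqrt(length(inside)))
})

test_that("infeasible packings and saturation are surfaced", {
  expect_error(
    simulate_imaging_condition(
      imaging_scenario(image_shape = c(40L, 40L), n_images = 1,
                       n_liposomes = 30, radius_mean = 6, radius_sd = 0.1,
                       seed = 1)
    ),
    "infeasible packing"
  )
  # 8-bit scenario with a foreground far above the representable range
  sat <- simulate_imaging_condition(
    imaging_scenario(image_shape = c(64L, 64L), n_images = 1,
                     n_liposomes = 4, radius_mean = 5,
                     lipid_fg_mean = 500, lipid_bg_mean = 50,
                     dna_bg_mean = 50, bit_depth = 8, seed = 2)
  )
  expect_gt(sat$truth$clip_fraction, 0)
  expect_lte(max(sat$condition$images[[1]]$lipid), 255)
})

test_that("a zero-liposome condition renders pure background", {
  sim <- simulate_imaging_condition(
    tiny_imaging(seed = 8, n_liposomes = 0)
  )
  expect_true(all(!sim$truth$masks[[1]]))
  expect_lt(abs(mean(sim$condition$images[[1]]$lipid) - 1000), 5)
})

test_that("scenario validation rejects bad parameters", {
  expect_error(imaging_scenario(enrichment_rho = -1), "enrichment_rho")
  expect_error(imaging_scenario(bit_depth = 12), "bit_depth")
  expect_error(imaging_scenario(image_shape = c(64, 0)), "image_shape")
  expect_error(imaging_scenario(n_images = 0), "n_images")
})
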