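test_that("C_R is the ratio of mean DNA intensities over mask and background", {
  lip <- matrix(0, 10, 10)
  lip[1:3, 1:3] <- 100
  img <- make_img(lip, matrix(800, 10, 10))
  mask <- make_mask(lip > 50, img)
  res <- colocalization_ratio(img, mask)
  expect_equal(res$C_R, 1) # constant DNA channel

  dna <- matrix(100, 10, 10)
  dna[lip > 50] <- 200
  img2 <- make_img(lip, dna)
  res2 <- colocalization_ratio(img2, make_mask(lip > 50, img2))
  expect_equal(res2$C_R, 2)
  expect_equal(res2$F_dna_lipid, 200)
  expect_equal(res2$F_dna_background, 100)
  expect_equal(res2$coverage, 0.09)
})

test_that("empty liposome or background regions raise errors, not NaN", {
  img <- make_img(matrix(10, 5, 5), matrix(10, 5, 5))
  expect_error(colocalization_ratio(img, make_mask(matrix(FALSE, 5, 5), img)),
               "empty liposome region")
  expect_error(colocalization_ratio(img, make_mask(matrix(TRUE, 5, 5), img)),
               "empty background region")
})

test_that("the vectorized C_R equals an explicit per-pixel loop", {
  set.seed(77)
  for (k in 1:10) {
    lip <- matrix(runif(32 * 32, 0, 4000), 32, 32)
    dna <- matrix(runif(32 * 32, 0, 4000), 32, 32)
    img <- make_img(lip, dna, image_id = paste0("r", k))
    mask <- make_mask(lip > 2000, img)
    got <- colocalization_ratio(img, mask)$C_R
    want <- oracle_cr(img, mask$mask)
    expect_lt(abs(got - want) / want, 1e-12)
  }
})

test_that("C_R is invariant to DNA-channel scaling but not to offsets", {
  set.seed(12)
  lip <- matrix(runif(400, 0, 100), 20, 20)
  dna <- matrix(runif(400, 50, 150), 20, 20)
  img <- make_img(lip, dna)
  mask <- make_mask(lip > 50, img)
  base <- colocalization_ratio(img, mask)$C_R
  scaled <- colocalization_ratio(make_img(lip, dna * 3), mask)$C_R
  offset <- colocalization_ratio(make_img(lip, dna + 500), mask)$C_R
  expect_equal(scaled, base, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(offset, base, tolerance = 1e-3)))
})

test_that("Pearson correlation hits its analytic anchors and its null", {
  lip <- matrix(seq_len(64), 8, 8)
  img_same <- make_img(lip, lip)
  expect_equal(pearson_coloc(img_same), 1)
  img_anti <- make_img(lip, -lip + 100)
  expect_equal(pearson_coloc(img_anti), -1)

  set.seed(4)
  img_null <- make_img(matrix(rnorm(256 * 256, 1000, 50), 256, 256),
                       matrix(rnorm(256 * 256, 1000, 50), 256, 256))
  expect_lt(abs(pearson_coloc(img_null)), 0.05)

  expect_error(pearson_coloc(make_img(matrix(5, 4, 4), lip[1:4, 1:4])),
               "zero variance")
})

test_that("condition mean C_R rises strictly with the generator enrichment", {
  means <- vapply(c(1, 1.5, 2, 3), function(rho) {
    sim <- simulate_imaging_condition(
      imaging_scenario(image_shape = c(128L, 128L), n_images = 3,
                       n_liposomes = 10, enrichment_rho = rho, seed = 19,
                       condition_id = sprintf("rho_%g", rho))
    )
    summarize_coloc(coloc_condition(sim$condition))$mean_C_R
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("an independent DNA channel calibrates to C_R ~ 1", {
  sim <- simulate_imaging_condition(
    imaging_scenario(n_images = 4, enrichment_rho = 1, seed = 29,
                     condition_id = "null_cal")
  )
  m <- summarize_coloc(coloc_condition(sim$condition))$mean_C_R
  expect_gte(m, 0.98)
  expect_lte(m, 1.04)
})

test_that("Manders coefficients stay in [0, 1] and track the mask", {
  sim <- simulate_imaging_condition(tiny_imaging(enrichment_rho = 2, seed = 13))
  res <- coloc_condition(sim$condition)
  expect_true(all(res$manders_m1 >= 0 & res$manders_m1 <= 1))
  expect_true(all(res$manders_m2 >= 0 & res$manders_m2 <= 1))
  # the lipid channel is concentrated on the mask, so M2 >> coverage
  expect_true(all(res$manders_m2 > res$coverage))
})

test_that("area_bias_check handles constants and degenerate input", {
  res <- tibble::tibble(
    coverage = seq(0.01, 0.1, length.out = 12),
    C_R = 1.5,
    pearson_r = seq(0.1, 0.4, length.out = 12)
  )
  rep <- area_bias_check(res)
  cr <- rep[rep$metric == "C_R", ]
  expect_equal(cr$slope, 0)
  expect_equal(c(cr$ci_low, cr$ci_high), c(0, 0))
  pe <- rep[rep$metric == "pearson_r", ]
  expect_gt(pe$slope, 0)

  expect_error(area_bias_check(res[1:5, ]), ">= 10 images")
  res$coverage <- 0.05
  expect_error(area_bias_check(res), "degenerate coverage")
})

test_that("summarize_coloc reports mean, SD and image counts per condition", {
  res <- tibble::tibble(
    condition_id = c("a", "a", "a", "b"),
    C_R = c(1, 2, 3, 5)
  )
  s <- summarize_coloc(res)
  expect_equal(s$mean_C_R[s$condition_id == "a"], 2)
  expect_equal(s$sd_C_R[s$condition_id == "a"], 1)
  expect_equal(s$n_images, c(3, 1))
  expect_equal(s$sd_C_R[s$condition_id == "b"], 0)
})
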