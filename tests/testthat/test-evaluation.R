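test_that("normalisation maps to [0,1] and is affine-invariant", {
  o <- matrix(c(-2, 0, 1, 2), 2, 2)
  n <- normalize_output(o)
  expect_equal(range(n), c(0, 1))
  expect_equal(normalize_output(3 * o + 5), n, tolerance = 1e-12)
  expect_equal(normalize_output(matrix(4, 3, 3)), matrix(0.5, 3, 3))
})

test_that("psnr matches closed forms and caps degenerate comparisons", {
  ref <- make_grating(4)$values
  expect_equal(psnr(ref, ref), 120)
  expect_equal(psnr(pmin(ref + 0.5, Inf), ref), 10 * log10(1 / 0.25),
               tolerance = 1e-12)
  expect_equal(psnr(ref + 0.1, ref), 20, tolerance = 1e-12)
  expect_error(psnr(ref[1:10, ], ref), "dimensions")
})

test_that("search grids enumerate constrained pairs", {
  expect_equal(nrow(search_grid(seq(490, 560, 10), seq(490, 560, 10))), 36)
  expect_equal(nrow(search_grid(seq(490, 598, 4), seq(490, 598, 4))), 406)
  expect_equal(nrow(search_grid(seq(515, 535, 1), 562)), 21)
  expect_error(search_grid(600, 500), "empty")
  g <- search_grid(seq(490, 560, 10), seq(490, 560, 10))
  expect_true(all(g$lmax_l >= g$lmax_m))
})

test_that("score of one image equals its psnr; duplication leaves z fixed", {
  scene <- scene_config(4, illuminant = ILLUM, lum_var = FALSE)
  lib1 <- spectral_library(FRUIT_LIB$targets[1], background = MEAN_LEAF)
  images <- build_image_library(lib1, scene, seed = 11)
  mos <- make_mosaic(60, 30, seed = 12)
  z1 <- score_pair(c(525, 562), images, mos)
  # direct recomputation
  sens <- build_sensitivity_mosaic(c(525, 562), mos, GRID)
  o <- integrate_channels(rgc_responses(quantal_catch(images[[1]], sens)),
                          identifier_masks(mos))$red_green
  ref <- scene$pattern$values[5:56, 5:26]
  expect_equal(z1, psnr(normalize_output(o), ref), tolerance = 1e-12)
  # duplicated image library
  expect_equal(score_pair(c(525, 562), c(images, images), mos), z1,
               tolerance = 1e-12)
})

test_that("z is invariant to global spectral scaling", {
  scene <- scene_config(4, illuminant = ILLUM, lum_var = TRUE)
  lib <- spectral_library(FRUIT_LIB$targets[1:4], background = MEAN_LEAF)
  images <- build_image_library(lib, scene, seed = 21)
  mos <- make_mosaic(60, 30, seed = 22)
  z <- score_pair(c(520, 562), images, mos)
  images10 <- lapply(images, function(im) {
    im$values <- im$values * 10
    im
  })
  z10 <- score_pair(c(520, 562), images10, mos)
  expect_lt(abs(z10 - z) / abs(z), 1e-9)
})

test_that("exhaustive search agrees with score_pair and is deterministic", {
  pairs <- search_grid(c(500, 530), c(562))
  scene <- scene_config(4, illuminant = ILLUM, lum_var = TRUE)
  lib <- spectral_library(FRUIT_LIB$targets[1:5], background = MEAN_LEAF)
  s <- exhaustive_search(pairs, lib, scene, seeds = c(31, 32))
  expect_equal(dim(s$z), c(2, 2))
  # independent route through score_pair with identical seeds/streams
  for (si in 1:2) {
    seed <- c(31, 32)[si]
    mos <- make_mosaic(60, 30, seed = derive_seed(seed, "mosaic"))
    images <- build_image_library(lib, scene, seed)
    for (j in 1:2) {
      expect_equal(s$z[j, si],
                   score_pair(unlist(pairs[j, ]), images, mos),
                   tolerance = 1e-10)
    }
  }
  s2 <- exhaustive_search(pairs, lib, scene, seeds = c(31, 32))
  expect_identical(s$z, s2$z)

  # luminance channel never depends on the masks: equals scoring G_ON
  sl <- exhaustive_search(pairs, lib, scene, seeds = 31,
                          channel = "luminance")
  mos <- make_mosaic(60, 30, seed = derive_seed(31, "mosaic"))
  images <- build_image_library(lib, scene, 31)
  expect_equal(sl$z[1, 1],
               score_pair(unlist(pairs[1, ]), images, mos,
                          channel = "luminance"),
               tolerance = 1e-10)
})

test_that("search object methods report the best pair coherently", {
  pairs <- search_grid(seq(500, 540, 20), 562)
  scene <- scene_config(4, illuminant = ILLUM, lum_var = FALSE)
  lib <- spectral_library(FRUIT_LIB$targets[1:4], background = MEAN_LEAF)
  s <- exhaustive_search(pairs, lib, scene, seeds = c(41, 42))
  expect_s3_class(s, "pvc_search")
  cf <- coef(s)
  expect_true(cf["lmax_m"] %in% pairs$lmax_m)
  expect_equal(unname(cf["lmax_l"]), 562)
  sm <- summary(s)
  expect_equal(sm$best$z, max(s$z_mean))
  expect_output(print(s), "performance surface")
  # surface csv round-trips
  tmp <- tempfile(fileext = ".csv")
  write_surface_csv(s, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), nrow(pairs) * 2)
  expect_equal(df$z[df$seed == 41], s$z[, 1])
  # plot method draws without error
  pdf(NULL)
  expect_silent(plot(s))
  dev.off()
})

test_that("replicate statistics recover known distributions", {
  expect_equal(aggregate_optima(c(524, 526))$mean, 525)
  expect_equal(aggregate_optima(c(524, 526))$sd, sqrt(2))
  one <- aggregate_optima(c(525, 525, 525))
  expect_equal(one$sd, 0)
  expect_equal(one$ci_hi - one$ci_lo, 0)
  set.seed(123)
  x <- rnorm(100, mean = 525, sd = 2)
  st <- aggregate_optima(x)
  expect_lt(abs(st$mean - 525), 3 * 2 / sqrt(100))
  expect_lt(abs(st$sd - 2), 0.6)
  expect_equal(st$ci_hi - st$ci_lo, 2 * 1.959964 * st$sd / 10,
               tolerance = 1e-6)
})

test_that("frequency comparison t-test behaves under null and separation", {
  expect_equal(compare_frequencies(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  big <- compare_frequencies(rnorm(20, 0, 0.01), rnorm(20, 50, 0.01))
  expect_lt(big$p.value, 1e-10)
  # empirical type-I error at alpha = 0.01
  set.seed(77)
  rej <- 0
  for (i in 1:10000) {
    a <- rnorm(10)
    b <- rnorm(10)
    if (compare_frequencies(a, b)$p.value < 0.01) rej <- rej + 1
  }
  p <- rej / 10000
  expect_gt(p, 0.01 - 2.8 * sqrt(0.01 * 0.99 / 10000))
  expect_lt(p, 0.01 + 2.8 * sqrt(0.01 * 0.99 / 10000))
})
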