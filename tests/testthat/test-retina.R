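test_that("mosaics are reproducible with sane composition", {
  expect_true(all(make_mosaic(10, 10, ratio = 1, seed = 1)$labels == "L"))
  expect_true(all(make_mosaic(10, 10, ratio = 0, seed = 1)$labels == "M"))
  m <- make_mosaic(60, 30, ratio = 0.5, seed = 4)
  frac <- mean(m$labels == "L")
  # binomial 99.99% interval for n = 1800
  expect_gte(frac, 0.42)
  expect_lte(frac, 0.58)
  expect_identical(make_mosaic(60, 30, seed = 4)$labels, m$labels)
})

test_that("pigment template peaks at lmax and fundamentals behave", {
  tmpl <- pigment_template()
  fine <- seq(400, 700, 0.5)
  for (lmax in c(460, 535, 562)) {
    expect_lt(abs(fine[which.max(tmpl(fine, lmax))] - lmax), 2)
    expect_lte(max(tmpl(fine, lmax)), 1 + 1e-9)
  }
  # absorptance -> 1 at peak as optical density grows, with clear media
  cf <- cone_fundamental(535, media = rep(0, 76), peak_density = 50)
  expect_gt(max(cf$values), 0.999)
  # determinism
  expect_identical(cone_fundamental(535)$values, cone_fundamental(535)$values)
  expect_error(cone_fundamental(630), "validity")
  expect_error(cone_fundamental(430), "validity")
  # ocular media reduce short-wavelength sensitivity
  clear <- cone_fundamental(535, media = ocular_media(GRID, "none"))
  filt <- cone_fundamental(535)
  expect_lt(filt$values[11] / clear$values[11],   # 440 nm
            filt$values[51] / clear$values[51])   # 600 nm
})

test_that("sensitivity mosaics hold exactly two prototype curves", {
  mos <- make_mosaic(20, 20, seed = 2)
  sens <- build_sensitivity_mosaic(c(535, 562), mos, GRID)
  expect_equal(sens$m, cone_fundamental(535, GRID)$values)
  expect_equal(sens$l, cone_fundamental(562, GRID)$values)
  # equal peaks -> all pixels identical
  s2 <- build_sensitivity_mosaic(c(550, 550), mos, GRID)
  expect_identical(s2$m, s2$l)
})

test_that("quantal catch matches the brute-force triple loop", {
  pat <- make_grating(4)
  lum <- synth_luminance_field(60, 30, seed = 5)
  im <- assemble_image(pat, FRUIT$targets[[3]], MEAN_LEAF,
                       illuminant = ILLUM, lum = lum,
                       optics = optics_model())
  mos <- make_mosaic(60, 30, seed = 6)
  sens <- build_sensitivity_mosaic(c(530, 562), mos, GRID)
  q <- quantal_catch(im, sens)
  expect_true(all(q >= 0))
  expect_equal(q, oracle_quantal_catch(im, sens), tolerance = 1e-12)

  # all-ones image and unit sensitivities: catch = number of samples
  im1 <- im
  im1$values[] <- 1
  s1 <- sens
  s1$m[] <- 1
  s1$l[] <- 1
  expect_equal(quantal_catch(im1, s1), matrix(76, 60, 30))

  im0 <- im
  im0$values[] <- 0
  expect_equal(quantal_catch(im0, sens), matrix(0, 60, 30))
})

test_that("receptive-field kernels have the documented structure", {
  # literal (printed-equation) form
  rf0 <- make_receptive_fields(normalization = "none")
  expect_equal(rf0$on[5, 5], 0.45, tolerance = 1e-15)
  expect_identical(rf0$off, -rf0$on)
  expect_equal(rf0$on[6, 5],
               exp(-1 / (2 * 0.25^2)) - 0.55 * exp(-1 / (2 * 1.66^2)),
               tolerance = 1e-12)
  # 90-degree rotational symmetry
  expect_equal(rf0$on, t(rf0$on))
  expect_equal(rf0$on, rf0$on[9:1, 9:1])

  # balanced form: zero integral, positive centre, negative near-surround
  rf <- make_receptive_fields()
  expect_equal(sum(rf$on), 0, tolerance = 1e-12)
  expect_gt(rf$on[5, 5], 0)
  expect_lt(rf$on[6, 5], 0)
  expect_identical(rf$off, -rf$on)

  # integral form: DC = 1 - omega
  rfi <- make_receptive_fields(normalization = "integral")
  expect_equal(sum(rfi$on), 0.45, tolerance = 1e-12)
})

test_that("rgc responses equal nested-loop DoG sums and trim borders", {
  mos <- make_mosaic(60, 30, seed = 8)
  set.seed(99)
  q <- matrix(runif(60 * 30, 0, 5), 60, 30)
  rf <- make_receptive_fields()
  g <- rgc_responses(q, rf)
  expect_equal(dim(g$on), c(52, 22))
  expect_identical(g$off, -g$on)
  for (pt in list(c(1, 1), c(26, 11), c(52, 22))) {
    expect_equal(g$on[pt[1], pt[2]],
                 oracle_dog_at(q, rf$on, pt[1] + 4, pt[2] + 4),
                 tolerance = 1e-12)
  }
  # constant input: response = q * sum(W)
  qc <- matrix(3, 20, 20)
  expect_equal(rgc_responses(qc, rf)$on,
               matrix(3 * sum(rf$on), 12, 12), tolerance = 1e-12)
  expect_error(rgc_responses(matrix(1, 5, 5), rf), "smaller")
})

test_that("identifier masks complement and channels integrate correctly", {
  mos <- make_mosaic(2, 2, seed = 1)
  mos$labels <- matrix(c("M", "L", "L", "M"), 2, 2)
  mk <- identifier_masks(mos)
  expect_equal(mk$l, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(mk$l + mk$m, matrix(1, 2, 2))

  mos2 <- make_mosaic(30, 30, seed = 3)
  q <- matrix(runif(900), 30, 30)
  g <- rgc_responses(q)
  # all-L: O = G_ON; all-M: O = -G_ON; any mosaic: luminance = G_ON
  allL <- mos2
  allL$labels[] <- "L"
  out <- integrate_channels(g, identifier_masks(allL))
  expect_equal(out$red_green, g$on)
  allM <- mos2
  allM$labels[] <- "M"
  out <- integrate_channels(g, identifier_masks(allM))
  expect_equal(out$red_green, -g$on)
  out <- integrate_channels(g, identifier_masks(mos2))
  expect_identical(out$luminance, g$on)
})

test_that("pipeline is homogeneous of degree 1 in the image", {
  pat <- make_grating(4)
  im <- assemble_image(pat, FRUIT$targets[[4]], MEAN_LEAF, illuminant = ILLUM)
  mos <- make_mosaic(60, 30, seed = 10)
  sens <- build_sensitivity_mosaic(c(525, 562), mos, GRID)
  masks <- identifier_masks(mos)
  o1 <- integrate_channels(rgc_responses(quantal_catch(im, sens)),
                           masks)$red_green
  im$values <- im$values * 7
  o7 <- integrate_channels(rgc_responses(quantal_catch(im, sens)),
                           masks)$red_green
  expect_equal(o7, 7 * o1, tolerance = 1e-9)
})

test_that("red step edge drives the red-green signal up on the target side", {
  pat <- make_grating(4)
  pat$values[] <- 0
  pat$values[31:60, ] <- 1
  lam <- GRID$values
  red <- spectrum(0.04 + 0.4 / (1 + exp(-(lam - 600) / 15)), GRID)
  im <- assemble_image(pat, red, MEAN_LEAF, illuminant = ILLUM)
  mos <- make_mosaic(60, 30, seed = 5)
  sens <- build_sensitivity_mosaic(c(525, 562), mos, GRID)
  o <- integrate_channels(rgc_responses(quantal_catch(im, sens)),
                          identifier_masks(mos))$red_green
  expect_gt(mean(o[31:52, ]), mean(o[1:22, ]))
})
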