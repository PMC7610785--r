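test_that("band integrals are exact for piecewise-linear spectra", {
  ax <- make_axis(400, 3600, 11)
  B <- length(ax$values)
  # constant: c * (hi - lo), with window bounds off the bin grid
  cube_c <- hypercube(array(3, dim = c(1, 1, B)), ax)
  b <- band_auc(cube_c, band_definition("x", 1425, 1485))
  expect_equal(b$values[1, 1], 3 * 60, tolerance = 1e-9)

  # linear ramp: closed-form quadratic integral
  y <- 0.002 * ax$values + 1
  cube_r <- hypercube(array(y, dim = c(1, 1, B)), ax)
  br <- band_auc(cube_r, band_definition("x", 1000, 1800))
  want <- 0.001 * (1800^2 - 1000^2) + (1800 - 1000)
  expect_equal(br$values[1, 1], want, tolerance = 1e-9)
})

test_that("band integrals match the Gaussian closed form within 1%", {
  ax <- make_axis(400, 3600, 11)
  for (sigma in c(15, 25, 40)) {
    y <- gaussian_profile(ax, data.frame(center = 2150, sigma = sigma,
                                         amplitude = 2))
    cube <- hypercube(array(y, dim = c(1, 1, length(ax$values))), ax)
    b <- band_auc(cube, band_definition("cd", 2025, 2275))
    want <- 2 * sigma * sqrt(2 * pi)
    expect_lt(abs(b$values[1, 1] - want) / want, 0.01)
  }
})

test_that("band_auc is linear in the cube", {
  ax <- make_axis(400, 3600, 11)
  B <- length(ax$values)
  X <- withr::with_seed(1, array(runif(2 * 2 * B), dim = c(2, 2, B)))
  Y <- withr::with_seed(2, array(runif(2 * 2 * B), dim = c(2, 2, B)))
  bd <- band_definition("b", 900, 1200)
  lhs <- band_auc(hypercube(2 * X + 3 * Y, ax), bd)$values
  rhs <- 2 * band_auc(hypercube(X, ax), bd)$values +
    3 * band_auc(hypercube(Y, ax), bd)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(band_auc(hypercube(X, ax), band_definition("z", 4000, 4100)),
               "outside")
})

test_that("nucleus band map is strictly higher on the planted nucleus", {
  sim <- simulate_cell_cube(phantom_spec(n_inside = 0, noise_sd = 0, seed = 2),
                            default_axis())
  pp <- preprocess_cube(sim$cube)
  b <- band_auc(pp, band_definition("nuclei", 775, 805))
  nuc <- sim$truth$component_masks$nuclei
  cyt <- sim$truth$cell_mask & !nuc
  expect_gt(min(b$values[nuc]), max(b$values[cyt]))
})

test_that("component band maps recover planted masks at Otsu threshold", {
  sim <- simulate_cell_cube(phantom_spec(n_inside = 4, noise_sd = 0,
                                         ev_amplitude = 1, seed = 3),
                            default_axis())
  pp <- preprocess_cube(sim$cube)
  bands <- default_bands()
  for (nm in c("nuclei", "nucleoli", "lipids", "proteins", "whole_cell")) {
    m <- band_auc(pp, bands[[nm]])$values
    nmv <- (m - min(m)) / diff(range(m))
    thr <- EBImage::otsu(EBImage::Image(nmv), range = c(0, 1))
    expect_gte(jaccard(nmv > thr, sim$truth$component_masks[[nm]]), 0.9)
  }
  # deuterium map recovers the planted EV pixels
  q <- attr(pp, "quant_cube")
  dm <- band_auc(q, bands$deuterium)$values
  dmv <- (dm - min(dm)) / diff(range(dm))
  thr <- EBImage::otsu(EBImage::Image(dmv), range = c(0, 1))
  tr <- sim$truth$ev_pixels
  planted <- matrix(FALSE, 48, 48)
  planted[cbind(tr$row, tr$col)] <- TRUE
  expect_gte(jaccard(dmv > thr, planted), 0.9)
})

test_that("deuterium FWHM matches the Gaussian closed form within one bin", {
  ax <- cropped_axis()
  for (sigma in c(10, 20, 40)) {
    y <- gaussian_profile(ax, data.frame(center = 2140, sigma = sigma,
                                         amplitude = 1))
    cube <- hypercube(array(y, dim = c(1, 1, length(ax$values))), ax)
    f <- deuterium_fwhm(cube)
    expect_lt(abs(f$fwhm[1, 1] - 2 * sqrt(2 * log(2)) * sigma),
              ax$resolution)
  }
})

test_that("flat silent windows return the sentinel width and unit score", {
  ax <- cropped_axis()
  cube <- hypercube(array(0, dim = c(1, 1, length(ax$values))), ax)
  f <- deuterium_fwhm(cube)
  expect_equal(f$fwhm[1, 1], 250)
  expect_equal(f$score[1, 1], 1)
})

test_that("sharper deuterium peaks score higher, independent of amplitude", {
  ax <- cropped_axis()
  B <- length(ax$values)
  mk <- function(sigma, amp) {
    y <- gaussian_profile(ax, data.frame(center = 2140, sigma = sigma,
                                         amplitude = amp))
    deuterium_fwhm(hypercube(array(y, dim = c(1, 1, B)), ax))
  }
  expect_gt(mk(15, 1)$score[1, 1], mk(40, 1)$score[1, 1])
  # scale invariance: FWHM depends on shape only
  expect_equal(mk(22, 1)$fwhm[1, 1], mk(22, 7)$fwhm[1, 1])
})

test_that("FWHM noise floor silences peakless pixels", {
  ax <- cropped_axis()
  B <- length(ax$values)
  arr <- array(0, dim = c(1, 2, B))
  arr[1, 1, ] <- gaussian_profile(ax, data.frame(center = 2140, sigma = 20,
                                                 amplitude = 1))
  arr[1, 2, ] <- 0.01   # flat, below floor
  f <- deuterium_fwhm(hypercube(arr, ax), noise_floor = 0.1)
  expect_lt(f$fwhm[1, 1], 60)
  expect_equal(f$fwhm[1, 2], 250)
})

test_that("composite rendering is order-independent and channel-faithful", {
  m1 <- matrix(seq(0, 1, length.out = 16), 4, 4)
  m0 <- matrix(0, 4, 4)
  g <- render_composite(list(a = m1), c(a = "white"))
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 1], (m1 - min(m1)) / diff(range(m1)))

  two <- render_composite(list(deut = m0, wc = m1),
                          c(deut = "red", wc = "green"))
  expect_equal(max(two[, , 1]), 0)   # zero deuterium -> no red anywhere

  ab <- render_composite(list(a = m1, b = m1 * 0.5),
                         c(a = "red", b = "blue"))
  ba <- render_composite(list(b = m1 * 0.5, a = m1),
                         c(a = "red", b = "blue"))
  expect_equal(ab, ba)

  expect_error(render_composite(list(a = m1, b = matrix(0, 3, 3)),
                                c(a = "red", b = "blue")), "share")
})
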