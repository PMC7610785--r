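test_that("spectral axis construction matches the instrument grid", {
  ax <- make_axis(0, 3700, 11)
  expect_length(ax$values, 337)
  expect_identical(ax$values[1], 0)
  expect_true(ax$values[337] >= 3700 - 11)

  silent <- make_axis(1800, 2800, 10)
  expect_length(silent$values, 101)
  expect_true(all(silent$values >= 1800 & silent$values <= 2800))

  expect_error(make_axis(400, 400.5, 11), "fewer than 2 bins")
  expect_error(make_axis(3600, 400, 11), "inverted")
  expect_error(make_axis(NA, 100, 11), "finite")
  expect_error(make_axis(0, 100, -1), "> 0")
})

test_that("trap spectra hit the programmed C-D/C-H ratio exactly when noise-free", {
  ax <- cropped_axis()
  M0 <- simulate_ev_spectra(0, 1, ax, noise_sd = 0)
  i_cd <- which.min(abs(ax$values - 2140))
  expect_equal(M0[1, i_cd], 0)

  M <- simulate_ev_spectra(0.5, 1, ax, noise_sd = 0)
  expect_equal(cd_ch_ratio(M, ax), 0.5, ignore_attr = TRUE)

  expect_error(simulate_ev_spectra(0.5, 1, make_axis(400, 1600, 11)),
               "cover both")
  expect_error(simulate_ev_spectra(-1, 5, ax), ">= 0")
})

test_that("noisy trap cohorts recover the programmed ratio within 3 SE", {
  ax <- cropped_axis()
  M <- simulate_ev_spectra(0.5, 200, ax, noise_sd = 0.01, seed = 3)
  r <- cd_ch_ratio(M, ax, noise_floor = spectrum_noise_floor(M, ax))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.5), 3 * se)
})

test_that("simulators are deterministic and leave global RNG state alone", {
  ax <- cropped_axis()
  set.seed(99)
  before <- .Random.seed
  a <- simulate_ev_spectra(0.4, 10, ax, noise_sd = 0.05, seed = 7)
  expect_identical(before, .Random.seed)
  b <- simulate_ev_spectra(0.4, 10, ax, noise_sd = 0.05, seed = 7)
  expect_identical(a, b)

  s1 <- simulate_cell_cube(phantom_spec(seed = 5), default_axis())
  s2 <- simulate_cell_cube(phantom_spec(seed = 5), default_axis())
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$truth$ev_pixels, s2$truth$ev_pixels)
})

test_that("phantom EV placements honour their masks", {
  sim <- simulate_cell_cube(phantom_spec(n_inside = 4, n_membrane = 3,
                                         n_outside = 3, seed = 2),
                            default_axis())
  tr <- sim$truth
  membrane_mx <- ramanev:::mask_boundary(tr$cell_mask)
  for (i in seq_len(nrow(tr$ev_pixels))) {
    p <- tr$ev_pixels[i, ]
    if (p$placement == "inside")
      expect_true(tr$cell_mask[p$row, p$col] && !membrane_mx[p$row, p$col])
    if (p$placement == "membrane")
      expect_true(membrane_mx[p$row, p$col])
    if (p$placement == "outside")
      expect_false(tr$cell_mask[p$row, p$col])
  }

  bad <- data.frame(row = 1, col = 1, amplitude = 1, placement = "inside")
  expect_error(
    simulate_cell_cube(phantom_spec(ev_pixels = bad), default_axis()),
    "inconsistent")
})

test_that("noise-free phantom is exactly the planted linear model", {
  ax <- default_axis()
  base <- phantom_spec(n_inside = 0, noise_sd = 0, seed = 4)
  with_ev <- phantom_spec(n_inside = 3, noise_sd = 0, seed = 4,
                          ev_amplitude = 0.7)
  c0 <- simulate_cell_cube(base, ax)$cube
  sim1 <- simulate_cell_cube(with_ev, ax)
  c1 <- sim1$cube
  diff <- c1$data - c0$data
  dsig <- gaussian_profile(ax, data.frame(center = 2140, sigma = 30,
                                          amplitude = 1))
  tr <- sim1$truth$ev_pixels
  nonzero <- apply(diff != 0, c(1, 2), any)
  expect_setequal(which(nonzero), tr$row + (tr$col - 1) * dim(c1)[1])
  for (i in seq_len(nrow(tr)))
    expect_equal(diff[tr$row[i], tr$col[i], ], tr$amplitude[i] * dsig)
})

test_that("planted deuterium amplitude is monotonically recoverable", {
  ax <- default_axis()
  amps <- c(0.2, 0.5, 1, 2)
  vals <- vapply(amps, function(a) {
    sim <- simulate_cell_cube(phantom_spec(n_inside = 1, noise_sd = 0,
                                           ev_amplitude = a, seed = 6), ax)
    p <- sim$truth$ev_pixels
    b <- band_auc(sim$cube, band_definition("deuterium", 2025, 2275))
    b$values[p$row[1], p$col[1]]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("clustered EV deposits occupy adjacent pixels of one placement", {
  sim <- simulate_cell_cube(phantom_spec(n_inside = 3, cluster_size = 2,
                                         seed = 8), default_axis())
  tr <- sim$truth$ev_pixels
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$placement == "inside"))
  # pairs are adjacent (unit Chebyshev distance within each cluster)
  for (k in seq(1, 5, by = 2)) {
    expect_lte(max(abs(tr$row[k] - tr$row[k + 1]),
                   abs(tr$col[k] - tr$col[k + 1])), 1)
  }
})

test_that("component basis validation rejects out-of-window peaks", {
  comps <- default_components()
  comps$nuclei$center <- 900
  expect_error(phantom_spec(components = comps), "no peak inside")
  comps2 <- default_components()
  comps2$deuterium <- NULL
  expect_error(phantom_spec(components = comps2), "missing")
})
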