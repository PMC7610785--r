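test_that("cell segmentation recovers the planted footprint", {
  sim <- simulate_cell_cube(phantom_spec(n_inside = 0, noise_sd = 0, seed = 1),
                            default_axis())
  pp <- preprocess_cube(sim$cube)
  cell <- segment_cell(band_auc(pp, band_definition("wc", 2800, 3000)),
                       pixel_size = 0.5)
  expect_gte(jaccard(cell$mask, sim$truth$cell_mask), 0.95)
  expect_error(segment_cell(matrix(1, 10, 10)), "constant")
})

test_that("segmentation keeps the larger of two disjoint blobs", {
  m <- matrix(0, 32, 32)
  m[4:8, 4:8] <- 1          # 25 px
  m[15:28, 15:28] <- 1      # 196 px
  cell <- segment_cell(m + 0.0)
  expect_true(all(cell$mask[16:27, 16:27]))
  expect_false(any(cell$mask[4:8, 4:8]))
})

test_that("noise-free detection finds exactly the planted pixels", {
  sp <- phantom_spec(noise_sd = 0, baseline_gradient = 0, n_inside = 5,
                     ev_amplitude = 1, seed = 1)
  sim <- simulate_cell_cube(sp, default_axis())
  expect_warning(rep <- quantify_uptake(sim$cube), "degenerate exterior")
  tr <- sim$truth$ev_pixels
  expect_setequal(paste(rep$distances$row, rep$distances$col),
                  paste(tr$row, tr$col))
  expect_equal(rep$pct_inside, 100)
})

test_that("isolated-positive pruning keeps clusters and drops singletons", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 10                    # isolated
  m[5, 5] <- 10; m[5, 6] <- 10     # pair
  ext <- matrix(TRUE, 8, 8); ext[m > 0] <- FALSE
  pos <- suppressWarnings(
    detect_deuterium_pixels(m, ext, prune_isolated = TRUE))
  expect_false(pos[2, 2])
  expect_true(pos[5, 5] && pos[5, 6])
})

test_that("membrane distances match the brute-force oracle on random masks", {
  for (s in 1:25) {
    n <- sample(c(16, 24, 32), 1)
    mask <- random_blob_mask(n, seed = s)
    if (sum(mask) < 9) next
    deut <- withr::with_seed(s + 1000,
      matrix(runif(n * n) < 0.05, n, n))
    if (!any(deut)) next
    cm <- as_cell_mask(mask, pixel_size = 0.5)
    got <- membrane_distances(deut, cm)$distance_um
    want <- brute_membrane_distances(deut, mask, 0.5)
    expect_identical(got, want)
  }
})

test_that("membrane distance signs and anchors behave as specified", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:12 - 1, 3:12 - 1] <- TRUE   # 10x10 square at rows/cols 2..11
  cm <- as_cell_mask(mask, pixel_size = 0.5)

  # membrane pixel -> 0
  d <- matrix(FALSE, 12, 12); d[2, 5] <- TRUE
  expect_equal(membrane_distances(d, cm)$distance_um, 0)

  # centre pixel matches brute force exactly
  d2 <- matrix(FALSE, 12, 12); d2[6, 6] <- TRUE
  expect_identical(membrane_distances(d2, cm)$distance_um,
                   brute_membrane_distances(d2, mask, 0.5))

  # outside pixel is negative
  d3 <- matrix(FALSE, 12, 12); d3[1, 1] <- TRUE
  expect_lt(membrane_distances(d3, cm)$distance_um, 0)

  expect_error(membrane_distances(matrix(FALSE, 3, 3), cm), "shape")
})

test_that("distances and percentages are translation invariant", {
  n <- 40
  base <- matrix(FALSE, n, n); base[10:20, 8:18] <- TRUE
  deut <- matrix(FALSE, n, n)
  deut[12, 10] <- TRUE; deut[15, 14] <- TRUE; deut[25, 25] <- TRUE
  w <- matrix(0, n, n); w[deut] <- c(2, 3, 5)[rank(which(deut))]

  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, n, n)
    out[(1 + dr):n, (1 + dc):n] <- m[1:(n - dr), 1:(n - dc)]
    out
  }
  sw <- matrix(0, n, n); sw[shift(deut, 7, 9)] <- w[deut]

  d0 <- membrane_distances(deut, as_cell_mask(base))
  d1 <- membrane_distances(shift(deut, 7, 9), as_cell_mask(shift(base, 7, 9)))
  expect_equal(sort(d0$distance_um), sort(d1$distance_um))

  p0 <- partition_signal(w, deut, as_cell_mask(base))
  p1 <- partition_signal(sw, shift(deut, 7, 9), as_cell_mask(shift(base, 7, 9)))
  expect_equal(p0$pct_inside, p1$pct_inside)
})

test_that("signal partition arithmetic follows the sign convention", {
  n <- 20
  mask <- matrix(FALSE, n, n); mask[5:15, 5:15] <- TRUE
  cm <- as_cell_mask(mask)

  all_in <- matrix(FALSE, n, n); all_in[8, 8] <- TRUE; all_in[10, 10] <- TRUE
  w <- matrix(1, n, n)
  p <- partition_signal(w, all_in, cm)
  expect_equal(p$pct_inside, 100)
  expect_equal(p$pct_outside, 0)

  half <- matrix(FALSE, n, n); half[10, 10] <- TRUE; half[2, 2] <- TRUE
  ph <- partition_signal(w, half, cm)
  expect_equal(ph$pct_inside, 50)
  expect_equal(ph$pct_inside + ph$pct_outside, 100, tolerance = 1e-9)

  # membrane counts as inside ("associated with")
  memb <- matrix(FALSE, n, n); memb[5, 10] <- TRUE
  expect_equal(partition_signal(w, memb, cm)$pct_inside, 100)

  none <- matrix(FALSE, n, n)
  expect_true(partition_signal(w, none, cm)$flagged)
})

test_that("extracted deuterium spectra carry coordinates and cell context", {
  sp <- phantom_spec(noise_sd = 0, baseline_gradient = 0, n_inside = 5,
                     ev_amplitude = 1, seed = 4)
  sim <- simulate_cell_cube(sp, default_axis())
  rep <- suppressWarnings(quantify_uptake(sim$cube))
  ex <- rep$spectra
  expect_equal(nrow(ex$spectra), 5)
  expect_setequal(paste(ex$locations$row, ex$locations$col),
                  paste(sim$truth$ev_pixels$row, sim$truth$ev_pixels$col))

  # interior spectra contain both the planted C-D band and cell signatures
  # (probed on the amplitude-faithful corrected cube)
  pp <- preprocess_cube(sim$cube)
  mask <- matrix(FALSE, 48, 48)
  mask[cbind(rep$distances$row, rep$distances$col)] <- TRUE
  exq <- extract_deuterium_spectra(attr(pp, "quant_cube"), mask, rep$cell)
  # cell context probed through the C-H stretch band, present at every
  # cell pixel whether the deposit sits over cytoplasm or nucleus
  ax <- exq$axis
  wd <- ramanev:::window_trapz_weights(ax, 2025, 2275)
  wch <- ramanev:::window_trapz_weights(ax, 2800, 3000)
  expect_true(all(exq$spectra %*% wd > 1))
  expect_true(all(exq$spectra %*% wch > 1))

  expect_warning(out <- extract_deuterium_spectra(sim$cube,
                                                  matrix(FALSE, 48, 48)),
                 "no deuterium")
  expect_equal(nrow(out$spectra), 0)
})

test_that("surface-bound deposits show higher relative deuterium than internal ones", {
  sp <- phantom_spec(noise_sd = 0, baseline_gradient = 0, n_inside = 3,
                     n_outside = 3, ev_amplitude = 1, seed = 6)
  sim <- simulate_cell_cube(sp, default_axis())
  rep <- suppressWarnings(quantify_uptake(sim$cube))
  pp <- preprocess_cube(sim$cube)
  mask <- matrix(FALSE, 48, 48)
  mask[cbind(rep$distances$row, rep$distances$col)] <- TRUE
  ex <- extract_deuterium_spectra(attr(pp, "quant_cube"), mask, rep$cell)
  ax <- ex$axis
  wd <- ramanev:::window_trapz_weights(ax, 2025, 2275)
  wpl <- ramanev:::window_trapz_weights(ax, 1425, 1485) +
    ramanev:::window_trapz_weights(ax, 1635, 1685) +
    ramanev:::window_trapz_weights(ax, 2800, 3000)
  rel <- as.numeric(ex$spectra %*% wd) /
    pmax(as.numeric(ex$spectra %*% wpl), 1e-6)
  inside <- ex$locations$distance_um > 0
  expect_gt(min(rel[!inside]), max(rel[inside]))
})

test_that("z-stacks pool per-slice uptake into one flagged 3D report", {
  ax <- default_axis()
  slices <- list(
    simulate_cell_cube(phantom_spec(n_inside = 2, cluster_size = 2,
                                    noise_sd = 0.05, seed = 31), ax)$cube,
    simulate_cell_cube(phantom_spec(n_inside = 1, n_outside = 1,
                                    cluster_size = 2, noise_sd = 0.05,
                                    seed = 32), ax)$cube)
  rep <- quantify_uptake_zstack(slices, prune_isolated = TRUE)
  expect_true(rep$is_3d)
  expect_equal(length(rep$reports), 2)
  expect_true(all(c("row", "col", "distance_um", "z") %in%
                    names(rep$distances)))
  expect_equal(rep$pct_inside + rep$pct_outside, 100, tolerance = 1e-9)
})
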