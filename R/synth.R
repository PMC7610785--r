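#' Default subcellular basis components
#'
#' Spectral signatures used by the cell phantom generator. Each component is a
#' small set of Gaussian peaks whose main peak sits inside the band window used
#' to image it: nuclei (DNA phosphodiester backbone, 775-805 cm^-1), nucleoli
#' (phenylalanine, 985-1015 cm^-1), lipids (CH2 bending, 1425-1485 cm^-1),
#' proteins (amide I, 1635-1685 cm^-1), whole-cell C-H stretch
#' (2800-3000 cm^-1), and the deuterium C-D band in the silent region
#' (1800-2800 cm^-1, centred at 2140 cm^-1).
#'
#' @return Named list of peak tables (columns `center`, `sigma`, `amplitude`).
#' @export
default_components <- function() {
  list(
    nuclei     = data.frame(center = 790,  sigma = 9,  amplitude = 1.0),
    nucleoli   = data.frame(center = 1000, sigma = 9,  amplitude = 1.2),
    lipids     = data.frame(center = c(1445, 2850), sigma = c(14, 25),
                            amplitude = c(1.0, 0.4)),
    proteins   = data.frame(center = c(1660, 2930), sigma = c(16, 35),
                            amplitude = c(0.9, 0.3)),
    whole_cell = data.frame(center = 2900, sigma = 45, amplitude = 1.2),
    deuterium  = data.frame(center = 2140, sigma = 30, amplitude = 1.0)
  )
}

# band window each component's main peak must fall in (silent region for
# deuterium); used to validate user-supplied component sets
.component_windows <- list(
  nuclei = c(775, 805), nucleoli = c(985, 1015), lipids = c(1425, 1485),
  proteins = c(1635, 1685), whole_cell = c(2800, 3000),
  deuterium = c(1800, 2800))

validate_components <- function(components) {
  for (nm in names(.component_windows)) {
    if (is.null(components[[nm]]))
      stop(sprintf("component '%s' missing from the basis set", nm))
    w <- .component_windows[[nm]]
    ctr <- as.data.frame(components[[nm]])$center
    if (!any(ctr >= w[1] & ctr <= w[2]))
      stop(sprintf("component '%s' has no peak inside its window [%g, %g] cm^-1",
                   nm, w[1], w[2]))
  }
  invisible(components)
}

#' Simulate single-EV trapping spectra
#'
#' Generates spectra of individually trapped extracellular vesicles with a
#' programmed carbon-deuterium to carbon-hydrogen intensity ratio. Each
#' spectrum is a C-H bending peak at 1440 cm^-1 plus a C-D peak at 2140 cm^-1
#' whose amplitude is scaled so that, noise-free, the intensity at the bin
#' nearest 2140 divided by the intensity at the bin nearest 1440 equals
#' `cd_to_ch_ratio` exactly; zero-mean Gaussian noise is then added per bin.
#'
#' @param cd_to_ch_ratio target intensity ratio (>= 0; 0 means unlabelled).
#' @param n_spectra number of spectra to draw.
#' @param axis a [make_axis()] grid covering 1440 and 2140 cm^-1.
#' @param noise_sd additive noise standard deviation per bin, in units of the
#'   C-H peak amplitude (which is 1).
#' @param seed integer seed; all randomness flows from it and global RNG state
#'   is left untouched.
#' @param ch_sigma,cd_sigma Gaussian peak widths in cm^-1.
#' @param context optional extra peak table added to every spectrum (e.g. an
#'   amide I shoulder); defaults to a weak 1660 cm^-1 protein peak.
#' @return A matrix of dimension `n_spectra x length(axis$values)` with the
#'   axis attached as attribute `"axis"`.
#' @export
simulate_ev_spectra <- function(cd_to_ch_ratio, n_spectra, axis,
                                noise_sd = 0.01, seed = 1,
                                ch_sigma = 15, cd_sigma = 20,
                                context = data.frame(center = 1660, sigma = 20,
                                                     amplitude = 0.25)) {
  if (cd_to_ch_ratio < 0) stop("cd_to_ch_ratio must be >= 0")
  if (n_spectra < 1) stop("n_spectra must be >= 1")
  v <- axis_values(axis)
  if (min(v) > 1440 - 15 || max(v) < 2140 + 15)
    stop("axis must cover both the 1440 and 2140 cm^-1 peaks")
  ch <- gaussian_profile(axis, data.frame(center = 1440, sigma = ch_sigma,
                                          amplitude = 1))
  cd_unit <- gaussian_profile(axis, data.frame(center = 2140, sigma = cd_sigma,
                                               amplitude = 1))
  i_ch <- axis_nearest(axis, 1440)
  i_cd <- axis_nearest(axis, 2140)
  cd_amp <- cd_to_ch_ratio * ch[i_ch] / cd_unit[i_cd]
  base <- ch + cd_amp * cd_unit
  if (!is.null(context) && nrow(as.data.frame(context)) > 0)
    base <- base + gaussian_profile(axis, context)
  M <- matrix(rep(base, each = n_spectra), nrow = n_spectra)
  if (noise_sd > 0)
    M <- M + withr::with_seed(as.integer(seed),
      matrix(stats::rnorm(n_spectra * length(v), sd = noise_sd),
             nrow = n_spectra))
  attr(M, "axis") <- if (inherits(axis, "raman_axis")) axis else as_raman_axis(axis)
  M
}

#' Describe a cell phantom
#'
#' Builds the parameter list consumed by [simulate_cell_cube()]: an elliptical
#' cell with nucleus, nucleoli, lipid droplets and a cytoplasmic protein
#' signature, a slowly varying autofluorescence baseline, a spatially uniform
#' system background (substrate/buffer bands outside the silent region), and
#' planted sub-resolution deuterium-positive EV pixels placed inside the cell,
#' on its membrane, or outside it.
#'
#' Defaults emulate a 24 x 24 um field at 0.5 um/pixel. EVs (~120 nm) are far
#' below the 500 nm pixel size, so each planted EV is a single-pixel point
#' source; clusters are adjacent pixels.
#'
#' @param dim image height/width in pixels (square frame, >= 32).
#' @param pixel_size micrometres per pixel.
#' @param n_inside,n_membrane,n_outside counts of planted EV pixels by
#'   placement.
#' @param ev_amplitude deuterium peak amplitude of each planted EV pixel
#'   (recycled across pixels).
#' @param ev_sigma deuterium peak width, cm^-1.
#' @param ev_pixels optional explicit data frame (`row`, `col`, `amplitude`,
#'   `placement` in `inside`/`membrane`/`outside`) overriding the counts.
#' @param cluster_size pixels per planted EV deposit (default 1). Deposits
#'   larger than one pixel are laid out as adjacent pixels (EV clusters, e.g.
#'   endosome-packaged vesicles, span neighbouring pixels at 500 nm
#'   sampling); every pixel of a cluster satisfies the cluster's placement.
#' @param baseline_amplitude overall scale of the polynomial autofluorescence
#'   baseline (plus broad hump).
#' @param baseline_coefs coefficients of the order-3 polynomial in scaled
#'   wavenumber.
#' @param baseline_gradient fractional left-right/top-bottom spatial variation
#'   of the baseline.
#' @param system_amplitude scale of the spatially uniform system background.
#' @param noise_sd per-bin additive Gaussian noise standard deviation.
#' @param components basis signature set, see [default_components()].
#' @param seed integer RNG seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = 48, pixel_size = 0.5,
                         n_inside = 5, n_membrane = 0, n_outside = 0,
                         ev_amplitude = 0.5, ev_sigma = 30, ev_pixels = NULL,
                         cluster_size = 1,
                         baseline_amplitude = 2,
                         baseline_coefs = c(0.8, 0.6, -0.3, 0.1),
                         baseline_gradient = 0.2,
                         system_amplitude = 1,
                         noise_sd = 0.05,
                         components = default_components(),
                         seed = 1) {
  if (dim < 32) stop("phantom frame must be at least 32 x 32 pixels")
  validate_components(components)
  structure(list(dim = as.integer(dim), pixel_size = pixel_size,
                 n_inside = n_inside, n_membrane = n_membrane,
                 n_outside = n_outside, ev_amplitude = ev_amplitude,
                 ev_sigma = ev_sigma, ev_pixels = ev_pixels,
                 cluster_size = as.integer(cluster_size),
                 baseline_amplitude = baseline_amplitude,
                 baseline_coefs = baseline_coefs,
                 baseline_gradient = baseline_gradient,
                 system_amplitude = system_amplitude,
                 noise_sd = noise_sd, components = components,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# disc/ellipse masks on an n x n grid
.disc_mask <- function(n, cr, cc, ra, rb = ra) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - cr) / ra)^2 + ((c - cc) / rb)^2 <= 1
}

# 8-connected boundary: mask pixels with any 8-neighbour off the mask (image
# edges count as off-mask)
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  inner <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inner <- inner & padded[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  mask & !inner
}

# geometry shared by all phantoms of a given frame size
.phantom_geometry <- function(n) {
  ctr <- (n + 1) / 2
  cell <- .disc_mask(n, ctr, ctr, round(0.32 * n), round(0.26 * n))
  nucleus <- .disc_mask(n, ctr - round(0.05 * n), ctr - round(0.03 * n),
                        round(0.13 * n))
  nucleus <- nucleus & cell
  nucleoli <- (.disc_mask(n, ctr - round(0.08 * n), ctr - round(0.06 * n),
                          max(1, round(0.03 * n))) |
               .disc_mask(n, ctr - round(0.01 * n), ctr + round(0.01 * n),
                          max(1, round(0.025 * n)))) & nucleus
  droplets <- (.disc_mask(n, ctr + round(0.12 * n), ctr + round(0.10 * n),
                          max(1, round(0.035 * n))) |
               .disc_mask(n, ctr + round(0.02 * n), ctr - round(0.17 * n),
                          max(1, round(0.03 * n))) |
               .disc_mask(n, ctr + round(0.15 * n), ctr - round(0.05 * n),
                          max(1, round(0.025 * n)))) & cell & !nucleus
  cytoplasm <- cell & !nucleus
  list(cell = cell,
       component_masks = list(nuclei = nucleus, nucleoli = nucleoli,
                              lipids = droplets, proteins = cytoplasm,
                              whole_cell = cell))
}

# system background: substrate/buffer bands placed clear of the C-D window
# and of every component band window, so univariate maps of a clean cell are
# not contaminated by normalisation-scale residues of the shared background
.system_profile <- function(axis, amplitude) {
  amplitude * gaussian_profile(axis, data.frame(
    center = c(1150, 1795, 3300), sigma = c(45, 40, 85),
    amplitude = c(0.5, 0.35, 0.7)))
}

.baseline_profile <- function(axis, spec) {
  v <- axis_values(axis)
  u <- (v - v[1]) / (v[length(v)] - v[1])
  poly <- spec$baseline_coefs[1] + spec$baseline_coefs[2] * u +
    spec$baseline_coefs[3] * u^2 + spec$baseline_coefs[4] * u^3
  hump <- 0.5 * exp(-(v - 1300)^2 / (2 * 450^2))
  spec$baseline_amplitude * (poly + hump)
}

#' Simulate a hyperspectral cell phantom
#'
#' Renders the phantom described by a [phantom_spec()] on a spectral axis.
#' Every pixel spectrum is the sum of the component signatures it belongs to,
#' a slowly varying autofluorescence baseline, a uniform system background,
#' planted deuterium EV peaks, and per-bin Gaussian noise. The full ground
#' truth (masks, EV table, baseline/noise parameters) is returned alongside
#' the cube so downstream stages can be validated against it.
#'
#' @param spec a [phantom_spec()].
#' @param axis a [make_axis()] grid (default 0-3700 cm^-1 at 11 cm^-1).
#' @return A list with elements `cube` ([hypercube()]) and `truth` (list with
#'   `cell_mask`, `membrane`, `component_masks`, `ev_pixels`,
#'   `baseline_params`, `noise_sd`, `seed`).
#' @export
simulate_cell_cube <- function(spec, axis = make_axis(0, 3700, 11)) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$dim
  geo <- .phantom_geometry(n)
  membrane <- mask_boundary(geo$cell)
  interior <- geo$cell & !membrane
  # strict interior a little away from the membrane so signed distances of
  # planted-inside pixels are unambiguous
  deep <- interior
  for (k in 1:2) deep <- deep & !mask_boundary(deep)
  outside <- !geo$cell

  ev <- spec$ev_pixels
  if (is.null(ev)) {
    csz <- max(1L, spec$cluster_size)
    offsets <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))[seq_len(min(csz, 4L))]
    ev <- withr::with_seed(spec$seed + 1L, {
      draw <- function(mask, count, placement) {
        # anchors such that every pixel of the cluster satisfies the placement
        ok <- mask
        for (off in offsets) {
          sh <- matrix(FALSE, n, n)
          rs <- seq_len(n - off[1]); cs <- seq_len(n - off[2])
          sh[rs, cs] <- mask[rs + off[1], cs + off[2]]
          ok <- ok & sh
        }
        idx <- which(ok)
        if (count > length(idx))
          stop(sprintf("cannot place %d EV clusters with placement '%s'",
                       count, placement))
        if (count == 0)
          return(data.frame(row = integer(), col = integer(),
                            amplitude = numeric(), placement = character()))
        sel <- sample(idx, count)
        anchors <- cbind(((sel - 1) %% n) + 1, ((sel - 1) %/% n) + 1)
        do.call(rbind, lapply(seq_len(count), function(i)
          data.frame(row = anchors[i, 1] + vapply(offsets, `[`, integer(1), 1),
                     col = anchors[i, 2] + vapply(offsets, `[`, integer(1), 2),
                     amplitude = rep_len(spec$ev_amplitude, length(offsets)),
                     placement = placement)))
      }
      # keep outside EVs away from the frame edge and the membrane
      out_ok <- outside & !mask_boundary(outside)
      out_ok[c(1, n), ] <- FALSE; out_ok[, c(1, n)] <- FALSE
      rbind(draw(deep, spec$n_inside, "inside"),
            draw(membrane, spec$n_membrane, "membrane"),
            draw(out_ok, spec$n_outside, "outside"))
    })
  } else {
    ev <- as.data.frame(ev)
    for (i in seq_len(nrow(ev))) {
      p <- ev$placement[i]; r <- ev$row[i]; c <- ev$col[i]
      ok <- switch(p,
                   inside = interior[r, c],
                   membrane = membrane[r, c],
                   outside = outside[r, c],
                   stop("placement must be inside/membrane/outside"))
      if (!ok)
        stop(sprintf("EV pixel (%d, %d) inconsistent with placement '%s'",
                     r, c, p))
    }
  }

  v <- axis_values(axis)
  B <- length(v)
  npx <- n * n
  M <- matrix(0, npx, B)
  comps <- spec$components
  for (nm in names(geo$component_masks)) {
    sig <- gaussian_profile(axis, comps[[nm]])
    M <- M + as.numeric(geo$component_masks[[nm]]) %o% sig
  }
  # autofluorescence: smooth spatial scaling of a fixed spectral profile
  rr <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  g <- 1 + spec$baseline_gradient * ((cc - (n + 1) / 2) / n +
                                     (rr - (n + 1) / 2) / n)
  bl <- .baseline_profile(axis, spec)
  M <- M + as.numeric(g) %o% bl
  sysbg <- .system_profile(axis, spec$system_amplitude)
  M <- M + rep(1, npx) %o% sysbg
  # planted EVs
  dsig <- gaussian_profile(axis, data.frame(center = 2140,
                                            sigma = spec$ev_sigma,
                                            amplitude = 1))
  if (nrow(ev) > 0) {
    px <- ev$row + (ev$col - 1) * n
    for (i in seq_len(nrow(ev)))
      M[px[i], ] <- M[px[i], ] + ev$amplitude[i] * dsig
  }
  if (spec$noise_sd > 0)
    M <- M + withr::with_seed(spec$seed,
      matrix(stats::rnorm(npx * B, sd = spec$noise_sd), npx, B))

  cube <- hypercube(array(M, dim = c(n, n, B)),
                    if (inherits(axis, "raman_axis")) axis else as_raman_axis(axis),
                    pixel_size = spec$pixel_size)
  truth <- list(cell_mask = geo$cell, membrane = membrane,
                component_masks = geo$component_masks, ev_pixels = ev,
                baseline_params = list(amplitude = spec$baseline_amplitude,
                                       coefs = spec$baseline_coefs,
                                       gradient = spec$baseline_gradient,
                                       system = spec$system_amplitude),
                noise_sd = spec$noise_sd, seed = spec$seed)
  list(cube = cube, truth = truth)
}

#' Phantom family for the three uptake cohorts
#'
#' Builds one phantom per uptake condition: `internalised` (EV clusters deep
#' in the cytoplasm, as for receptive cells at 37 C), `surface` (EVs at the
#' membrane, as for uptake-inhibited cells), and `low` (few EVs, mostly
#' off-cell). The planted ordering of inside-signal fraction and of median
#' signed membrane distance is internalised > surface > low.
#'
#' @param seed integer seed; each cohort derives its own sub-seed.
#' @param dim frame size in pixels.
#' @param noise_sd per-bin noise level.
#' @param ev_amplitude planted deuterium amplitude.
#' @return Named list of [phantom_spec()]s.
#' @export
uptake_cohort_specs <- function(seed = 1, dim = 48, noise_sd = 0.05,
                                ev_amplitude = 0.5) {
  list(
    internalised = phantom_spec(dim = dim, n_inside = 6, n_membrane = 0,
                                n_outside = 1, ev_amplitude = ev_amplitude,
                                cluster_size = 2, noise_sd = noise_sd,
                                seed = seed * 101L + 1L),
    surface = phantom_spec(dim = dim, n_inside = 1, n_membrane = 5,
                           n_outside = 2, ev_amplitude = ev_amplitude,
                           cluster_size = 2, noise_sd = noise_sd,
                           seed = seed * 101L + 2L),
    low = phantom_spec(dim = dim, n_inside = 0, n_membrane = 1,
                       n_outside = 4, ev_amplitude = ev_amplitude,
                       cluster_size = 2, noise_sd = noise_sd,
                       seed = seed * 101L + 3L)
  )
}

#' Simulate deuterium-positive pixel spectra for two uptake modes
#'
#' Direct generator for the chemometrics stage: spectra of deuterium-positive
#' pixels as they appear after preprocessing. Internalised pixels carry the
#' planted deuterium band on top of the full cellular signature (protein,
#' lipid and C-H stretch peaks contributed by the surrounding confocal
#' volume); surface-bound pixels carry a stronger relative deuterium band
#' with only a weak cellular contribution. Spectra are area-normalised, as
#' extracted pixel spectra are.
#'
#' @param n_per_cohort spectra per cohort.
#' @param axis a [make_axis()] grid.
#' @param noise_sd per-bin noise before normalisation.
#' @param seed integer seed.
#' @return List with `spectra` (matrix), `labels` (character vector
#'   `internalised`/`surface`), and `axis`.
#' @export
simulate_uptake_pixel_spectra <- function(n_per_cohort = 30,
                                          axis = make_axis(400, 3600, 11),
                                          noise_sd = 0.02, seed = 1) {
  comps <- default_components()
  cell <- gaussian_profile(axis, comps$proteins) +
    gaussian_profile(axis, comps$lipids) +
    gaussian_profile(axis, comps$whole_cell)
  deut <- gaussian_profile(axis, comps$deuterium)
  inside <- cell + 0.6 * deut
  surface <- 0.15 * cell + 0.8 * deut
  n <- n_per_cohort
  B <- length(axis_values(axis))
  M <- rbind(matrix(rep(inside, each = n), n),
             matrix(rep(surface, each = n), n))
  if (noise_sd > 0)
    M <- M + withr::with_seed(as.integer(seed),
      matrix(stats::rnorm(2 * n * B, sd = noise_sd), 2 * n))
  w <- trapz_weights(axis)
  M <- M / as.numeric(M %*% w)
  attr(M, "axis") <- axis
  list(spectra = M, labels = rep(c("internalised", "surface"), each = n),
       axis = axis)
}
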