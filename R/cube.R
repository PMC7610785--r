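#' Construct a Raman spectrum
#'
#' @param axis a [make_axis()] grid.
#' @param intensities numeric vector, one value per axis bin.
#' @param empty logical flag marking an empty/saturated pixel spectrum.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(axis, intensities, empty = FALSE) {
  if (!inherits(axis, "raman_axis")) axis <- as_raman_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis$values))
    stop("intensities length does not match the axis")
  if (any(!is.finite(intensities)))
    stop("spectrum intensities must be finite")
  structure(list(axis = axis, intensities = intensities, empty = isTRUE(empty)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d bins%s\n", length(x$intensities),
              if (x$empty) " [flagged empty]" else ""))
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' The imaging unit: an H x W grid of Raman spectra sharing one wavenumber
#' axis, with the spatial pixel size recorded in micrometres. Z-stacks are
#' represented as lists of 2D cubes processed slice by slice.
#'
#' @param data numeric array of dimension `c(H, W, B)` where `B` matches the
#'   axis length.
#' @param axis a [make_axis()] grid.
#' @param pixel_size spatial sampling in micrometres per pixel (default 0.5,
#'   i.e. 500 nm imaging resolution).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, axis, pixel_size = 0.5) {
  if (!inherits(axis, "raman_axis")) axis <- as_raman_axis(axis)
  if (length(dim(data)) != 3L)
    stop("cube data must be an (H, W, B) array; pass z-stacks as lists of slices")
  if (dim(data)[3] != length(axis$values))
    stop("cube spectral dimension does not match the axis")
  if (dim(data)[1] < 1L || dim(data)[2] < 1L) stop("cube spatial dims must be >= 1")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(data = data, axis = axis, pixel_size = pixel_size,
                 empty_mask = NULL, auc_scale = NULL),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bins, %.3g um/pixel\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# flatten to an (H*W) x B matrix of pixel spectra (row-major in pixel index:
# pixel (r, c) is row r + (c-1)*H, matching R array order)
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

# rebuild a cube from a pixel-spectra matrix, carrying over metadata
matrix_cube <- function(M, template, axis = template$axis) {
  d <- dim(template$data)
  out <- template
  out$axis <- axis
  out$data <- array(M, dim = c(d[1], d[2], length(axis$values)))
  out
}

#' Extract one pixel spectrum from a cube
#'
#' @param cube a [hypercube()].
#' @param row,col pixel indices (1-based).
#' @return A [raman_spectrum()].
#' @export
cube_spectrum <- function(cube, row, col) {
  raman_spectrum(cube$axis, cube$data[row, col, ],
                 empty = !is.null(cube$empty_mask) && cube$empty_mask[row, col])
}

#' Evaluate a sum of Gaussian peaks on an axis
#'
#' Peak shape used throughout the synthetic module: Gaussian in wavenumber,
#' `a * exp(-(v - center)^2 / (2 * sigma^2))`.
#'
#' @param axis a [make_axis()] grid.
#' @param peaks a data frame or matrix with columns `center`, `sigma`,
#'   `amplitude` (cm^-1, cm^-1, arbitrary units).
#' @return Numeric vector of intensities on the axis.
#' @export
gaussian_profile <- function(axis, peaks) {
  v <- axis_values(axis)
  peaks <- as.data.frame(peaks)
  y <- numeric(length(v))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$amplitude[i] *
      exp(-(v - peaks$center[i])^2 / (2 * peaks$sigma[i]^2))
  y
}
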