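#' Construct a spectral axis
#'
#' The wavenumber grid shared by all spectra and hyperspectral cubes. The grid
#' is uniform: it starts at `min_cm1` and advances in steps of `resolution_cm1`
#' up to (at most) `max_cm1`, mirroring a dispersive Raman spectrograph with a
#' fixed bin spacing.
#'
#' @param min_cm1 lower bound of the grid, in cm^-1.
#' @param max_cm1 upper bound of the grid, in cm^-1. The last bin is the
#'   largest grid point not exceeding `max_cm1`.
#' @param resolution_cm1 bin spacing in cm^-1 (the instrument default used
#'   throughout is 11 cm^-1).
#' @return An object of class `raman_axis`: a list with `values` (ascending
#'   wavenumbers) and `resolution`.
#' @examples
#' ax <- make_axis(0, 3700, 11)
#' length(ax$values)  # 337 bins
#' @export
make_axis <- function(min_cm1, max_cm1, resolution_cm1) {
  if (!is.finite(min_cm1) || !is.finite(max_cm1) || !is.finite(resolution_cm1))
    stop("axis bounds and resolution must be finite")
  if (min_cm1 >= max_cm1)
    stop("axis bounds inverted or empty: min_cm1 must be < max_cm1")
  if (resolution_cm1 <= 0)
    stop("resolution_cm1 must be > 0")
  n <- floor((max_cm1 - min_cm1) / resolution_cm1) + 1L
  if (n < 2L)
    stop("axis would have fewer than 2 bins; widen the range or refine the resolution")
  structure(
    list(values = min_cm1 + resolution_cm1 * (seq_len(n) - 1),
         resolution = resolution_cm1),
    class = "raman_axis")
}

#' @export
print.raman_axis <- function(x, ...) {
  cat(sprintf("<raman_axis> %d bins, %.6g to %.6g cm^-1, resolution %.6g cm^-1\n",
              length(x$values), x$values[1], x$values[length(x$values)],
              x$resolution))
  invisible(x)
}

# validate a vector of wavenumbers as a uniform ascending grid
as_raman_axis <- function(values) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("axis must contain at least 2 finite wavenumbers")
  d <- diff(values)
  if (any(d <= 0)) stop("axis wavenumbers must be strictly increasing")
  res <- mean(d)
  if (max(abs(d - res)) > 1e-6 * max(abs(values)))
    stop("axis spacing is not uniform")
  structure(list(values = as.numeric(values), resolution = res),
            class = "raman_axis")
}

axis_values <- function(axis) {
  if (inherits(axis, "raman_axis")) axis$values else as.numeric(axis)
}

# index of the bin nearest to a wavenumber
axis_nearest <- function(axis, wavenumber) {
  v <- axis_values(axis)
  if (wavenumber < v[1] - axis$resolution || wavenumber > v[length(v)] + axis$resolution)
    stop(sprintf("wavenumber %.1f cm^-1 outside axis range [%.1f, %.1f]",
                 wavenumber, v[1], v[length(v)]))
  which.min(abs(v - wavenumber))
}

# indices of bins with lo <= wavenumber <= hi
axis_window <- function(axis, lo, hi) {
  v <- axis_values(axis)
  idx <- which(v >= lo & v <= hi)
  if (length(idx) == 0L)
    stop(sprintf("window [%.1f, %.1f] cm^-1 has no overlap with the axis", lo, hi))
  idx
}

#' Trapezoidal integral
#'
#' @param x abscissa (ascending).
#' @param y ordinate, same length as `x`.
#' @return The trapezoidal-rule integral of `y` over `x`.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# weight vector w such that sum(w * y) is the trapezoidal integral of y over
# the full axis
trapz_weights <- function(axis) {
  v <- axis_values(axis)
  n <- length(v)
  d <- diff(v)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

# weight vector for the exact integral of the piecewise-linear interpolant of
# y over [lo, hi]; partial edge bins are handled by interpolating the
# integrand at the window bounds, so the functional stays linear in y
window_trapz_weights <- function(axis, lo, hi) {
  v <- axis_values(axis)
  n <- length(v)
  if (lo >= hi) stop("band window must have lo < hi")
  lo <- max(lo, v[1]); hi <- min(hi, v[n])
  if (lo >= hi) stop("band window does not overlap the axis")
  w <- numeric(n)
  knots <- sort(unique(c(lo, hi, v[v > lo & v < hi])))
  for (s in seq_len(length(knots) - 1)) {
    a <- knots[s]; b <- knots[s + 1]
    i <- findInterval((a + b) / 2, v)          # segment lies in [v[i], v[i+1]]
    h <- v[i + 1] - v[i]
    # f(t) = y[i]*(v[i+1]-t)/h + y[i+1]*(t-v[i])/h; integrate over [a, b]
    len <- b - a
    mid <- (a + b) / 2
    w[i]     <- w[i]     + len * (v[i + 1] - mid) / h
    w[i + 1] <- w[i + 1] + len * (mid - v[i]) / h
  }
  w
}
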