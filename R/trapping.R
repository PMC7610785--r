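#' C-D to C-H peak intensity ratio of a trapped-EV spectrum
#'
#' The per-vesicle deuteration measure: the peak intensity near 2140 cm^-1
#' (carbon-deuterium stretch) divided by the peak intensity near 1440 cm^-1
#' (carbon-hydrogen bend). Peak intensity is the maximum corrected intensity
#' within `half_window` of the nominal position, which tolerates small
#' calibration shifts on a coarse (11 cm^-1) grid. Numerator intensities at
#' or below the noise floor report a ratio of 0 (no detectable deuterium);
#' denominators at or below the floor give an undefined, flagged ratio.
#'
#' @param x a [raman_spectrum()], or a numeric vector/matrix of intensities
#'   (spectra in rows) with `axis` supplied.
#' @param axis the wavenumber grid when `x` is not a `raman_spectrum`.
#' @param cd,ch nominal peak positions in cm^-1.
#' @param half_window local-maximum search half-width in cm^-1 (default 15).
#' @param noise_floor intensity below which a peak counts as absent
#'   (default 0). Use [spectrum_noise_floor()] to estimate one from
#'   signal-free silent-region bins.
#' @return For a single spectrum, a numeric ratio (`NA` with attribute
#'   `"flagged"` when undefined). For a matrix, a numeric vector.
#' @export
cd_ch_ratio <- function(x, axis = NULL, cd = 2140, ch = 1440,
                        half_window = 15, noise_floor = 0) {
  if (inherits(x, "raman_spectrum")) {
    axis <- x$axis
    M <- matrix(x$intensities, 1)
  } else {
    if (is.null(axis)) axis <- attr(x, "axis")
    if (is.null(axis)) stop("axis must be supplied for bare intensity input")
    if (!inherits(axis, "raman_axis")) axis <- as_raman_axis(axis)
    M <- if (is.matrix(x)) x else matrix(x, 1)
  }
  icd <- axis_window(axis, cd - half_window, cd + half_window)
  ich <- axis_window(axis, ch - half_window, ch + half_window)
  num <- apply(M[, icd, drop = FALSE], 1, max)
  den <- apply(M[, ich, drop = FALSE], 1, max)
  out <- num / den
  out[num <= noise_floor] <- 0
  bad <- den <= max(noise_floor, 0)
  out[bad] <- NA_real_
  if (length(out) == 1L) {
    out <- as.numeric(out)
    attr(out, "flagged") <- bad[1]
  }
  out
}

#' Noise floor of trap spectra from signal-free silent-region bins
#'
#' `k` times the standard deviation of the corrected intensities over
#' silent-region windows well away from the C-D band (1800-2000 and
#' 2300-2500 cm^-1 by default), pooled over all spectra.
#'
#' @param M matrix of spectra (rows) or a numeric vector.
#' @param axis the wavenumber grid.
#' @param windows list of length-2 windows to pool.
#' @param k multiplier (default 3).
#' @return Scalar noise floor.
#' @export
spectrum_noise_floor <- function(M, axis = attr(M, "axis"),
                                 windows = list(c(1800, 2000), c(2300, 2500)),
                                 k = 3) {
  if (!inherits(axis, "raman_axis")) axis <- as_raman_axis(axis)
  if (!is.matrix(M)) M <- matrix(M, 1)
  idx <- unlist(lapply(windows, function(w) axis_window(axis, w[1], w[2])))
  vals <- as.numeric(M[, idx, drop = FALSE])
  s <- stats::sd(vals)
  if (!is.finite(s)) s <- 0
  k * s
}

#' Build trap records from spectra and cohort labels
#'
#' @param M matrix of preprocessed trap spectra (rows), with axis attached or
#'   supplied.
#' @param cohort character/factor vector of cohort labels (e.g. incubation
#'   time in hours), recycled to the number of spectra.
#' @param axis wavenumber grid.
#' @param ... passed to [cd_ch_ratio()].
#' @return A data frame with columns `cohort`, `ratio`, `flagged`.
#' @export
trap_records <- function(M, cohort, axis = attr(M, "axis"), ...) {
  if (!is.matrix(M)) M <- matrix(M, 1)
  cohort <- as.character(rep_len(cohort, nrow(M)))
  if (any(!nzchar(cohort))) stop("cohort labels must be nonempty")
  r <- cd_ch_ratio(M, axis = axis, ...)
  data.frame(cohort = cohort, ratio = as.numeric(r), flagged = is.na(r))
}

#' Per-cohort summary of C-D/C-H ratios
#'
#' Descriptive statistics per cohort: n, mean, SD, and a bootstrap percentile
#' confidence interval of the mean. Cohorts with fewer than two usable
#' records are reported with missing SD and CI. Deterministic given `seed`.
#'
#' @param records a [trap_records()] data frame.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return Data frame with one row per cohort: `cohort`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`.
#' @export
cohort_summary <- function(records, n_boot = 1000, conf = 0.95, seed = 1) {
  stopifnot(all(c("cohort", "ratio") %in% names(records)))
  groups <- split(records$ratio[!is.na(records$ratio)],
                  records$cohort[!is.na(records$ratio)])
  alpha <- (1 - conf) / 2
  rows <- withr::with_seed(as.integer(seed), lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    if (n < 2)
      return(data.frame(cohort = g, n = n, mean = mean(x), sd = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    boots <- vapply(seq_len(n_boot),
                    function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    data.frame(cohort = g, n = n, mean = mean(x), sd = stats::sd(x),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  do.call(rbind, rows)
}
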