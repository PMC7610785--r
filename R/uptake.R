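#' Segment the cell footprint from a whole-cell band map
#'
#' Otsu threshold on the 2800-3000 cm^-1 C-H band image, binary closing
#' (radius 1), retention of the largest connected component, and hole
#' filling. The membrane is the 8-connected boundary of the resulting mask.
#'
#' @param whole_cell_map a [band_auc()] map or bare H x W matrix.
#' @param pixel_size micrometres per pixel (taken from a `band_map`'s source
#'   cube is not possible, so pass it explicitly; default 0.5).
#' @return A list of class `cell_mask`: `mask` (logical H x W), `membrane`
#'   (two-column matrix of boundary row/col coordinates), `pixel_size`,
#'   `otsu_threshold` (on the min-max scaled map).
#' @export
segment_cell <- function(whole_cell_map, pixel_size = 0.5) {
  m <- if (inherits(whole_cell_map, "band_map")) whole_cell_map$values
       else whole_cell_map
  rng <- range(m)
  if (diff(rng) == 0) stop("whole-cell map is constant; cannot segment")
  nm <- (m - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
  bw <- nm > thr
  closed <- EBImage::closing(EBImage::Image(bw * 1),
                             EBImage::makeBrush(3, shape = "box")) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(closed * 1))
  labm <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (max(labm) == 0) stop("no foreground found in the whole-cell map")
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  mask <- labm == keep
  mask <- matrix(as.logical(EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5),
                 nrow(m), ncol(m))
  bnd <- which(mask_boundary(mask), arr.ind = TRUE)
  structure(list(mask = mask,
                 membrane = unname(cbind(bnd[, 1], bnd[, 2])),
                 pixel_size = pixel_size, otsu_threshold = thr),
            class = "cell_mask")
}

#' Detect deuterium-positive pixels
#'
#' A pixel is deuterium-positive when its value in the deuterium band map
#' exceeds the cell-exterior mean by more than `k` exterior standard
#' deviations (the conventional 3-sigma rule by default). When the exterior
#' is degenerate (zero spread, e.g. noise-free data), the threshold falls
#' back, with a warning, to a high exterior quantile. Isolated positives
#' (no 8-connected positive neighbour) can optionally be pruned.
#'
#' @param deuterium_map a [band_auc()] map or bare H x W matrix.
#' @param exterior_mask logical H x W matrix of cell-exterior pixels.
#' @param k threshold multiplier (default 3).
#' @param prune_isolated drop positives with no positive 8-neighbour.
#' @param fallback_quantile exterior quantile used when the exterior SD is
#'   zero (default 0.999).
#' @return Logical H x W matrix with attribute `"threshold"`.
#' @export
detect_deuterium_pixels <- function(deuterium_map, exterior_mask, k = 3,
                                    prune_isolated = FALSE,
                                    fallback_quantile = 0.999) {
  m <- if (inherits(deuterium_map, "band_map")) deuterium_map$values
       else deuterium_map
  if (!all(dim(exterior_mask) == dim(m)))
    stop("exterior_mask must match the map's shape")
  if (!any(exterior_mask)) stop("exterior_mask is empty")
  ext <- m[exterior_mask]
  s <- stats::sd(ext)
  if (!is.finite(s) || s == 0) {
    warning("degenerate exterior statistics (SD = 0); falling back to a fixed quantile threshold")
    thr <- stats::quantile(ext, fallback_quantile, names = FALSE)
  } else {
    thr <- mean(ext) + k * s
  }
  pos <- m > thr
  if (prune_isolated && any(pos)) {
    h <- nrow(pos); w <- ncol(pos)
    padded <- matrix(FALSE, h + 2, w + 2)
    padded[2:(h + 1), 2:(w + 1)] <- pos
    nb <- matrix(0L, h, w)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb + padded[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    }
    pos <- pos & nb > 0
  }
  attr(pos, "threshold") <- thr
  pos
}

#' Signed distances from deuterium-positive pixels to the nearest membrane
#'
#' For each positive pixel, the Euclidean centre-to-centre distance (in
#' micrometres) to the nearest membrane pixel, signed positive for pixels
#' inside the cell mask, negative outside, and zero on the membrane itself.
#'
#' @param deuterium_mask logical H x W matrix of positive pixels.
#' @param cell a [segment_cell()] result.
#' @return Data frame with columns `row`, `col`, `distance_um`.
#' @export
membrane_distances <- function(deuterium_mask, cell) {
  stopifnot(inherits(cell, "cell_mask"))
  if (!all(dim(deuterium_mask) == dim(cell$mask)))
    stop("masks must share one shape")
  if (nrow(cell$membrane) == 0) stop("membrane is empty")
  pix <- which(deuterium_mask, arr.ind = TRUE)
  if (nrow(pix) == 0)
    return(data.frame(row = integer(), col = integer(),
                      distance_um = numeric()))
  mr <- cell$membrane[, 1]; mc <- cell$membrane[, 2]
  d2 <- outer(pix[, 1], mr, "-")^2 + outer(pix[, 2], mc, "-")^2
  d <- sqrt(apply(d2, 1, min)) * cell$pixel_size
  inside <- cell$mask[pix]
  onm <- mask_boundary(cell$mask)[pix]
  sgn <- ifelse(onm, 0, ifelse(inside, 1, -1))
  data.frame(row = unname(pix[, 1]), col = unname(pix[, 2]),
             distance_um = sgn * d)
}

#' Partition deuterium signal inside versus outside the cell
#'
#' Intensity-weighted split of the detected deuterium signal: the inside
#' percentage is the sum of the deuterium map over positive pixels with
#' signed membrane distance >= 0 (membrane pixels count as
#' "associated with" the cell) divided by the sum over all positive pixels.
#'
#' @param deuterium_map a [band_auc()] map or bare matrix, in
#'   amplitude-faithful units (see [quantify_uptake()]).
#' @param deuterium_mask logical matrix of positive pixels.
#' @param cell a [segment_cell()] result.
#' @return List with `pct_inside`, `pct_outside` (summing to 100), and
#'   `flagged` (TRUE when no positive pixels or non-positive total signal
#'   made the split undefined).
#' @export
partition_signal <- function(deuterium_map, deuterium_mask, cell) {
  m <- if (inherits(deuterium_map, "band_map")) deuterium_map$values
       else deuterium_map
  if (!any(deuterium_mask))
    return(list(pct_inside = NA_real_, pct_outside = NA_real_, flagged = TRUE))
  dist <- membrane_distances(deuterium_mask, cell)
  w <- m[cbind(dist$row, dist$col)]
  total <- sum(w)
  if (!is.finite(total) || total <= 0)
    return(list(pct_inside = NA_real_, pct_outside = NA_real_, flagged = TRUE))
  pct_in <- 100 * sum(w[dist$distance_um >= 0]) / total
  list(pct_inside = pct_in, pct_outside = 100 - pct_in, flagged = FALSE)
}

#' Extract spectra of deuterium-positive pixels
#'
#' @param cube a preprocessed [hypercube()].
#' @param deuterium_mask logical H x W matrix of positive pixels.
#' @param cell optional [segment_cell()] result; when given, each spectrum is
#'   tagged with its signed membrane distance.
#' @param cell_id identifier recorded with each spectrum.
#' @return List with `spectra` (n x B matrix), `locations` (data frame with
#'   `row`, `col`, `distance_um`, `cell_id`), and `axis`. Empty mask gives an
#'   empty result with a warning.
#' @export
extract_deuterium_spectra <- function(cube, deuterium_mask, cell = NULL,
                                      cell_id = "cell1") {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!all(dim(deuterium_mask) == d[1:2]))
    stop("deuterium_mask must match the cube's spatial shape")
  pix <- which(deuterium_mask, arr.ind = TRUE)
  if (nrow(pix) == 0) {
    warning("no deuterium-positive pixels to extract")
    return(list(spectra = matrix(numeric(), 0, d[3]),
                locations = data.frame(row = integer(), col = integer(),
                                       distance_um = numeric(),
                                       cell_id = character()),
                axis = cube$axis))
  }
  M <- cube_matrix(cube)
  rows <- pix[, 1] + (pix[, 2] - 1) * d[1]
  dist <- if (!is.null(cell)) membrane_distances(deuterium_mask, cell)$distance_um
          else rep(NA_real_, nrow(pix))
  list(spectra = M[rows, , drop = FALSE],
       locations = data.frame(row = unname(pix[, 1]), col = unname(pix[, 2]),
                              distance_um = dist,
                              cell_id = rep(cell_id, nrow(pix))),
       axis = cube$axis)
}

#' Full uptake quantification for one cell image
#'
#' The automated framework tying the stages together for a single (already
#' simulated or loaded) raw cube: preprocess; segment the cell from the
#' whole-cell C-H band; detect deuterium-positive pixels against
#' cell-exterior statistics; compute signed membrane distances; partition the
#' deuterium signal inside/outside; extract the positive-pixel spectra.
#'
#' Detection and signal partitioning use the deuterium band map in
#' amplitude-faithful units: the baseline-corrected, background-subtracted
#' cube before per-pixel area normalisation (normalising each pixel to unit
#' area would weight cell-interior pixels down relative to exterior ones and
#' distort the inside/outside split). The normalised cube is still what the
#' extracted spectra and the univariate images come from.
#'
#' @param cube a raw [hypercube()].
#' @param config a [preprocess_config()].
#' @param k detection threshold multiplier (default 3).
#' @param prune_isolated drop detected positives with no positive
#'   8-neighbour before quantification (default FALSE; enable when planted
#'   or expected deuterium deposits span adjacent pixels, where it rejects
#'   isolated threshold exceedances without touching real clusters).
#' @param cell_id identifier for the report.
#' @param deuterium_band a [band_definition()] (default 2025-2275 cm^-1).
#' @return A list of class `uptake_report`: `cell_id`, `cell`, positive-pixel
#'   `distances` data frame, `pct_inside`, `pct_outside`, `flagged`,
#'   `spectra` (extraction result), `maps` (named band maps), `fwhm`
#'   ([deuterium_fwhm()] result), and `thresholds` actually used.
#' @export
quantify_uptake <- function(cube, config = preprocess_config(), k = 3,
                            prune_isolated = FALSE, cell_id = "cell1",
                            deuterium_band = band_definition("deuterium",
                                                             2025, 2275)) {
  pp <- preprocess_cube(cube, config)
  ext <- attr(pp, "exterior_mask")
  if (is.null(ext)) ext <- auto_exterior_mask(pp)
  wc_map <- band_auc(pp, band_definition("whole_cell", 2800, 3000))
  cell <- segment_cell(wc_map, pixel_size = cube$pixel_size)
  dmap <- band_auc(pp, deuterium_band)
  qcube <- attr(pp, "quant_cube")
  if (is.null(qcube)) qcube <- pp
  qmap <- band_auc(qcube, deuterium_band)$values
  pos <- detect_deuterium_pixels(qmap, ext, k = k,
                                 prune_isolated = prune_isolated)
  floor_cd <- exterior_noise_floor(pp, ext,
                                   window = c(deuterium_band$lo,
                                              deuterium_band$hi), k = k)
  fwhm <- deuterium_fwhm(pp, window = c(deuterium_band$lo, deuterium_band$hi),
                         noise_floor = floor_cd)
  dist <- membrane_distances(pos, cell)
  part <- partition_signal(qmap, pos, cell)
  spec <- if (any(pos)) extract_deuterium_spectra(pp, pos, cell, cell_id)
          else suppressWarnings(extract_deuterium_spectra(pp, pos, cell, cell_id))
  structure(list(cell_id = cell_id, cell = cell, distances = dist,
                 pct_inside = part$pct_inside, pct_outside = part$pct_outside,
                 flagged = part$flagged, spectra = spec,
                 maps = list(whole_cell = wc_map, deuterium = dmap,
                             deuterium_quant = qmap),
                 fwhm = fwhm,
                 thresholds = list(otsu = cell$otsu_threshold,
                                   detection = attr(pos, "threshold"),
                                   detection_k = k,
                                   fwhm_noise_floor = floor_cd)),
            class = "uptake_report")
}

#' @export
print.uptake_report <- function(x, ...) {
  cat(sprintf("<uptake_report> %s: %d deuterium-positive pixels", x$cell_id,
              nrow(x$distances)))
  if (x$flagged) cat(" [no deuterium signal]\n")
  else cat(sprintf(", %.1f%% inside / %.1f%% outside\n",
                   x$pct_inside, x$pct_outside))
  invisible(x)
}

#' Pool per-slice uptake reports of a z-stack
#'
#' Applies [quantify_uptake()] to each slice of a z-stack (a list of 2D
#' cubes), pools the signed distances, and combines the inside/outside split
#' weighting each slice by its detected signal.
#'
#' @param slices list of raw [hypercube()]s.
#' @param ... passed to [quantify_uptake()].
#' @param cell_id identifier for the pooled report.
#' @return A list of class `uptake_report_3d`: pooled `distances`,
#'   `pct_inside`, `pct_outside`, per-slice `reports`, and `is_3d = TRUE`.
#' @export
quantify_uptake_zstack <- function(slices, ..., cell_id = "cell1") {
  stopifnot(is.list(slices), length(slices) >= 1)
  reports <- lapply(seq_along(slices), function(z)
    quantify_uptake(slices[[z]], ..., cell_id = sprintf("%s_z%d", cell_id, z)))
  dist <- do.call(rbind, lapply(seq_along(reports), function(z)
    cbind(reports[[z]]$distances, z = z)))
  wts <- vapply(reports, function(r)
    sum(pmax(r$maps$deuterium_quant[as.matrix(r$distances[, c("row", "col")])], 0)),
    numeric(1))
  ok <- !vapply(reports, `[[`, logical(1), "flagged") & wts > 0
  pct_in <- if (any(ok))
    sum(vapply(reports[ok], `[[`, numeric(1), "pct_inside") * wts[ok]) / sum(wts[ok])
  else NA_real_
  structure(list(cell_id = cell_id, distances = dist, pct_inside = pct_in,
                 pct_outside = if (is.na(pct_in)) NA_real_ else 100 - pct_in,
                 flagged = !any(ok), reports = reports, is_3d = TRUE),
            class = "uptake_report_3d")
}
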