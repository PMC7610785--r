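#' Write a hyperspectral cube to HDF5
#'
#' Native storage: datasets `cube` (H x W x B), `axis` (wavenumbers),
#' `pixel_size`, and optionally the phantom ground-truth masks and EV table.
#'
#' @param cube a [hypercube()].
#' @param path output `.h5` file (overwritten).
#' @param truth optional phantom truth list from [simulate_cell_cube()].
#' @return `path`, invisibly.
#' @export
write_cube_h5 <- function(cube, path, truth = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$data, path, "cube")
  rhdf5::h5write(cube$axis$values, path, "axis")
  rhdf5::h5write(cube$pixel_size, path, "pixel_size")
  if (!is.null(truth)) {
    rhdf5::h5createGroup(path, "truth")
    rhdf5::h5write(truth$cell_mask * 1L, path, "truth/cell_mask")
    ev <- truth$ev_pixels
    rhdf5::h5write(as.matrix(ev[, c("row", "col", "amplitude")]), path,
                   "truth/ev_table")
    rhdf5::h5write(as.character(ev$placement), path, "truth/ev_placement")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a hyperspectral cube from HDF5
#'
#' @param path `.h5` file written by [write_cube_h5()].
#' @return A [hypercube()].
#' @export
read_cube_h5 <- function(path) {
  data <- rhdf5::h5read(path, "cube")
  axis <- as_raman_axis(as.numeric(rhdf5::h5read(path, "axis")))
  ps <- as.numeric(rhdf5::h5read(path, "pixel_size"))
  rhdf5::h5closeAll()
  hypercube(data, axis, pixel_size = ps)
}

#' Write a cube as a plain-text matrix export
#'
#' Generic instrument-export-like text format: a header row of wavenumbers
#' preceded by `row` and `col` column names, then one pixel spectrum per
#' line with its 1-based pixel coordinates. A `# pixel_size_um:` comment line
#' carries the spatial calibration.
#'
#' @param cube a [hypercube()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_cube_text <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_um: %.17g", cube$pixel_size), con)
  writeLines(paste(c("row", "col", sprintf("%.10g", cube$axis$values)),
                   collapse = "\t"), con)
  M <- cube_matrix(cube)
  pix <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  lines <- vapply(seq_len(nrow(M)), function(i)
    paste(c(pix$row[i], pix$col[i], sprintf("%.17g", M[i, ])),
          collapse = "\t"), character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a plain-text matrix cube export
#'
#' Parses the format written by [write_cube_text()], validating axis
#' monotonicity and rejecting ragged rows with the offending line number.
#'
#' @param path text file.
#' @return A [hypercube()].
#' @export
read_cube_text <- function(path) {
  lines <- readLines(path)
  ps <- 0.5
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("pixel_size_um:\\s*([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) ps <- as.numeric(m[2])
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("text cube export needs a header row and data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "row" || header[2] != "col")
    stop("missing or malformed wavenumber header row (line 1 of data)")
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (any(is.na(wn))) stop("non-numeric wavenumber in header row")
  if (any(diff(wn) <= 0)) stop("header wavenumbers are not strictly increasing")
  axis <- as_raman_axis(wn)
  B <- length(wn)
  body <- lines[-1]
  vals <- vector("list", length(body))
  coords <- matrix(0L, length(body), 2)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != B + 2)
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + 1, B + 2, length(f)))
    coords[i, ] <- as.integer(f[1:2])
    vals[[i]] <- as.numeric(f[-(1:2)])
  }
  H <- max(coords[, 1]); W <- max(coords[, 2])
  if (nrow(coords) != H * W)
    stop(sprintf("expected %d pixel rows for a %d x %d image, found %d",
                 H * W, H, W, nrow(coords)))
  M <- matrix(0, H * W, B)
  M[coords[, 1] + (coords[, 2] - 1) * H, ] <- do.call(rbind, vals)
  hypercube(array(M, dim = c(H, W, B)), axis, pixel_size = ps)
}

#' Read a per-pixel long-format CSV cube
#'
#' Columns `row`, `col`, `wavenumber`, `intensity`; every pixel must carry
#' the same ascending wavenumber grid.
#'
#' @param path CSV file.
#' @param pixel_size micrometres per pixel (not stored in this format).
#' @return A [hypercube()].
#' @export
read_cube_csv <- function(path, pixel_size = 0.5) {
  df <- utils::read.csv(path)
  need <- c("row", "col", "wavenumber", "intensity")
  if (!all(need %in% names(df)))
    stop("per-pixel CSV needs columns row, col, wavenumber, intensity")
  wn <- sort(unique(df$wavenumber))
  axis <- as_raman_axis(wn)
  H <- max(df$row); W <- max(df$col); B <- length(wn)
  if (nrow(df) != H * W * B)
    stop(sprintf("expected %d rows for a %d x %d x %d cube, found %d",
                 H * W * B, H, W, B, nrow(df)))
  arr <- array(0, dim = c(H, W, B))
  arr[cbind(df$row, df$col, match(df$wavenumber, wn))] <- df$intensity
  hypercube(arr, axis, pixel_size = pixel_size)
}

#' Read a cube in any supported format
#'
#' @param path input file.
#' @param format `"h5"`, `"text"`, or `"csv"`; guessed from the extension by
#'   default.
#' @param ... passed to the format-specific reader.
#' @return A [hypercube()].
#' @export
read_cube <- function(path, format = c("auto", "h5", "text", "csv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, h5 = "h5", hdf5 = "h5", csv = "csv", "text")
  }
  switch(format,
         h5 = read_cube_h5(path, ...),
         text = read_cube_text(path, ...),
         csv = read_cube_csv(path, ...))
}

#' Write the phantom ground-truth EV table as CSV
#'
#' @param truth phantom truth list from [simulate_cell_cube()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth$ev_pixels[, c("row", "col", "amplitude", "placement")],
                   path, row.names = FALSE)
  invisible(path)
}
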