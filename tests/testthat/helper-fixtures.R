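# shared fixtures and independent oracles used across the suite

default_axis <- function() make_axis(0, 3700, 11)
cropped_axis <- function() make_axis(400, 3600, 11)

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# independent brute-force nearest-membrane search: plain double loop over
# boundary pixels, kept deliberately separate from the package's vectorized
# implementation
brute_membrane_distances <- function(deut_mask, mask, pixel_size) {
  bnd <- which(ramanev:::mask_boundary(mask), arr.ind = TRUE)
  pix <- which(deut_mask, arr.ind = TRUE)
  out <- numeric(nrow(pix))
  for (i in seq_len(nrow(pix))) {
    best <- Inf
    for (j in seq_len(nrow(bnd))) {
      d <- sqrt((pix[i, 1] - bnd[j, 1])^2 + (pix[i, 2] - bnd[j, 2])^2)
      if (d < best) best <- d
    }
    s <- if (ramanev:::mask_boundary(mask)[pix[i, 1], pix[i, 2]]) 0
         else if (mask[pix[i, 1], pix[i, 2]]) 1 else -1
    out[i] <- s * best * pixel_size
  }
  out
}

# build a cell_mask object directly from a logical mask (bypassing
# segmentation) for geometry-only tests
as_cell_mask <- function(mask, pixel_size = 0.5) {
  bnd <- which(ramanev:::mask_boundary(mask), arr.ind = TRUE)
  structure(list(mask = mask, membrane = unname(cbind(bnd[, 1], bnd[, 2])),
                 pixel_size = pixel_size, otsu_threshold = NA_real_),
            class = "cell_mask")
}

# random connected blob mask on an n x n grid (ellipse, possibly clipped)
random_blob_mask <- function(n, seed) {
  withr::with_seed(seed, {
    cr <- runif(1, n * 0.3, n * 0.7)
    cc <- runif(1, n * 0.3, n * 0.7)
    ra <- runif(1, n * 0.1, n * 0.35)
    rb <- runif(1, n * 0.1, n * 0.35)
    r <- matrix(seq_len(n), n, n)
    c <- matrix(seq_len(n), n, n, byrow = TRUE)
    ((r - cr) / ra)^2 + ((c - cc) / rb)^2 <= 1
  })
}
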