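#' Principal component analysis of extracted pixel spectra
#'
#' Mean-centred PCA (no variance scaling; the spectra are already
#' area-normalised and on one scale) computed by singular value
#' decomposition. Component signs are fixed by making each loading's
#' largest-magnitude element positive, so results are fully reproducible.
#'
#' @param spectra n x B matrix of spectra sharing one axis (rows = spectra).
#' @param n_components number of components to keep (`1 <= n_components < n`).
#' @param labels optional cohort label per spectrum.
#' @return A list of class `pca_result`: `scores` (n x k), `loadings`
#'   (k x B, orthonormal rows), `explained` (variance fractions,
#'   nonincreasing), `center` (mean spectrum), `labels`.
#' @export
fit_pca <- function(spectra, n_components, labels = NULL) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  if (n_components < 1) stop("n_components must be >= 1")
  if (n <= n_components)
    stop("need more spectra than components")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per spectrum")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  k <- n_components
  V <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  scores <- Xc %*% V
  ev <- sv$d^2 / max(n - 1, 1)
  total <- sum(ev)
  explained <- if (total > 0) ev[seq_len(k)] / total else rep(0, k)
  structure(list(scores = scores, loadings = t(V), explained = explained,
                 center = mu, labels = labels),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d spectra, %d components; explained: %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Cohort separation on the first principal component
#'
#' Standardised mean difference of PC1 scores between two cohorts:
#' `|mean_a - mean_b| / pooled SD`. Symmetric in its arguments.
#'
#' @param result a [fit_pca()] result carrying labels.
#' @param label_a,label_b cohort labels to compare.
#' @return Scalar separation statistic.
#' @export
cohort_separation <- function(result, label_a, label_b) {
  stopifnot(inherits(result, "pca_result"))
  if (is.null(result$labels)) stop("PCA result carries no cohort labels")
  a <- result$scores[result$labels == label_a, 1]
  b <- result$scores[result$labels == label_b, 1]
  if (length(a) < 2 || length(b) < 2)
    stop("both cohorts need at least 2 members")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(if (mean(a) == mean(b)) 0 else Inf)
  abs(mean(a) - mean(b)) / sp
}
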