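# PCA feature extraction and PCA-combined similarity metrics.
#
# For 2D images the rows of the image are the sample vectors; a basis is
# fit on the fixed image's rows and both images are projected onto it, so
# the two score matrices live in the same coordinates.  Metrics (SSD,
# Pearson, Spearman, Kendall) are then computed between the flattened
# score matrices.  For 3D volumes PCA is applied slice-wise along each
# axis and the per-slice score matrices are summed (triplanar reduction).

#' Correlation between two vectors
#'
#' Pearson is the product-moment coefficient, Spearman is Pearson on
#' average ranks, Kendall is tau-a: (concordant - discordant) / (n(n-1)/2),
#' with no tie correction (metric inputs here are continuous).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param kind `"pearson"`, `"spearman"` or `"kendall"`.
#' @return value in \[-1, 1\].
#' @export
correlation <- function(x, y, kind = c("pearson", "spearman", "kendall")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (kind == "kendall") return(cpp_kendall_tau_a(x, y))
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: ", kind, " correlation undefined")
  if (kind == "pearson") cor(x, y) else cor(x, y, method = "spearman")
}

#' Fit a PCA basis
#'
#' Mean-centered principal directions by descending explained variance.
#' Component signs are fixed so the largest-magnitude loading is positive.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of components, `k <= min(nrow(X), ncol(X))`.
#' @return list of class `pca_basis` with `mean`, `components`
#'   (d x k, orthonormal columns) and `var_explained` (fractions).
#' @export
pca_fit <- function(X, k) {
  if (!is.matrix(X) || nrow(X) < 2) stop("need at least 2 sample vectors")
  kmax <- min(nrow(X), ncol(X))
  if (k > kmax) stop("k exceeds min(n_samples, dim)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = kmax)
  var_all <- sv$d[seq_len(kmax)]^2
  frac <- if (sum(var_all) > 0) var_all / sum(var_all) else var_all
  comp <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp,
                 var_explained = frac[seq_len(k)], var_all = frac),
            class = "pca_basis")
}

#' Project samples onto a PCA basis
#' @param basis a [pca_fit()] result.
#' @param X matrix, samples in rows (same dimension as the fit).
#' @return score matrix (n x k).
#' @export
pca_project <- function(basis, X) {
  sweep(X, 2, basis$mean) %*% basis$components
}

# number of leading components covering `target` of the variance, capped
pca_k_rule <- function(frac, target = 0.95, cap = 32L) {
  k <- which(cumsum(frac) >= target)[1]
  if (is.na(k)) k <- length(frac)
  min(k, cap, length(frac))
}

.metric_base <- function(kind) sub("^pca-", "", kind)

metric_from_vectors <- function(x, y, kind) {
  base <- .metric_base(kind)
  if (base == "ssd") sum((x - y)^2) else correlation(x, y, base)
}

#' PCA-combined similarity between two 2D images
#'
#' Fits a basis on the fixed image's rows and projects both images onto
#' it, each image centered by its *own* row mean — the shared basis keeps
#' the score coordinates comparable while own-mean centering makes the
#' features invariant to constant intensity offsets (the bias robustness
#' PCA features are used for).  The requested metric is computed between
#' the flattened score matrices.
#'
#' @param f,m images on the same grid.
#' @param kind metric: `"ssd"`, `"pearson"`, `"spearman"` or `"kendall"`
#'   (a `"pca-"` prefix is accepted and ignored).
#' @param k number of components; default: enough to explain 95% of `f`'s
#'   row variance, capped at 32.
#' @return scalar metric value.
#' @export
pca_similarity_2d <- function(f, m, kind = "ssd", k = NULL) {
  if (!identical(dim(f), dim(m))) stop("image shape mismatch")
  full <- pca_fit(f, min(nrow(f), ncol(f)))
  if (is.null(k)) k <- pca_k_rule(full$var_all)
  comp <- full$components[, seq_len(k), drop = FALSE]
  sf <- sweep(f, 2, colMeans(f)) %*% comp
  sm <- sweep(m, 2, colMeans(m)) %*% comp
  metric_from_vectors(as.vector(sf), as.vector(sm), kind)
}

# slice-wise PCA scores along one axis, summed over slices; as in the 2D
# metric, the basis is shared (fit on the fixed slice) and each slice is
# centered by its own row mean
triplanar_axis_scores <- function(f3, m3, axis, k) {
  n <- dim(f3)[axis]
  slice_of <- function(a, i) switch(axis, a[i, , ], a[, i, ], a[, , i])
  mid <- slice_of(f3, max(1L, n %/% 2L))
  full <- pca_fit(mid, min(dim(mid)))
  if (is.null(k)) k <- pca_k_rule(full$var_all, cap = 8L)
  k <- min(k, min(dim(mid)))
  sf <- 0; sm <- 0
  for (i in seq_len(n)) {
    fs <- slice_of(f3, i)
    ms <- slice_of(m3, i)
    comp <- pca_fit(fs, k)$components
    sf <- sf + sweep(fs, 2, colMeans(fs)) %*% comp
    sm <- sm + sweep(ms, 2, colMeans(ms)) %*% comp
  }
  list(f = sf, m = sm)
}

#' PCA-combined similarity between two 3D volumes (triplanar)
#'
#' For each axis, PCA is fit on every fixed-image slice perpendicular to
#' that axis, both volumes' slices are projected, and score matrices are
#' summed over slices.  The metric compares the concatenation of the three
#' per-axis summaries.
#'
#' @param f,m 3D arrays with identical dims.
#' @param kind metric name as in [pca_similarity_2d()].
#' @param k components per slice (default: 95% rule on a central slice,
#'   capped at 8).
#' @return scalar metric value.
#' @export
pca_similarity_3d <- function(f, m, kind = "ssd", k = NULL) {
  if (!identical(dim(f), dim(m))) stop("volume dims mismatch")
  xs <- lapply(1:3, function(a) triplanar_axis_scores(f, m, a, k))
  vf <- unlist(lapply(xs, function(s) as.vector(s$f)))
  vm <- unlist(lapply(xs, function(s) as.vector(s$m)))
  metric_from_vectors(vf, vm, kind)
}

#' Similarity metric dispatcher
#'
#' Computes any supported metric between two images or volumes: plain
#' metrics on flattened intensities, `pca-*` metrics through the PCA
#' projection route.
#'
#' @param f,m images (matrices) or volumes (3D arrays) of identical shape.
#' @param kind one of `"ssd"`, `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"pca-ssd"`, `"pca-pearson"`, `"pca-spearman"`, `"pca-kendall"`.
#' @param k PCA components (see [pca_similarity_2d()]).
#' @return scalar metric value.
#' @export
similarity_metric <- function(f, m, kind = "ssd", k = NULL) {
  kinds <- c("ssd", "pearson", "spearman", "kendall",
             "pca-ssd", "pca-pearson", "pca-spearman", "pca-kendall")
  if (!kind %in% kinds) stop("unknown metric: ", kind)
  if (grepl("^pca-", kind)) {
    if (length(dim(f)) == 3) pca_similarity_3d(f, m, kind, k)
    else pca_similarity_2d(f, m, kind, k)
  } else if (kind == "ssd") {
    ssd(f, m)
  } else {
    correlation(as.vector(f), as.vector(m), kind)
  }
}
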