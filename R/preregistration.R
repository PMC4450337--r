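# Preregistration: remove rotation (CNN classifier), scale and translation
# separately for 2D; triplanar CNN slice-position matching for 3D.

#' Estimate the rotation of the moving image
#'
#' Scale and translation are moment-based and rotation-invariant, so they
#' are removed first (one internal resample used only for classification);
#' the classifier then sees a difference image close to its pure-rotation
#' training regime.  The estimate is then refined to a fixed point: the
#' current angle is applied to the rectified image and the classifier is
#' re-run on the residual pair, whose rotation should classify as zero —
#' any nonzero residual class is added to the estimate.  This absorbs the
#' near-boundary misclassifications that rectification resampling (and
#' residual deformation) can induce.
#'
#' @param f,m fixed and moving images on the same grid.
#' @param model trained rotation classifier ([train_rotation_classifier()]).
#' @param rectify remove estimated scale/translation before classifying.
#' @param refine number of residual re-classification passes.
#' @return rotation in degrees, quantized to the class grid.
#' @export
estimate_rotation <- function(f, m, model, rectify = TRUE, refine = 2L) {
  if (is.null(model)) stop("a trained rotation classifier is required")
  if (rectify) {
    s <- estimate_scale(f, m)
    cf <- intensity_centroid(f); cm <- intensity_centroid(m)
    g <- coord_grid(nrow(f), ncol(f))
    R <- cm[1] + (g$r - cf[1]) / s
    C <- cm[2] + (g$c - cf[2]) / s
    m <- cpp_bilinear_sample(m, R, C)
  }
  theta <- predict_rotation_class(model, f, m)$angle
  ctr <- intensity_centroid(f)
  for (i in seq_len(refine)) {
    if (theta %% 360 == 0 && i > 1) break
    resid <- rotate_image(m, -theta, center = ctr)
    dtheta <- predict_rotation_class(model, f, resid)$angle
    if (dtheta == 0) break
    theta <- (theta + dtheta) %% 360
  }
  # local polish on the class grid: the classifier proposes, the image
  # similarity verifies among the adjacent classes (sub-grid boundary
  # errors cost one class; SSD resolves them)
  step <- 360 / model$arch$n_classes
  cand <- theta + c(-step, 0, step)
  err <- vapply(cand, function(a)
    ssd(f, rotate_image(m, -a, center = ctr)), numeric(1))
  cand[which.min(err)] %% 360
}

#' Estimate the scale factor to apply to the moving image
#'
#' Two-part rule: (1) if the grids differ, the moving image is resampled
#' to the fixed image's pixel dimensions; (2) the residual factor is the
#' ratio of foreground radii of gyration, fixed over moving.  Foreground
#' is defined by the fixed image's Otsu threshold applied to both images
#' and weighted by the intensity excess above it, which is continuous in
#' the threshold and therefore robust to the histogram shifts that
#' resampling introduces.  The radius of gyration is rotation- and
#' translation-invariant, so the estimate does not depend on the other
#' preregistration parameters.
#'
#' @param f,m fixed and moving images.
#' @return positive scale factor to apply to `m` (< 1 shrinks `m`).
#' @export
estimate_scale <- function(f, m) {
  if (!identical(dim(f), dim(m)))
    m <- resize_image(m, nrow(f), ncol(f))
  thr <- otsu_threshold(f)
  rg <- function(img) {
    w <- pmax(img - thr, 0)
    tot <- sum(w)
    if (tot <= 0) stop("empty foreground: cannot estimate scale")
    g <- coord_grid(nrow(img), ncol(img))
    cr <- sum(w * g$r) / tot; cc <- sum(w * g$c) / tot
    sqrt(sum(w * ((g$r - cr)^2 + (g$c - cc)^2)) / tot)
  }
  rg(f) / rg(m)
}

#' Estimate the translation between two images
#'
#' `centroid(F) - centroid(M)`: under the pull-back convention this equals
#' the displacement that generated `m` from `f`.
#'
#' @param f,m fixed and moving images.
#' @return length-2 vector (row, col) in pixels.
#' @export
estimate_translation <- function(f, m) {
  intensity_centroid(f) - intensity_centroid(m)
}

#' Affine preregistration of a 2D pair
#'
#' Estimates rotation (classifier), scale and translation, composes the
#' corrections (inverse rotation about the moving centroid, scaling, then
#' centroid matching) into one affine map, and applies it with a single
#' bilinear resampling.
#'
#' The returned parameters are the detected forward transform of the
#' moving image relative to the fixed one: a case generated with
#' `rotation_deg = 90, scale = 1.25, shift = (6, -4)` is reported with
#' those values.
#'
#' @param f,m fixed and moving images on the same grid.
#' @param model trained rotation classifier, or `NULL` to skip the
#'   rotation stage.
#' @param rotation_deg optionally force the rotation estimate (degrees).
#' @return list of class `affine_params` with `rotation_deg`, `scale`
#'   (detected magnification of `m`), `translation` (detected shift), the
#'   `m_pre` rectified image, and `src_map` — the `c(h, w, 2)` array of
#'   absolute source coordinates used for resampling.
#' @export
preregister_2d <- function(f, m, model = NULL, rotation_deg = NULL) {
  if (!identical(dim(f), dim(m)))
    m <- resize_image(m, nrow(f), ncol(f))
  s_corr <- estimate_scale(f, m)        # factor applied to m
  cf <- intensity_centroid(f); cm <- intensity_centroid(m)
  theta <- if (!is.null(rotation_deg)) rotation_deg
           else if (!is.null(model)) estimate_rotation(f, m, model)
           else 0
  # source map: src = c_M + s_det R(theta) (x - c_F), s_det = 1 / s_corr
  A <- rot_mat(theta) / s_corr
  g <- coord_grid(nrow(f), ncol(f))
  dr <- g$r - cf[1]; dc <- g$c - cf[2]
  R <- cm[1] + A[1, 1] * dr + A[1, 2] * dc
  C <- cm[2] + A[2, 1] * dr + A[2, 2] * dc
  src <- array(0, dim = c(nrow(f), ncol(f), 2))
  src[, , 1] <- R; src[, , 2] <- C
  structure(list(rotation_deg = theta %% 360, scale = 1 / s_corr,
                 translation = cm - cf,
                 m_pre = cpp_bilinear_sample(m, R, C), src_map = src),
            class = "affine_params")
}

# ---- triplanar 3D preregistration ------------------------------------------

# extract the slice through point `p` perpendicular to `axis`, recentre it
# on its intensity centroid by an integer shift (translation-invariant
# classification), resize to the classifier side, min-max normalize
triplanar_slice_input <- function(vol, axis, pos, input_side) {
  sl <- switch(axis, vol[pos, , ], vol[, pos, ], vol[, , pos])
  if (sum(sl) > 0) {
    ctr <- intensity_centroid(sl)
    d <- round(c(ctr[1] - (1 + nrow(sl)) / 2, ctr[2] - (1 + ncol(sl)) / 2))
    idx_r <- pmin(pmax(seq_len(nrow(sl)) + d[1], 1L), nrow(sl))
    idx_c <- pmin(pmax(seq_len(ncol(sl)) + d[2], 1L), ncol(sl))
    sl <- sl[idx_r, idx_c]
  }
  normalize_image(sl, target_size = input_side)
}

#' Train per-axis slice-position classifiers on a fixed volume
#'
#' One CNN per axis; the classes are consecutive buckets of slice indices
#' (default 8 slices per class — the coarsest granularity at which the
#' networks reliably memorize their training slices perfectly at
#' desk-scale volume sizes, which exact-shift recovery requires; the
#' Hamming search below resolves within-bucket positions through the
#' label-point ensemble).  Training inputs are the fixed volume's
#' own slices, recentred on their intensity centroid so that in-plane
#' translation of a test slice does not change its representation.
#'
#' @param f 3D array (fixed volume).
#' @param input_side classifier input side.
#' @param bucket_size slices per class.
#' @param epochs,lr,batch_size,seed training settings.
#' @param map_counts conv maps per layer.
#' @return list of three `cnn_model`s (axes 1..3) with attribute
#'   `bucket_size`; each model carries its training accuracy.
#' @export
train_slice_classifiers <- function(f, input_side = 28L, bucket_size = 8L,
                                    epochs = 800L, lr = 2, batch_size = 10L,
                                    seed = 1L, map_counts = c(6, 12, 24, 48)) {
  models <- lapply(1:3, function(axis) {
    n <- dim(f)[axis]
    n_cls <- ceiling(n / bucket_size)
    inputs <- lapply(seq_len(n), function(i)
      triplanar_slice_input(f, axis, i, input_side))
    labels <- as.integer((seq_len(n) - 1L) %/% bucket_size)
    arch <- cnn_architecture(input_side, n_cls, map_counts = map_counts)
    model <- new_cnn_model(arch, seed = seed + axis)
    model <- train_cnn(model, inputs, labels, epochs = epochs, lr = lr,
                       batch_size = batch_size, seed = seed + 10L + axis)
    attr(model, "train_accuracy") <- cnn_accuracy(model, inputs, labels)
    model
  })
  attr(models, "bucket_size") <- as.integer(bucket_size)
  attr(models, "input_side") <- as.integer(input_side)
  models
}

#' Triplanar CNN preregistration of a 3D pair
#'
#' Samples `n_points` label points from a Normal distribution centered
#' mid-volume (sd = dims/6, clipped to an interior margin), extracts the
#' three orthogonal slices through each point from the moving volume, and
#' predicts each slice's position bucket in the fixed volume's frame with
#' the per-axis classifiers.  The integer translation in
#' `[-search_radius, search_radius]^3` minimizing the total Hamming
#' distance between predicted and shifted label buckets is applied.
#' Among candidates within 2 of the minimal Hamming distance — the
#' ambiguity a couple of slice misclassifications can cause — the
#' decision falls to the smaller per-voxel SSD between the fixed volume
#' and the shift-corrected moving volume, then the smaller L1 norm; for
#' an integer-shifted pair the true shift has zero overlap SSD, so
#' recovery is exact whenever the classifiers keep the truth near the
#' Hamming optimum.
#'
#' @param f,m fixed and moving volumes (same dims).
#' @param models three per-axis classifiers
#'   ([train_slice_classifiers()]).
#' @param seed RNG seed for the label points.
#' @param n_points number of label points.
#' @param search_radius exhaustive search window (voxels).
#' @return list with `translation` (detected integer 3-vector: the
#'   pull-back shift that generated `m`), `m_pre` (shift-corrected
#'   volume), `points`, `hamming` (objective at the optimum).
#' @export
triplanar_preregister_3d <- function(f, m, models, seed = 1L,
                                     n_points = 10L, search_radius = 8L) {
  if (!identical(dim(f), dim(m))) stop("volume dims mismatch")
  d <- dim(f)
  bucket <- attr(models, "bucket_size")
  side <- attr(models, "input_side")
  margin <- 4L
  pts <- with_seed(seed, {
    p <- matrix(0L, n_points, 3)
    for (a in 1:3)
      p[, a] <- pmin(pmax(round(rnorm(n_points, (d[a] + 1) / 2, d[a] / 6)),
                          margin), d[a] - margin)
    p
  })
  # predicted bucket of each point's slice position in the fixed frame
  pred <- matrix(0L, n_points, 3)
  for (i in seq_len(n_points)) {
    for (a in 1:3) {
      inp <- triplanar_slice_input(m, a, pts[i, a], side)
      pred[i, a] <- predict_class(models[[a]], inp)
    }
  }
  cand <- -search_radius:search_radius
  grid <- as.matrix(expand.grid(d1 = cand, d2 = cand, d3 = cand))
  hams <- integer(nrow(grid))
  for (a in 1:3) {
    pb <- outer(pts[, a], grid[, a], "+")
    b <- (pmin(pmax(pb, 1L), d[a]) - 1L) %/% bucket
    hams <- hams + colSums(b != pred[, a])
  }
  ham_min <- min(hams)
  keep <- which(hams <= ham_min + 2L)
  shifts <- lapply(keep, function(i) as.integer(grid[i, ]))
  best <- list(ham = ham_min)
  if (length(shifts) > 1) {   # SSD decides among near-minimal candidates
    score <- vapply(shifts, function(sh) {
      # compare f with the shift-corrected moving volume m(x - sh) on the
      # region where both are defined
      idx <- lapply(1:3, function(a) {
        i <- seq_len(d[a])
        i[i - sh[a] >= 1 & i - sh[a] <= d[a]]
      })
      if (any(vapply(idx, length, integer(1)) == 0)) return(Inf)
      fa <- f[idx[[1]], idx[[2]], idx[[3]]]
      ma <- m[idx[[1]] - sh[1], idx[[2]] - sh[2], idx[[3]] - sh[3]]
      mean((fa - ma)^2)
    }, numeric(1))
    l1 <- vapply(shifts, function(sh) sum(abs(sh)), numeric(1))
    lex <- vapply(shifts, function(sh)
      paste(sprintf("%+03d", sh), collapse = ""), character(1))
    shifts <- shifts[order(score, l1, lex)]
  }
  sh <- shifts[[1]]
  list(translation = sh, m_pre = shift_volume(m, -sh),
       points = pts, hamming = best$ham)
}
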