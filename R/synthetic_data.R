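# Phantom and deformation-case generators with known ground truth.
#
# Every generator is a pure function of its arguments including the seed
# (the caller's RNG stream is untouched).  Moving images are built by
# applying the stated transforms to the fixed image, so recovery errors
# measured elsewhere are attributable to the estimators.

gauss2d <- function(g, cr, cc, sr, sc, theta = 0) {
  dr <- g$r - cr; dc <- g$c - cc
  ct <- cos(theta); st <- sin(theta)
  a <- ct * dr + st * dc; b <- -st * dr + ct * dc
  exp(-(a^2 / (2 * sr^2) + b^2 / (2 * sc^2)))
}

#' Generate a rotation-asymmetric grayscale phantom
#'
#' Four families are provided: `blobs` (anisotropic Gaussian mixtures),
#' `rings` (off-center rings with a wedge), `bars` (oriented bars), and
#' `brainlike` (an ellipse with internal ventricle-like structures).  All
#' are normalized to \[0, 1\], mildly smoothed, and asymmetric under 90
#' degree rotation so rotation classes are separable.
#'
#' @param kind phantom family.
#' @param side image side (>= 32).
#' @param seed RNG seed.
#' @return `side x side` matrix in \[0, 1\].
#' @export
make_phantom <- function(kind = c("blobs", "rings", "bars", "brainlike"),
                         side = 128L, seed = 1L) {
  kind <- match.arg(kind)
  if (side < 32) stop("side must be >= 32")
  g <- coord_grid(side, side)
  ctr <- (1 + side) / 2
  img <- with_seed(seed, {
    base <- matrix(0, side, side)
    # structures are kept compact (about 2/3 of the frame) so that the
    # scale/translation ranges exercised in registration cases keep the
    # object, including its smooth tails, inside the field of view
    if (kind == "blobs") {
      for (i in 1:6) {
        base <- base + runif(1, 0.6, 1) *
          gauss2d(g, ctr + runif(1, -0.17, 0.17) * side,
                  ctr + runif(1, -0.17, 0.17) * side,
                  runif(1, 0.03, 0.08) * side, runif(1, 0.03, 0.08) * side,
                  runif(1, 0, pi))
      }
      # fixed anisotropic off-center anchor: guarantees every draw clears
      # the 90-degree asymmetry floor regardless of the random layout
      base <- base + 1.3 * gauss2d(g, ctr + 0.12 * side, ctr + 0.05 * side,
                                   0.02 * side, 0.08 * side, 0)
      # soft intensity saturation: keeps stacked mixtures from dominating
      # the min-max normalization and washing out off-peak contrast
      base <- tanh(base)
    } else if (kind == "rings") {
      cr <- ctr + runif(1, -0.05, 0.05) * side
      cc <- ctr + runif(1, -0.05, 0.05) * side
      rad <- sqrt((g$r - cr)^2 + (g$c - cc)^2)
      for (r0 in runif(3, 0.07, 0.24) * side)
        base <- base + exp(-(rad - r0)^2 / (2 * (0.015 * side)^2))
      ang <- atan2(g$c - cc, g$r - cr)
      a0 <- runif(1, -pi, pi)
      wedge <- exp(-((ang - a0 + pi) %% (2 * pi) - pi)^2 / (2 * 0.35^2))
      base <- base + wedge * exp(-(rad - 0.16 * side)^2 / (2 * (0.07 * side)^2))
    } else if (kind == "bars") {
      for (i in 1:5) {
        base <- base + runif(1, 0.65, 1) *
          gauss2d(g, ctr + runif(1, -0.16, 0.16) * side,
                  ctr + runif(1, -0.16, 0.16) * side,
                  runif(1, 0.015, 0.035) * side, runif(1, 0.1, 0.2) * side,
                  runif(1, 0, pi))
      }
      # fixed axis-aligned anchor bar (see blobs)
      base <- base + gauss2d(g, ctr - 0.11 * side, ctr + 0.09 * side,
                             0.015 * side, 0.11 * side, 0)
    } else {
      # brainlike: one canonical "anatomy" (outer ellipse, two dark
      # ventricles, two bright nuclei) with small subject-to-subject
      # jitter, emulating a homogeneous family of anatomical models
      # jitter amplitudes are set so that rotation difference images are
      # nearest-neighbour separable by angle across subjects, the regime
      # of a homogeneous anatomical-model family
      j <- function(s) runif(1, -s, s) * side
      base <- 0.9 * gauss2d(g, ctr + j(0.0035), ctr + j(0.0035),
                            (0.21 + runif(1, -0.005, 0.005)) * side,
                            (0.135 + runif(1, -0.005, 0.005)) * side, 0.15)
      base <- base - 0.55 * gauss2d(g, ctr - 0.027 * side + j(0.0035),
                                    ctr - 0.034 * side + j(0.0035),
                                    0.06 * side, 0.024 * side,
                                    -0.4 + runif(1, -0.035, 0.035))
      base <- base - 0.55 * gauss2d(g, ctr - 0.027 * side + j(0.0035),
                                    ctr + 0.04 * side + j(0.0035),
                                    0.06 * side, 0.024 * side,
                                    0.4 + runif(1, -0.035, 0.035))
      base <- base + runif(1, 0.528, 0.572) *
        gauss2d(g, ctr + 0.107 * side + j(0.005), ctr + j(0.005),
                0.034 * side, 0.054 * side, runif(1, -0.1, 0.1))
      base <- base + runif(1, 0.433, 0.467) *
        gauss2d(g, ctr - 0.12 * side + j(0.005), ctr + 0.027 * side + j(0.005),
                0.027 * side, 0.027 * side, 0)
    }
    base
  })
  # remove the slow Gaussian-tail halo so phantoms have compact support
  # (a nonzero background floor would bias intensity moments)
  img <- pmax(img - 0.08 * max(img), 0)
  img <- gaussian_smooth_image(img, side / 128)
  normalize_image(img)
}

#' Generate a smooth random diffeomorphic warp
#'
#' Gaussian-smoothed white-noise velocity rescaled so its largest vector
#' equals `amplitude`, returned together with its exponential.
#'
#' @param side grid side.
#' @param amplitude maximum velocity magnitude (px).
#' @param smoothness Gaussian width (px) of the velocity field.
#' @param seed RNG seed.
#' @return list with `v` (velocity) and `disp` (`exp(v)`), both
#'   `c(side, side, 2)` arrays.
#' @export
make_smooth_warp <- function(side = 128L, amplitude = 5, smoothness = 8,
                             seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  v <- zero_field(side, side)
  if (amplitude > 0) {
    v <- with_seed(seed, {
      raw <- array(rnorm(side * side * 2), dim = c(side, side, 2))
      raw
    })
    v <- gaussian_regularize(v, smoothness)
    mx <- sqrt(max(v[, , 1]^2 + v[, , 2]^2))
    if (mx > 0) v <- v * (amplitude / mx)
  }
  list(v = v, disp = exponential_map(v))
}

#' Generate a registration case with known ground truth
#'
#' The moving image is the fixed image under, in order: rotation by
#' `rotation_deg` and magnification by `scale` about the fixed image's
#' intensity centroid, a translation by `shift` (pull-back convention, as
#' in [warp_image()]), and finally a smooth diffeomorphic warp of the
#' given amplitude.  The composition order matches the model
#' [preregister_2d()] inverts, and all truths are recorded.
#'
#' @param side image side.
#' @param rotation_deg true rotation (degrees); `snap_classes` optionally
#'   snaps it to the class grid.
#' @param scale true magnification of the moving image (> 0).
#' @param shift length-2 true translation (pixels, row/col).
#' @param warp_amplitude maximum warp displacement (px; 0 disables).
#' @param seed RNG seed (phantom and warp).
#' @param kind phantom family, or pass `fixed` to supply a base image.
#' @param fixed optional fixed image (overrides `kind`).
#' @param snap_classes if non-`NULL`, snap `rotation_deg` to the grid of
#'   this many classes.
#' @param warp_smoothness Gaussian width of the warp (px).
#' @return list of class `synthetic_case`: `fixed`, `moving`, `truth`
#'   (rotation_deg, scale, shift, warp `v`/`disp`), `seed`.
#' @export
make_registration_case <- function(side = 128L, rotation_deg = 0,
                                   scale = 1, shift = c(0, 0),
                                   warp_amplitude = 0, seed = 1L,
                                   kind = "blobs", fixed = NULL,
                                   snap_classes = NULL,
                                   warp_smoothness = 8) {
  if (scale <= 0) stop("scale must be positive")
  if (!is.null(snap_classes))
    rotation_deg <- (round(rotation_deg / (360 / snap_classes)) *
                       (360 / snap_classes)) %% 360
  if (is.null(fixed)) fixed <- make_phantom(kind, side, seed)
  ctr <- intensity_centroid(fixed)
  # single-resample affine: src = c + R(-theta) ((x - c - t) / s), i.e.
  # content rotated by +theta (the rotate_image convention), magnified by
  # s, moved by t
  A <- rot_mat(-rotation_deg) / scale
  g <- coord_grid(nrow(fixed), ncol(fixed))
  dr <- g$r - ctr[1] - shift[1]; dc <- g$c - ctr[2] - shift[2]
  R <- ctr[1] + A[1, 1] * dr + A[1, 2] * dc
  C <- ctr[2] + A[2, 1] * dr + A[2, 2] * dc
  moving <- cpp_bilinear_sample(fixed, R, C)
  w <- make_smooth_warp(nrow(fixed), warp_amplitude, warp_smoothness,
                        seed + 104729L)
  if (warp_amplitude > 0) moving <- warp_image(moving, w$disp)
  structure(list(fixed = fixed, moving = moving,
                 truth = list(rotation_deg = rotation_deg, scale = scale,
                              shift = shift, v = w$v, disp = w$disp),
                 seed = seed),
            class = "synthetic_case")
}

#' Build a labeled rotation dataset from base images
#'
#' For every base and every class angle `theta` on the grid, the sample is
#' the normalized difference image `diff(F, F o r_theta)` labeled with the
#' class index.  Samples are shuffled under the seed and split 80/20 into
#' train / held-out sets.
#'
#' @param bases list of base images.
#' @param n_classes rotation classes (divides 360).
#' @param input_side classifier input side.
#' @param seed RNG seed for the shuffle.
#' @return list with `train` and `test`, each `list(inputs, labels)`
#'   (labels 0-based).
#' @export
make_rotation_dataset <- function(bases, n_classes = 36L, input_side = 28L,
                                  seed = 1L) {
  if (length(bases) < 1) stop("need at least one base image")
  step <- 360 / n_classes
  inputs <- list(); labels <- integer(0)
  for (b in bases) {
    for (k in seq_len(n_classes) - 1L) {
      m <- if (k == 0) b else rotate_image(b, k * step)
      inputs[[length(inputs) + 1L]] <- make_difference_input(b, m, input_side)
      labels <- c(labels, k)
    }
  }
  n <- length(inputs)
  ord <- with_seed(seed, sample.int(n))
  n_train <- max(1L, floor(0.8 * n))
  tr <- ord[seq_len(n_train)]
  te <- if (n_train < n) ord[(n_train + 1):n] else integer(0)
  list(train = list(inputs = inputs[tr], labels = labels[tr]),
       test = list(inputs = inputs[te], labels = labels[te]))
}

gauss3d <- function(dims, c1, c2, c3, s1, s2, s3) {
  d1 <- (seq_len(dims[1]) - c1) / s1
  d2 <- (seq_len(dims[2]) - c2) / s2
  d3 <- (seq_len(dims[3]) - c3) / s3
  e1 <- exp(-d1^2 / 2); e2 <- exp(-d2^2 / 2); e3 <- exp(-d3^2 / 2)
  outer(outer(e1, e2), e3)
}

#' Generate a smooth asymmetric 3D phantom
#'
#' A composite of anisotropic 3D Gaussian blobs in \[0, 1\]; adjacent
#' slices along every axis differ, so slice-position classes are
#' learnable.
#'
#' @param dims three positive integers (>= 32 each).
#' @param seed RNG seed.
#' @return 3D array in \[0, 1\].
#' @export
make_3d_phantom <- function(dims = c(64L, 64L, 64L), seed = 1L) {
  if (any(dims < 32)) stop("each dim must be >= 32")
  vol <- with_seed(seed, {
    v <- array(0, dim = dims)
    for (i in 1:8) {
      v <- v + runif(1, 0.4, 1) * gauss3d(
        dims,
        dims[1] * runif(1, 0.3, 0.7), dims[2] * runif(1, 0.3, 0.7),
        dims[3] * runif(1, 0.3, 0.7),
        dims[1] * runif(1, 0.05, 0.16), dims[2] * runif(1, 0.05, 0.16),
        dims[3] * runif(1, 0.05, 0.16))
    }
    v
  })
  vol <- vol - min(vol)
  if (max(vol) > 0) vol <- vol / max(vol)
  vol
}

#' Integer-shift a 3D volume (pull-back, clamped edges)
#'
#' `out[x] = vol[x + shift]` with indices clamped to the volume bounds.
#'
#' @param vol 3D array.
#' @param shift integer 3-vector.
#' @return shifted volume.
#' @export
shift_volume <- function(vol, shift) {
  d <- dim(vol)
  idx <- lapply(1:3, function(a)
    pmin(pmax(seq_len(d[a]) + shift[a], 1L), d[a]))
  vol[idx[[1]], idx[[2]], idx[[3]]]
}
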