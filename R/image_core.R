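# Image containers and shared primitives.
#
# Images are plain numeric matrices (2D, indexed [row, col]) or 3D arrays,
# normalized to [0, 1].  Pixel centers sit at integer coordinates, 1-based in
# R.  Displacement fields are arrays of dim c(h, w, 2) with [,,1] the row
# component and [,,2] the column component, used in pull-back convention:
# a warped image samples the source at x + disp(x).

coord_grid <- function(h, w) {
  list(r = matrix(seq_len(h), h, w), c = matrix(seq_len(w), h, w, byrow = TRUE))
}

zero_field <- function(h, w) array(0, dim = c(h, w, 2))

stopifnot_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix image")
  if (nrow(img) < 2 || ncol(img) < 2)
    stop("image must be at least 2x2")
  if (any(!is.finite(img)))
    stop("image contains non-finite intensities")
  invisible(img)
}

#' Min-max normalize an intensity grid to \[0, 1\]
#'
#' Rescales `(x - min) / (max - min)` elementwise.  A constant grid carries
#' no registration signal and maps to all zeros rather than dividing by
#' zero.  Optionally resizes to a square target side with bilinear
#' interpolation (classifier inputs are normalized to a fixed side this
#' way).
#'
#' @param raw numeric matrix of finite intensities.
#' @param target_size optional integer side; when given the result is
#'   resized to `target_size x target_size`.
#' @return numeric matrix with values in \[0, 1\].
#' @export
normalize_image <- function(raw, target_size = NULL) {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("expected a numeric matrix")
  if (length(raw) < 1) stop("empty image")
  if (any(!is.finite(raw))) stop("non-finite intensities in input")
  rng <- range(raw)
  img <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
         else matrix(0, nrow(raw), ncol(raw))
  if (!is.null(target_size))
    img <- pmin(pmax(resize_image(img, target_size, target_size), 0), 1)
  img
}

#' Resize an image with bilinear interpolation
#'
#' Align-corners mapping: output pixel centers span the same extent as the
#' input's.
#'
#' @param img numeric matrix.
#' @param height,width output dimensions (>= 1).
#' @return resized matrix.
#' @export
resize_image <- function(img, height, width) {
  stopifnot_image(img)
  h <- nrow(img); w <- ncol(img)
  rr <- if (height > 1) 1 + (seq_len(height) - 1) * (h - 1) / (height - 1)
        else rep((1 + h) / 2, height)
  cc <- if (width > 1) 1 + (seq_len(width) - 1) * (w - 1) / (width - 1)
        else rep((1 + w) / 2, width)
  R <- matrix(rr, height, width)
  C <- matrix(cc, height, width, byrow = TRUE)
  cpp_bilinear_sample(img, R, C)
}

#' Warp an image by a displacement field
#'
#' Pull-back sampling: `out(x) = img(x + disp(x))`.  Samples falling outside
#' the domain take the clamped edge value.
#'
#' @param img numeric matrix.
#' @param disp displacement array `c(h, w, 2)` (row, col components, pixels).
#' @param mode `"bilinear"` or `"nearest"`.
#' @return warped matrix, same shape as `img`.
#' @export
warp_image <- function(img, disp, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot_image(img)
  if (!identical(dim(disp), c(nrow(img), ncol(img), 2L)) &&
      !identical(dim(disp), c(nrow(img), ncol(img), 2)))
    stop("displacement field shape does not match image")
  g <- coord_grid(nrow(img), ncol(img))
  R <- g$r + disp[, , 1]
  C <- g$c + disp[, , 2]
  if (mode == "bilinear") cpp_bilinear_sample(img, R, C)
  else cpp_nearest_sample(img, R, C)
}

#' Sample an image under an affine map
#'
#' Output pixel `x` (row, col) samples the source at
#' `src = center_out + A %*% (x - center_out) + offset` — i.e. `A` acts about
#' `center_out` and `offset` shifts the source position.  Used to apply
#' rotations, scalings and their compositions with a single interpolation.
#'
#' @param img numeric matrix.
#' @param A 2x2 matrix acting on (row, col) offsets.
#' @param center point about which `A` acts (default image center).
#' @param offset length-2 source shift (pixels).
#' @param mode interpolation mode.
#' @return resampled matrix.
#' @export
affine_warp <- function(img, A, center = NULL, offset = c(0, 0),
                        mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot_image(img)
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((1 + h) / 2, (1 + w) / 2)
  g <- coord_grid(h, w)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  R <- center[1] + A[1, 1] * dr + A[1, 2] * dc + offset[1]
  C <- center[2] + A[2, 1] * dr + A[2, 2] * dc + offset[2]
  if (mode == "bilinear") cpp_bilinear_sample(img, R, C)
  else cpp_nearest_sample(img, R, C)
}

#' Rotation matrix acting on (row, col) offsets
#'
#' `rot_mat(theta)` maps content by `theta` degrees when used as the source
#' map of [affine_warp()]: `rotate_image(img, deg)` rotates image content by
#' `deg` degrees about the chosen center.
#' @param degrees angle in degrees.
#' @return 2x2 matrix.
#' @export
rot_mat <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Rotate an image about a center
#'
#' @inheritParams affine_warp
#' @param degrees rotation of the image content, degrees.
#' @export
rotate_image <- function(img, degrees, center = NULL,
                         mode = c("bilinear", "nearest")) {
  affine_warp(img, rot_mat(-degrees), center = center, mode = match.arg(mode))
}

#' Image gradient by finite differences
#'
#' Central differences at interior pixels, one-sided at the borders.
#'
#' @param img numeric matrix.
#' @return array `c(h, w, 2)`: d/drow and d/dcol.
#' @export
image_gradient <- function(img) {
  stopifnot_image(img)
  h <- nrow(img); w <- ncol(img)
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gr[1, ] <- img[2, ] - img[1, ]
  gr[h, ] <- img[h, ] - img[h - 1, ]
  gc[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gc[, 1] <- img[, 2] - img[, 1]
  gc[, w] <- img[, w] - img[, w - 1]
  out <- array(0, dim = c(h, w, 2))
  out[, , 1] <- gr; out[, , 2] <- gc
  out
}

#' Intensity-weighted centroid
#'
#' @param img numeric matrix with nonnegative total intensity > 0.
#' @return length-2 vector (row, col), continuous pixel coordinates.
#' @export
intensity_centroid <- function(img) {
  stopifnot_image(img)
  tot <- sum(img)
  if (tot <= 0) stop("no mass: total intensity must be positive")
  g <- coord_grid(nrow(img), ncol(img))
  c(sum(img * g$r), sum(img * g$c)) / tot
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram; used to derive
#' foreground masks when none are supplied.
#'
#' @param img numeric matrix in \[0, 1\].
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img) {
  stopifnot_image(img)
  v <- as.vector(img)
  breaks <- seq(min(v), max(v), length.out = 257)
  if (breaks[1] == breaks[257]) return(breaks[1])
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), 256)
  p <- h / sum(h)
  mids <- (breaks[-257] + breaks[-1]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # the maximizer is a plateau when the histogram has an empty gap between
  # modes; the plateau midpoint is the stable choice
  mean(mids[between >= max(between) - 1e-12])
}

#' Foreground mask by Otsu threshold
#' @param img numeric matrix.
#' @return logical matrix (TRUE = foreground).
#' @export
otsu_mask <- function(img) img > otsu_threshold(img)

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks are defined to overlap
#' perfectly (Dice 1).
#'
#' @param A,B logical (or 0/1) matrices or arrays of identical shape.
#' @return ratio in \[0, 1\].
#' @export
dice_overlap <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("mask shape mismatch")
  a <- as.logical(A); b <- as.logical(B)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Sum of squared differences between two images
#' @param F,M numeric matrices/arrays of identical shape.
#' @return nonnegative scalar.
#' @export
ssd <- function(F, M) {
  if (!identical(dim(F), dim(M))) stop("shape mismatch")
  sum((F - M)^2)
}
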