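# Log-demons engine: intensity forces, Gaussian regularization, the
# log-domain iteration on a stationary velocity field, and three-level
# coarse-to-fine optimization.

#' Demons configuration
#'
#' @param force_kind `"thirion"` (fixed-image force only) or `"symmetric"`
#'   (adds the moving-image force, faster and more stable convergence).
#' @param alpha force-strength normalization of the symmetric force
#'   (dimensionless; larger alpha damps the update).
#' @param sigma_fluid Gaussian width (px) smoothing the update field
#'   (fluid-like regularization).
#' @param sigma_diffusion Gaussian width (px) smoothing the velocity field
#'   (diffusion-like regularization).
#' @param max_iter iterations per pyramid level.
#' @param levels pyramid levels (3 recommended).
#' @param stop_tol relative metric change over a 5-iteration window below
#'   which a level stops.
#' @param metric similarity recorded in the trace and used for stopping;
#'   any name accepted by [similarity_metric()].
#' @return list of class `demons_config`.
#' @export
demons_config <- function(force_kind = c("symmetric", "thirion"),
                          alpha = 1.0, sigma_fluid = 1.0,
                          sigma_diffusion = 1.0, max_iter = 50L,
                          levels = 3L, stop_tol = 1e-4, metric = "ssd") {
  force_kind <- match.arg(force_kind)
  if (alpha <= 0) stop("alpha must be positive")
  if (levels < 1) stop("levels must be >= 1")
  structure(list(force_kind = force_kind, alpha = alpha,
                 sigma_fluid = sigma_fluid,
                 sigma_diffusion = sigma_diffusion,
                 max_iter = as.integer(max_iter),
                 levels = as.integer(levels),
                 stop_tol = stop_tol, metric = metric),
            class = "demons_config")
}

# guard below which the demons denominator is treated as zero
.demons_guard <- 1e-9

#' Thirion demons force
#'
#' `u = (m - f) grad(f) / (||grad(f)||^2 + (m - f)^2)` pointwise, zero where
#' the denominator falls below 1e-9.  `u` is the velocity of moving-image
#' content toward the fixed image.
#'
#' @param f fixed image (matrix).
#' @param m_warped moving image warped by the current transform.
#' @param grad_f gradient array of `f` (see [image_gradient()]).
#' @return velocity array `c(h, w, 2)`.
#' @export
demons_force_thirion <- function(f, m_warped, grad_f) {
  if (!identical(dim(f), dim(m_warped))) stop("image shape mismatch")
  diff <- m_warped - f
  den <- grad_f[, , 1]^2 + grad_f[, , 2]^2 + diff^2
  scale <- ifelse(den < .demons_guard, 0, diff / pmax(den, .demons_guard))
  u <- grad_f
  u[, , 1] <- scale * grad_f[, , 1]
  u[, , 2] <- scale * grad_f[, , 2]
  u
}

#' Symmetric demons force
#'
#' Adds the moving-image term:
#' `u = (m-f) grad(f) / (||grad(f)||^2 + a^2 (m-f)^2)
#'    + (m-f) grad(m) / (||grad(m)||^2 + a^2 (m-f)^2)`,
#' with the same denominator guard as the Thirion force.
#'
#' @inheritParams demons_force_thirion
#' @param grad_m gradient array of `m_warped`.
#' @param alpha positive force-strength normalization.
#' @return velocity array `c(h, w, 2)`.
#' @export
demons_force_symmetric <- function(f, m_warped, grad_f, grad_m, alpha = 1.0) {
  if (!identical(dim(f), dim(m_warped))) stop("image shape mismatch")
  if (alpha <= 0) stop("alpha must be positive")
  diff <- m_warped - f
  d2 <- alpha^2 * diff^2
  den_f <- grad_f[, , 1]^2 + grad_f[, , 2]^2 + d2
  den_m <- grad_m[, , 1]^2 + grad_m[, , 2]^2 + d2
  sf <- ifelse(den_f < .demons_guard, 0, diff / pmax(den_f, .demons_guard))
  sm <- ifelse(den_m < .demons_guard, 0, diff / pmax(den_m, .demons_guard))
  u <- grad_f
  u[, , 1] <- sf * grad_f[, , 1] + sm * grad_m[, , 1]
  u[, , 2] <- sf * grad_f[, , 2] + sm * grad_m[, , 2]
  u
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian regularization of a vector field
#'
#' Per-component separable Gaussian convolution with reflect boundary;
#' `sigma = 0` returns the field unchanged.
#'
#' @param field array `c(h, w, 2)`.
#' @param sigma Gaussian width in pixels.
#' @return smoothed field.
#' @export
gaussian_regularize <- function(field, sigma) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(field)
  k <- gaussian_kernel_1d(sigma)
  out <- field
  out[, , 1] <- cpp_sepconv_reflect(field[, , 1], k)
  out[, , 2] <- cpp_sepconv_reflect(field[, , 2], k)
  out
}

gaussian_smooth_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  cpp_sepconv_reflect(img, gaussian_kernel_1d(sigma))
}

#' One log-demons iteration
#'
#' Warps the moving image by `exp(v)`, computes the demons force on the
#' pair, fluid-smooths it, takes the first-order log-domain update of `v`
#' (the force is the push-forward velocity of moving content; its lift to
#' the pull-back sampling convention used by [warp_image()] enters with a
#' negative sign), diffusion-smooths `v`, and reports the SSD energy of the
#' updated transform.
#'
#' @param f,m fixed and moving images on a common grid.
#' @param v current velocity field.
#' @param cfg a [demons_config()].
#' @return list with `v` (updated), `phi` (its exponential), `m_warped`,
#'   and `energy` (SSD after the update).
#' @export
log_demons_step <- function(f, m, v, cfg = demons_config()) {
  if (!identical(dim(f), dim(m))) stop("image shape mismatch")
  phi <- exponential_map(v)
  m_w <- warp_image(m, phi)
  grad_f <- image_gradient(f)
  u <- if (cfg$force_kind == "thirion") {
    demons_force_thirion(f, m_w, grad_f)
  } else {
    demons_force_symmetric(f, m_w, grad_f, image_gradient(m_w), cfg$alpha)
  }
  u <- gaussian_regularize(u, cfg$sigma_fluid)
  v_new <- v - u
  if (any(!is.finite(v_new))) stop("velocity field diverged (non-finite)")
  v_new <- gaussian_regularize(v_new, cfg$sigma_diffusion)
  phi_new <- exponential_map(v_new)
  m_w_new <- warp_image(m, phi_new)
  list(v = v_new, phi = phi_new, m_warped = m_w_new,
       energy = ssd(f, m_w_new))
}

pyr_down <- function(img) {
  s <- gaussian_smooth_image(img, 1)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2)]
}

upsample_velocity <- function(v, h, w) {
  out <- array(0, dim = c(h, w, 2))
  out[, , 1] <- resize_image(v[, , 1], h, w) * 2
  out[, , 2] <- resize_image(v[, , 2], h, w) * 2
  out
}

# first iteration at which the trace's relative change over `window`
# iterations drops below tol; NA if it never does
trace_convergence_iter <- function(trace, tol, window = 5L) {
  if (length(trace) <= window) return(NA_integer_)
  eps <- 1e-12 + 1e-8 * abs(trace[1])
  for (t in (window + 1):length(trace)) {
    rel <- abs(trace[t] - trace[t - window]) / (abs(trace[t - window]) + eps)
    if (rel < tol) return(t)
  }
  NA_integer_
}

#' Coarse-to-fine log-demons registration
#'
#' Builds a Gaussian pyramid (`cfg$levels` levels, blur-then-decimate),
#' runs the log-demons iteration at each level from coarsest to finest,
#' and doubles + upsamples the velocity field between levels.  Inputs are
#' expected to be preregistered (on a common grid).
#'
#' @param f,m fixed and moving images on a common grid.
#' @param cfg a [demons_config()].
#' @return list with `disp` (final displacement field `exp(v)`), `v`,
#'   `m_warped`, and `traces` — one vector of per-iteration metric values
#'   per level (coarsest first), as an `energy_trace` object.
#' @export
multiresolution_register <- function(f, m, cfg = demons_config()) {
  if (!identical(dim(f), dim(m))) stop("image shape mismatch")
  pyr_f <- list(f); pyr_m <- list(m)
  for (l in seq_len(cfg$levels - 1)) {
    if (min(dim(pyr_f[[l]])) < 16)
      stop("images too small for the requested number of levels")
    pyr_f[[l + 1]] <- pyr_down(pyr_f[[l]])
    pyr_m[[l + 1]] <- pyr_down(pyr_m[[l]])
  }
  traces <- vector("list", cfg$levels)
  v <- NULL
  for (l in rev(seq_len(cfg$levels))) {
    fl <- pyr_f[[l]]; ml <- pyr_m[[l]]
    if (is.null(v)) v <- zero_field(nrow(fl), ncol(fl))
    else v <- upsample_velocity(v, nrow(fl), ncol(fl))
    trace <- numeric(0)
    for (it in seq_len(cfg$max_iter)) {
      st <- log_demons_step(fl, ml, v, cfg)
      v <- st$v
      trace <- c(trace, similarity_metric(fl, st$m_warped, cfg$metric))
      if (!is.na(trace_convergence_iter(trace, cfg$stop_tol))) break
    }
    traces[[cfg$levels - l + 1]] <- trace
  }
  disp <- exponential_map(v)
  structure(list(disp = disp, v = v, m_warped = warp_image(m, disp),
                 traces = structure(traces, metric = cfg$metric,
                                    class = "energy_trace")),
            class = "demons_result")
}
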