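# The two-layer framework: alternate affine preregistration (CNN rotation +
# moment-based scale/translation) with multiresolution log-demons until the
# similarity metric stops improving.
#
# The composed transform is carried as a dense source-coordinate map S:
# the current moving image is always a single interpolation of the ORIGINAL
# moving image, m_cur(x) = m(S(x)), so repeated outer iterations do not
# accumulate resampling blur.

#' Framework configuration
#'
#' @param outer_iters maximum outer (preregistration + demons) iterations.
#' @param tol relative metric-change tolerance stopping the outer loop.
#' @param metric similarity metric name (see [similarity_metric()]).
#' @param demons a [demons_config()] for the nonrigid layer.
#' @param freeze_rotation estimate rotation only in the first outer
#'   iteration.
#' @return list of class `framework_config`.
#' @export
framework_config <- function(outer_iters = 3L, tol = 1e-3, metric = "ssd",
                             demons = demons_config(),
                             freeze_rotation = FALSE) {
  if (outer_iters < 1) stop("outer_iters must be >= 1")
  demons$metric <- metric
  structure(list(outer_iters = as.integer(outer_iters), tol = tol,
                 metric = metric, demons = demons,
                 freeze_rotation = freeze_rotation),
            class = "framework_config")
}

sample_map <- function(S, coords_r, coords_c) {
  out <- S
  out[, , 1] <- cpp_bilinear_sample(S[, , 1], coords_r, coords_c)
  out[, , 2] <- cpp_bilinear_sample(S[, , 2], coords_r, coords_c)
  out
}

#' Two-layer adaptive registration
#'
#' Per outer iteration: [preregister_2d()] on the current moving image
#' (rotation via the classifier when supplied), then
#' [multiresolution_register()]; transforms compose affine-first,
#' displacement-second.  The loop stops when the configured metric
#' improves by less than `cfg$tol` (relative) or `cfg$outer_iters` is
#' reached.
#'
#' @param f,m fixed and moving images on a common grid.
#' @param model trained rotation classifier, or `NULL` to run the affine
#'   stage without the rotation estimate.
#' @param cfg a [framework_config()].
#' @return list of class `registration_result`: `warped` (final moving
#'   image), `src_map` (composed transform as absolute source
#'   coordinates), `disp` (source map minus identity), `affine` (list of
#'   per-iteration `affine_params`), `traces` (per-iteration list of
#'   demons traces), `metric_values` (per outer iteration),
#'   `dice_before`, `dice_after`, `iterations`, `converged`.
#' @export
two_layer_register <- function(f, m, model = NULL,
                               cfg = framework_config()) {
  if (!identical(dim(f), dim(m)))
    m <- resize_image(m, nrow(f), ncol(f))
  h <- nrow(f); w <- ncol(f)
  g <- coord_grid(h, w)
  S <- array(0, dim = c(h, w, 2))
  S[, , 1] <- g$r; S[, , 2] <- g$c
  dice_before <- dice_overlap(otsu_mask(f), otsu_mask(m))
  m_cur <- m
  affine <- list(); traces <- list(); metric_values <- numeric(0)
  converged <- FALSE
  # lower is better for ssd-type metrics, higher for correlations
  lower_better <- .metric_base(cfg$metric) == "ssd"
  for (it in seq_len(cfg$outer_iters)) {
    S_prev <- S
    use_model <- if (!is.null(model) &&
                     (!cfg$freeze_rotation || it == 1L)) model else NULL
    theta <- if (is.null(use_model) && cfg$freeze_rotation && it > 1L) 0 else NULL
    pr <- preregister_2d(f, m_cur, model = use_model, rotation_deg = theta)
    S <- sample_map(S, pr$src_map[, , 1], pr$src_map[, , 2])
    m_cur <- cpp_bilinear_sample(m, S[, , 1], S[, , 2])
    dm <- multiresolution_register(f, m_cur, cfg$demons)
    S <- sample_map(S, g$r + dm$disp[, , 1], g$c + dm$disp[, , 2])
    m_cur <- cpp_bilinear_sample(m, S[, , 1], S[, , 2])
    value <- similarity_metric(f, m_cur, cfg$metric)
    if (it > 1) {
      prev <- metric_values[it - 1]
      worse <- if (lower_better) value - prev else prev - value
      if (worse > cfg$tol * (abs(prev) + 1e-12)) {
        # this iteration degraded the fit: revert and stop
        S <- S_prev
        m_cur <- cpp_bilinear_sample(m, S[, , 1], S[, , 2])
        converged <- TRUE
        break
      }
    }
    pr$m_pre <- NULL; pr$src_map <- NULL
    affine[[it]] <- pr
    traces[[it]] <- dm$traces
    metric_values <- c(metric_values, value)
    if (it > 1) {
      rel <- abs(value - metric_values[it - 1]) /
        (abs(metric_values[it - 1]) + 1e-12)
      if (rel < cfg$tol) { converged <- TRUE; break }
    }
  }
  disp <- S
  disp[, , 1] <- S[, , 1] - g$r
  disp[, , 2] <- S[, , 2] - g$c
  structure(list(warped = m_cur, src_map = S, disp = disp, affine = affine,
                 traces = traces, metric_values = metric_values,
                 dice_before = dice_before,
                 dice_after = dice_overlap(otsu_mask(f), otsu_mask(m_cur)),
                 iterations = length(metric_values), converged = converged),
            class = "registration_result")
}

#' Normalize a multi-level convergence trace
#'
#' Per-iteration mean across levels (truncated to the shortest level),
#' then min-max scaled to \[0, 1\]; a constant mean trace maps to all
#' zeros.
#'
#' @param traces list of per-level metric vectors (an `energy_trace`).
#' @return numeric vector in \[0, 1\].
#' @export
normalize_convergence_trace <- function(traces) {
  if (length(traces) == 0 || any(lengths(traces) == 0))
    stop("nonempty traces required")
  L <- min(lengths(traces))
  m <- rowMeans(vapply(traces, function(tr) tr[seq_len(L)], numeric(L)))
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Compare convergence speed across similarity metrics
#'
#' Runs multiresolution demons once per metric with a full iteration
#' budget (per-level early stopping disabled so traces are comparable)
#' and reduces each run's per-level traces by the mean-then-normalize
#' rule ([normalize_convergence_trace()]).  The normalized trace is
#' oriented to descend (correlation metrics ascend toward 1 and are
#' flipped), and the reported convergence iteration is the first at
#' which the trace completes `1 - tol` of its total descent — the
#' point where the normalized convergence extent has dropped to `tol`.
#'
#' @param f,m fixed and moving images on a common grid.
#' @param metrics metric names to compare.
#' @param cfg a [demons_config()] (its `stop_tol` is overridden to 0).
#' @param tol residual normalized extent counted as converged.
#' @return named vector of convergence iterations (trace length + 1 when
#'   a metric never gets there within the budget).
#' @export
compare_convergence <- function(f, m,
                                metrics = c("ssd", "pca-ssd", "pca-pearson"),
                                cfg = demons_config(), tol = 0.05) {
  vapply(metrics, function(mt) {
    c2 <- cfg
    c2$metric <- mt
    c2$stop_tol <- 0
    res <- multiresolution_register(f, m, c2)
    nm <- normalize_convergence_trace(res$traces)
    n <- length(nm)
    if (mean(utils::head(nm, 3)) < mean(utils::tail(nm, 3)))
      nm <- 1 - nm
    k <- which(nm <= tol)[1]
    if (is.na(k)) n + 1 else k
  }, numeric(1))
}

#' Evaluate a registration result
#'
#' Dice on Otsu masks (or supplied masks) plus final values of the
#' requested similarity metrics.
#'
#' @param f fixed image.
#' @param warped registered moving image (or a `registration_result`).
#' @param mask_f,mask_m optional binary masks; Otsu-derived otherwise.
#' @param metrics character vector of metric names.
#' @return list with `dice` and `metrics` (named numeric).
#' @export
evaluate_registration <- function(f, warped, mask_f = NULL, mask_m = NULL,
                                  metrics = "ssd") {
  if (inherits(warped, "registration_result")) warped <- warped$warped
  if (is.null(mask_f)) mask_f <- otsu_mask(f)
  if (is.null(mask_m)) mask_m <- otsu_mask(warped)
  vals <- vapply(metrics, function(k) similarity_metric(f, warped, k),
                 numeric(1))
  list(dice = dice_overlap(mask_f, mask_m),
       metrics = stats::setNames(vals, metrics))
}
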