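# Convolutional rotation / slice-position classifier: architecture
# bookkeeping and forward pass.
#
# The reference stack alternates valid convolutions and 2x2 mean-pooling
# subsampling: conv9 -> pool2 -> conv5 -> pool2 -> conv5 -> pool2 -> conv5
# -> pool2, followed by a full connection with per-class sigmoid output
# units (trained under the total-square-error loss; reported class scores
# are normalized to sum to 1).  A 128x128 input
# traverses sides 120, 60, 56, 28, 24, 12, 8, 4.  Smaller inputs keep only
# the leading pairs that fit (a 28x28 input keeps two pairs and ends at
# 3x3 maps).  Each convolutional layer holds one shared kernel per INPUT
# map; output maps combine the convolved maps with weights alpha_ij
# constrained to the simplex (sum_i alpha_ij = 1, alpha_ij in [0, 1]).

#' Sigmoid activation
#' @param x numeric.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' CNN architecture for a given input side
#'
#' Builds conv+subsample pairs from the reference kernel sizes, stopping
#' when the next convolution no longer fits or its output side is not
#' divisible by the pool factor.
#'
#' @param input_side input image side (pixels).
#' @param n_classes number of output classes.
#' @param map_counts output maps per conv layer.
#' @param kernel_sizes conv kernel sides per layer.
#' @param pool subsampling factor.
#' @return list of class `cnn_architecture` with per-pair specs, the side
#'   sequence, and the flattened feature dimension.
#' @export
cnn_architecture <- function(input_side, n_classes,
                             map_counts = c(6, 12, 24, 48),
                             kernel_sizes = c(9, 5, 5, 5), pool = 2L) {
  s <- as.integer(input_side)
  n_in <- 1L
  pairs <- list()
  sides <- s
  for (p in seq_along(kernel_sizes)) {
    k <- kernel_sizes[p]
    s_conv <- s - k + 1L
    if (s_conv < pool || s_conv %% pool != 0L) break
    n_out <- map_counts[min(p, length(map_counts))]
    pairs[[p]] <- list(kernel = as.integer(k), n_in = n_in,
                       n_out = as.integer(n_out),
                       side_in = s, side_conv = s_conv,
                       side_pool = s_conv %/% pool)
    sides <- c(sides, s_conv, s_conv %/% pool)
    s <- s_conv %/% pool
    n_in <- as.integer(n_out)
  }
  if (length(pairs) == 0) stop("input too small for any conv layer")
  structure(list(input_side = as.integer(input_side),
                 n_classes = as.integer(n_classes), pool = as.integer(pool),
                 pairs = pairs, sides = sides,
                 feature_dim = n_in * s^2, final_side = s,
                 final_maps = n_in),
            class = "cnn_architecture")
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Initialize a CNN model
#'
#' Kernel weights are drawn uniformly within a gain-corrected
#' `+- 8 sqrt(6 / (fan_in + fan_out))` envelope: each logistic sigmoid in
#' the stack attenuates signal variance by its slope 1/4, and with two
#' sigmoids per conv+subsample pair an uncorrected initialization
#' collapses inter-sample feature variance to numerical dust.  Pooling
#' layers start at `beta = 4` with bias `-beta/2`, a unit-gain centered
#' pooling sigmoid.  Alpha weights start uniform on the simplex; the
#' full-connection weights use the plain Glorot envelope.
#'
#' @param arch a [cnn_architecture()].
#' @param seed RNG seed (initialization is deterministic given it).
#' @return list of class `cnn_model`.
#' @export
new_cnn_model <- function(arch, seed = 1L) {
  with_seed(seed, {
    pairs <- lapply(arch$pairs, function(p) {
      k2 <- p$kernel^2
      kernels <- lapply(seq_len(p$n_in), function(i)
        matrix(8 * glorot(k2 * p$n_in, k2 * p$n_out, k2), p$kernel, p$kernel))
      list(kernels = kernels,
           alpha = matrix(1 / p$n_in, p$n_in, p$n_out),
           conv_bias = numeric(p$n_out),
           beta = rep(4, p$n_out),
           pool_bias = rep(-2, p$n_out))
    })
    W <- matrix(glorot(arch$feature_dim, arch$n_classes,
                       arch$feature_dim * arch$n_classes),
                arch$n_classes, arch$feature_dim)
    structure(list(arch = arch, pairs = pairs, W = W,
                   b_out = numeric(arch$n_classes)),
              class = "cnn_model")
  })
}

meanpool2 <- function(x) {
  ro <- seq(1, nrow(x), by = 2); co <- seq(1, ncol(x), by = 2)
  (x[ro, co, drop = FALSE] + x[ro + 1, co, drop = FALSE] +
   x[ro, co + 1, drop = FALSE] + x[ro + 1, co + 1, drop = FALSE]) / 4
}

upsample_pool2 <- function(g) {
  g[rep(seq_len(nrow(g)), each = 2), rep(seq_len(ncol(g)), each = 2),
    drop = FALSE] / 4
}


#' Forward pass of one conv layer
#'
#' `x_j = f( sum_i alpha_ij (x_i * k_i) + b_j )` with valid convolution.
#'
#' @param maps_in list of input map matrices.
#' @param kernels list of kernel matrices, one per input map.
#' @param biases per-output biases.
#' @param alpha `n_in x n_out` simplex weight matrix.
#' @return list with `maps` (outputs) and `convolved` (the `x_i * k_i`).
#' @export
conv_layer_forward <- function(maps_in, kernels, biases, alpha) {
  convolved <- lapply(seq_along(maps_in), function(i)
    cpp_corr2_valid(maps_in[[i]], kernels[[i]]))
  n_out <- length(biases)
  maps <- vector("list", n_out)
  for (j in seq_len(n_out)) {
    u <- biases[j]
    acc <- 0
    for (i in seq_along(convolved)) acc <- acc + alpha[i, j] * convolved[[i]]
    maps[[j]] <- sigmoid(acc + u)
  }
  list(maps = maps, convolved = convolved)
}

#' Forward pass of one subsampling layer
#'
#' `x_j = f( beta_j down(x_j) + b_j )` with `down` the non-overlapping 2x2
#' mean pooling.
#'
#' @param maps_in list of map matrices with even sides.
#' @param beta per-map multipliers.
#' @param biases per-map biases.
#' @return list with `maps` (outputs) and `pooled` (pre-activation pools).
#' @export
subsample_layer_forward <- function(maps_in, beta, biases) {
  if (any(vapply(maps_in, function(m) nrow(m) %% 2 != 0 || ncol(m) %% 2 != 0,
                 logical(1))))
    stop("subsampling requires even map sides")
  pooled <- lapply(maps_in, meanpool2)
  maps <- lapply(seq_along(maps_in), function(j)
    sigmoid(beta[j] * pooled[[j]] + biases[j]))
  list(maps = maps, pooled = pooled)
}

#' Forward pass of the classifier
#'
#' @param model a `cnn_model`.
#' @param img input image matrix of side `model$arch$input_side`.
#' @param keep keep intermediate activations (for backpropagation).
#' @return numeric class-score vector summing to 1; with `keep = TRUE`, a
#'   list with `scores` and the cached intermediates.
#' @export
forward_pass <- function(model, img, keep = FALSE) {
  arch <- model$arch
  if (!identical(dim(img), c(arch$input_side, arch$input_side)))
    stop("input side does not match the architecture")
  maps <- list(img)
  cache <- if (keep) vector("list", length(model$pairs)) else NULL
  for (p in seq_along(model$pairs)) {
    par <- model$pairs[[p]]
    cv <- conv_layer_forward(maps, par$kernels, par$conv_bias, par$alpha)
    sb <- subsample_layer_forward(cv$maps, par$beta, par$pool_bias)
    if (keep)
      cache[[p]] <- list(maps_in = maps, convolved = cv$convolved,
                         conv_maps = cv$maps, pooled = sb$pooled,
                         pool_maps = sb$maps)
    maps <- sb$maps
  }
  a <- unlist(maps, use.names = FALSE)
  z <- as.vector(model$W %*% a + model$b_out)
  y <- sigmoid(z)           # per-class output units, trained under Eq-style
  scores <- y / sum(y)      # squared error; normalized scores for reporting
  if (!keep) return(scores)
  list(scores = scores, outputs = y, features = a, cache = cache)
}

#' Total square error loss
#'
#' Per sample `E = 1/2 sum_k (t_k - y_k)^2`; over a batch, the sum of the
#' per-sample losses.
#'
#' @param targets one-hot target vector (or matrix, samples in rows).
#' @param outputs score vector (or matrix, samples in rows).
#' @return nonnegative scalar.
#' @export
loss_total_square_error <- function(targets, outputs) {
  if (length(targets) != length(outputs)) stop("length mismatch")
  sum((targets - outputs)^2) / 2
}

#' Predicted class of an input (0-based; ties go to the smallest index)
#' @param model a `cnn_model`.
#' @param img input matrix.
#' @return integer class in `[0, n_classes)`.
#' @export
predict_class <- function(model, img) {
  which.max(forward_pass(model, img)) - 1L
}
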