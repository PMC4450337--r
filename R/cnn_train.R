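# Backpropagation training of the classifier, and the rotation-classifier
# front end operating on difference images.

zero_like_grads <- function(model) {
  pairs <- lapply(model$pairs, function(par) {
    list(kernels = lapply(par$kernels, function(k) k * 0),
         alpha = par$alpha * 0,
         conv_bias = par$conv_bias * 0,
         beta = par$beta * 0,
         pool_bias = par$pool_bias * 0)
  })
  list(pairs = pairs, W = model$W * 0, b_out = model$b_out * 0)
}

# gradient of the batch total-square-error loss (Eq-style sum over samples)
# with respect to every parameter; also returns the loss and predictions
cnn_gradients <- function(model, inputs, labels) {
  arch <- model$arch
  g <- zero_like_grads(model)
  loss <- 0
  pred <- integer(length(inputs))
  np <- length(model$pairs)
  for (s in seq_along(inputs)) {
    fw <- forward_pass(model, inputs[[s]], keep = TRUE)
    y <- fw$outputs
    t <- numeric(arch$n_classes); t[labels[s] + 1L] <- 1
    loss <- loss + loss_total_square_error(t, y)
    pred[s] <- which.max(y) - 1L
    # sigmoid output units under the squared-error loss
    dz <- (y - t) * y * (1 - y)
    g$W <- g$W + outer(dz, fw$features)
    g$b_out <- g$b_out + dz
    da <- as.vector(crossprod(model$W, dz))
    # unflatten into the final pool maps
    side <- arch$final_side
    dmaps <- vector("list", arch$final_maps)
    off <- 0L
    for (j in seq_len(arch$final_maps)) {
      dmaps[[j]] <- matrix(da[(off + 1):(off + side^2)], side, side)
      off <- off + side^2
    }
    for (p in rev(seq_len(np))) {
      par <- model$pairs[[p]]
      ch <- fw$cache[[p]]
      n_out <- length(par$conv_bias)
      n_in <- length(par$kernels)
      dconv <- vector("list", n_out)
      for (j in seq_len(n_out)) {           # subsample layer
        xo <- ch$pool_maps[[j]]
        du <- dmaps[[j]] * xo * (1 - xo)
        g$pairs[[p]]$beta[j] <- g$pairs[[p]]$beta[j] + sum(du * ch$pooled[[j]])
        g$pairs[[p]]$pool_bias[j] <- g$pairs[[p]]$pool_bias[j] + sum(du)
        dconv[[j]] <- upsample_pool2(par$beta[j] * du)
      }
      din <- vector("list", n_in)           # conv layer
      gsum <- vector("list", n_in)
      for (j in seq_len(n_out)) {
        xo <- ch$conv_maps[[j]]
        du <- dconv[[j]] * xo * (1 - xo)
        g$pairs[[p]]$conv_bias[j] <- g$pairs[[p]]$conv_bias[j] + sum(du)
        for (i in seq_len(n_in)) {
          g$pairs[[p]]$alpha[i, j] <- g$pairs[[p]]$alpha[i, j] +
            sum(du * ch$convolved[[i]])
          gsum[[i]] <- if (is.null(gsum[[i]])) par$alpha[i, j] * du
                       else gsum[[i]] + par$alpha[i, j] * du
        }
      }
      for (i in seq_len(n_in)) {
        g$pairs[[p]]$kernels[[i]] <- g$pairs[[p]]$kernels[[i]] +
          cpp_corr2_valid(ch$maps_in[[i]], gsum[[i]])
        din[[i]] <- cpp_conv2_full(gsum[[i]], par$kernels[[i]])
      }
      dmaps <- din
    }
  }
  list(grads = g, loss = loss, pred = pred)
}

#' Euclidean projection onto the probability simplex
#' @param v numeric vector.
#' @return vector with nonnegative entries summing to 1.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}

#' One gradient-descent update on a labeled batch
#'
#' Updates all parameters (kernels, conv/pool biases, pooling multipliers,
#' alpha combination weights, full-connection weights) by gradient descent
#' on the batch total-square-error loss, then re-projects every alpha
#' column onto the simplex.
#'
#' @param model a `cnn_model`.
#' @param inputs list of input matrices.
#' @param labels integer class labels in `[0, n_classes)`.
#' @param lr learning rate.
#' @return updated model, with attributes `loss` and `pred` of the batch
#'   evaluated before the update.
#' @export
backprop_update <- function(model, inputs, labels, lr = 1) {
  res <- cnn_gradients(model, inputs, labels)
  g <- res$grads
  if (lr != 0) {
    for (p in seq_along(model$pairs)) {
      gp <- g$pairs[[p]]
      for (i in seq_along(model$pairs[[p]]$kernels))
        model$pairs[[p]]$kernels[[i]] <-
          model$pairs[[p]]$kernels[[i]] - lr * gp$kernels[[i]]
      model$pairs[[p]]$conv_bias <- model$pairs[[p]]$conv_bias - lr * gp$conv_bias
      model$pairs[[p]]$beta <- model$pairs[[p]]$beta - lr * gp$beta
      model$pairs[[p]]$pool_bias <- model$pairs[[p]]$pool_bias - lr * gp$pool_bias
      a <- model$pairs[[p]]$alpha - lr * gp$alpha
      model$pairs[[p]]$alpha <- apply(a, 2, project_simplex)
      dim(model$pairs[[p]]$alpha) <- dim(a)
    }
    model$W <- model$W - lr * g$W
    model$b_out <- model$b_out - lr * g$b_out
  }
  if (any(!is.finite(model$W))) stop("non-finite gradients: training aborted")
  attr(model, "loss") <- res$loss
  attr(model, "pred") <- res$pred
  model
}

#' Train a classifier by mini-batch gradient descent
#'
#' Shuffles the training set each epoch (deterministically under `seed`),
#' performs [backprop_update()] on consecutive mini-batches, and records
#' per-epoch training loss and accuracy.  Training stops early once
#' training accuracy has been 1 for ten consecutive epochs (the margin,
#' and with it held-out accuracy, keeps improving for a while after the
#' training set is first classified perfectly).
#'
#' @param model a `cnn_model`.
#' @param inputs list of input matrices.
#' @param labels integer labels in `[0, n_classes)`.
#' @param epochs maximum epochs.
#' @param lr learning rate, applied to the batch-mean gradient (the
#'   reference setting is 1 at batch size 10).
#' @param batch_size mini-batch size (the reference setting is 10).
#' @param seed RNG seed for shuffling.
#' @return the trained model, with a `history` attribute (data.frame:
#'   epoch, loss, accuracy).
#' @export
train_cnn <- function(model, inputs, labels, epochs = 100L, lr = 1,
                      batch_size = 10L, seed = 1L) {
  n <- length(inputs)
  hist_loss <- numeric(0); hist_acc <- numeric(0)
  perfect <- 0L
  best <- NULL
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      loss <- 0; correct <- 0L
      for (b in seq(1, n, by = batch_size)) {
        idx <- ord[b:min(b + batch_size - 1, n)]
        model <- backprop_update(model, inputs[idx], labels[idx],
                                 lr / length(idx))
        loss <- loss + attr(model, "loss")
        correct <- correct + sum(attr(model, "pred") == labels[idx])
      }
      hist_loss <- c(hist_loss, loss)
      hist_acc <- c(hist_acc, correct / n)
      if (correct == n) {
        # in-epoch accuracy is measured before each batch update; confirm
        # on the post-epoch parameters and checkpoint the best state
        ta <- cnn_accuracy(model, inputs, labels)
        if (is.null(best) || ta > best$acc) best <- list(acc = ta, model = model)
        perfect <- if (ta == 1) perfect + 1L else 0L
      } else perfect <- 0L
      if (perfect >= 10L) break
    }
  })
  if (!is.null(best) && best$acc > cnn_accuracy(model, inputs, labels))
    model <- best$model
  attr(model, "history") <- data.frame(epoch = seq_along(hist_loss),
                                       loss = hist_loss,
                                       accuracy = hist_acc)
  model
}

#' Classification accuracy of a model on a labeled set
#' @param model a `cnn_model`.
#' @param inputs list of input matrices.
#' @param labels integer labels.
#' @return fraction correct.
#' @export
cnn_accuracy <- function(model, inputs, labels) {
  pred <- vapply(inputs, function(x) predict_class(model, x), integer(1))
  mean(pred == labels)
}

#' Difference image for the rotation classifier
#'
#' Elementwise absolute difference of fixed and moving image, resized to
#' the classifier input side.  Inputs are expected normalized to \[0, 1\],
#' so the difference already lives in \[0, 1\] and its *magnitude* is kept:
#' per-sample min-max rescaling would blow a near-zero residual difference
#' (the signature of a correctly derotated pair) up into a full-range
#' pattern unlike anything in the training set.
#'
#' @param f,m images on the same grid, intensities in \[0, 1\].
#' @return difference image in \[0, 1\].
#' @param input_side classifier input side (`NULL` keeps the image size).
#' @export
make_difference_input <- function(f, m, input_side = NULL) {
  if (!identical(dim(f), dim(m))) stop("image shape mismatch")
  d <- abs(f - m)
  if (!is.null(input_side))
    d <- resize_image(d, input_side, input_side)
  pmin(pmax(d, 0), 1)
}

#' Train the rotation classifier
#'
#' Builds the labeled set of difference images `diff(F, F o r_theta)` for
#' every base image and every class angle on the grid
#' `0, 360/c, ..., 360 - 360/c`, splits it 80/20, and trains the CNN by
#' mini-batch backpropagation.
#'
#' @param bases list of base images (rotation-asymmetric; near
#'   rotation-invariant bases are rejected).
#' @param n_classes number of rotation classes (must divide 360).
#' @param input_side classifier input side (reference settings: 128, 64
#'   or 28).
#' @param epochs maximum training epochs.
#' @param lr,batch_size optimizer settings.
#' @param seed RNG seed controlling initialization, the train/held-out
#'   split and shuffling.
#' @param map_counts conv maps per layer.
#' @return trained `cnn_model` with attributes `history`, `train_accuracy`,
#'   `heldout_accuracy`, and fields `n_classes`/`input_side` in its arch.
#' @export
train_rotation_classifier <- function(bases, n_classes = 36L,
                                      input_side = 28L, epochs = 500L,
                                      lr = 1, batch_size = 10L, seed = 1L,
                                      map_counts = c(6, 12, 24, 48)) {
  if (360L %% as.integer(n_classes) != 0L) stop("n_classes must divide 360")
  for (b in bases) {
    if (ssd(b, rotate_image(b, 90)) <= 0.01 * length(b))
      warning("base image is nearly rotation-invariant; ",
              "rotation classes may be inseparable")
  }
  ds <- make_rotation_dataset(bases, n_classes, input_side, seed)
  arch <- cnn_architecture(input_side, n_classes, map_counts = map_counts)
  model <- new_cnn_model(arch, seed = seed)
  model <- train_cnn(model, ds$train$inputs, ds$train$labels,
                     epochs = epochs, lr = lr, batch_size = batch_size,
                     seed = seed + 1L)
  attr(model, "train_accuracy") <-
    cnn_accuracy(model, ds$train$inputs, ds$train$labels)
  attr(model, "heldout_accuracy") <-
    if (length(ds$test$labels) > 0)
      cnn_accuracy(model, ds$test$inputs, ds$test$labels)
    else NA_real_
  model
}

#' Predict the rotation class and angle between two images
#'
#' Runs the forward pass on the difference image; ties in the score vector
#' break toward the smallest class index.
#'
#' @param model trained rotation classifier.
#' @param f,m fixed and moving images (same grid).
#' @return list with `class` (0-based), `angle` (degrees on the class
#'   grid) and `scores`.
#' @export
predict_rotation_class <- function(model, f, m) {
  d <- make_difference_input(f, m, model$arch$input_side)
  y <- forward_pass(model, d)
  cls <- which.max(y) - 1L
  list(class = cls, angle = cls * 360 / model$arch$n_classes, scores = y)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a single RDS archive holding the architecture and all
#' parameter tensors under named keys.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `load_cnn_model` returns the model.
#' @export
save_cnn_model <- function(model, path) saveRDS(unclass(model), path)

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) structure(readRDS(path), class = "cnn_model")
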