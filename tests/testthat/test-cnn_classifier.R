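test_that("sigmoid values and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(round(sigmoid(4), 4), 0.982)
  expect_equal(sigmoid(-3), 1 - sigmoid(3), tolerance = 1e-12)
  expect_gt(sigmoid(30), 1 - 1e-12)
})

test_that("reference architecture bookkeeping for a 128x128 input", {
  arch <- cnn_architecture(128, 360)
  expect_equal(arch$sides, c(128, 120, 60, 56, 28, 24, 12, 8, 4))
  expect_equal(arch$final_side, 4)
  expect_equal(length(arch$pairs), 4)
  # one conv feature connection carries kernel_size^2 shared weights
  m <- new_cnn_model(cnn_architecture(28, 4), seed = 1)
  expect_equal(length(m$pairs[[1]]$kernels[[1]]), 81)
  # smaller inputs keep only the pairs that fit
  expect_equal(cnn_architecture(28, 36)$sides, c(28, 20, 10, 6, 3))
  expect_equal(cnn_architecture(64, 36)$sides, c(64, 56, 28, 24, 12, 8, 4))
})

test_that("conv layer forward: valid shapes, direct summation, delta kernel", {
  # 3x3 all-ones map, 2x2 all-ones kernel, alpha = 1, b = 0 -> sigma(4)
  out <- conv_layer_forward(list(matrix(1, 3, 3)), list(matrix(1, 2, 2)),
                            biases = 0, alpha = matrix(1, 1, 1))
  expect_equal(out$maps[[1]], matrix(sigmoid(4), 2, 2))
  # delta kernel: output is sigma of the cropped input
  img <- matrix(runif(36), 6, 6)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  out <- conv_layer_forward(list(img), list(delta), 0, matrix(1, 1, 1))
  expect_equal(out$maps[[1]], sigmoid(img[2:5, 2:5]))
  # a 128x128 input and 9x9 kernel give 120x120 maps
  out <- conv_layer_forward(list(matrix(0, 128, 128)), list(matrix(0, 9, 9)),
                            0, matrix(1, 1, 1))
  expect_identical(dim(out$maps[[1]]), c(120L, 120L))
})

test_that("subsample layer: mean pooling then sigmoid, halved sides", {
  blk <- matrix(c(1, 5, 3, 7), 2, 2)   # mean 4
  out <- subsample_layer_forward(list(blk), beta = 1, biases = 0)
  expect_equal(out$maps[[1]], matrix(sigmoid(4), 1, 1))
  v <- matrix(0.3, 4, 4)
  out <- subsample_layer_forward(list(v), beta = 1, biases = 0)
  expect_equal(out$maps[[1]], matrix(sigmoid(0.3), 2, 2))
  out <- subsample_layer_forward(list(matrix(0, 120, 120)), 1, 0)
  expect_identical(dim(out$maps[[1]]), c(60L, 60L))
  expect_error(subsample_layer_forward(list(matrix(0, 5, 5)), 1, 0), "even")
})

test_that("forward pass: score normalization and uniformity at zero weights", {
  model <- tiny_cnn()
  img <- matrix(runif(64), 8, 8)
  y <- forward_pass(model, img)
  expect_equal(sum(y), 1, tolerance = 1e-12)
  model$W[] <- 0; model$b_out[] <- 0
  expect_equal(forward_pass(model, img), rep(1 / 3, 3))
  expect_error(forward_pass(model, matrix(0, 9, 9)), "side")
})

test_that("total square error loss", {
  expect_equal(loss_total_square_error(c(1, 0), c(1, 0)), 0)
  expect_equal(loss_total_square_error(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_gte(loss_total_square_error(runif(5), runif(5)), 0)
})

test_that("analytic gradients match central finite differences (toy network)", {
  model <- tiny_cnn()
  b <- tiny_batch()
  gr <- deepdemons:::cnn_gradients(model, b$inputs, b$labels)
  loss_of <- function(m) deepdemons:::cnn_gradients(m, b$inputs, b$labels)$loss
  eps <- 1e-5
  check <- function(get, set, g, n_probe = NULL) {
    idx <- seq_along(get(model))
    if (!is.null(n_probe) && length(idx) > n_probe)
      idx <- idx[round(seq(1, length(idx), length.out = n_probe))]
    worst <- 0
    for (i in idx) {
      m1 <- set(model, i, get(model)[i] + eps)
      m2 <- set(model, i, get(model)[i] - eps)
      fd <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      worst <- max(worst, abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-6))
    }
    worst
  }
  expect_lt(check(function(m) m$W,
                  function(m, i, v) { m$W[i] <- v; m },
                  gr$grads$W, 20), 1e-4)
  expect_lt(check(function(m) m$b_out,
                  function(m, i, v) { m$b_out[i] <- v; m },
                  gr$grads$b_out), 1e-4)
  for (field in c("conv_bias", "beta", "pool_bias", "alpha")) {
    expect_lt(check(function(m) m$pairs[[1]][[field]],
                    function(m, i, v) { m$pairs[[1]][[field]][i] <- v; m },
                    gr$grads$pairs[[1]][[field]]), 1e-4)
  }
  expect_lt(check(function(m) m$pairs[[1]]$kernels[[1]],
                  function(m, i, v) { m$pairs[[1]]$kernels[[1]][i] <- v; m },
                  gr$grads$pairs[[1]]$kernels[[1]]), 1e-4)
})

test_that("backprop update: zero lr is a no-op, training lowers the loss", {
  model <- tiny_cnn()
  b <- tiny_batch()
  m0 <- backprop_update(model, b$inputs, b$labels, lr = 0)
  attributes(m0) <- attributes(model)
  expect_equal(m0, model)
  loss0 <- deepdemons:::cnn_gradients(model, b$inputs, b$labels)$loss
  m <- model
  for (i in 1:200) m <- backprop_update(m, b$inputs, b$labels, lr = 1)
  expect_lt(attr(m, "loss"), loss0)
})

test_that("alpha stays on the simplex after every update", {
  arch <- cnn_architecture(12, 3, map_counts = c(2, 3), kernel_sizes = c(3, 3))
  m <- new_cnn_model(arch, seed = 3)
  set.seed(11)
  inputs <- lapply(1:6, function(i) matrix(runif(144), 12, 12))
  labels <- rep(0:2, 2)
  for (i in 1:25) {
    m <- backprop_update(m, inputs, labels, lr = 2)
    for (p in seq_along(m$pairs)) {
      a <- m$pairs[[p]]$alpha
      expect_true(all(a >= -1e-12 & a <= 1 + 1e-12))
      expect_equal(colSums(a), rep(1, ncol(a)), tolerance = 1e-9)
    }
  }
})

test_that("project_simplex returns valid simplex points", {
  for (i in 1:20) {
    v <- rnorm(7, sd = 3)
    p <- project_simplex(v)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_equal(project_simplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
})

test_that("difference input: zero for identical pair, symmetric, resized", {
  f <- cached_phantom("blobs", 64, 1)
  m <- cached_phantom("blobs", 64, 2)
  expect_equal(make_difference_input(f, f), matrix(0, 64, 64))
  expect_equal(make_difference_input(f, m), make_difference_input(m, f))
  expect_identical(dim(make_difference_input(f, m, 28)), c(28L, 28L))
  # magnitude is preserved: a constant offset keeps its value
  expect_equal(make_difference_input(matrix(0.2, 8, 8), matrix(0.9, 8, 8)),
               matrix(0.7, 8, 8))
  expect_true(all(make_difference_input(f, m) >= 0 &
                    make_difference_input(f, m) <= 1))
})

test_that("a small rotation classifier trains to perfect accuracy and predicts 90 deg", {
  bases <- lapply(0:5, function(i) cached_phantom("brainlike", 64, 30 + i))
  model <- train_rotation_classifier(bases, n_classes = 4, input_side = 28,
                                     epochs = 150, lr = 2, seed = 1)
  expect_gte(attr(model, "train_accuracy"), 0.99)
  f <- cached_phantom("brainlike", 64, 33)
  pr <- predict_rotation_class(model, f, rotate_image(f, 90))
  expect_equal(pr$class, 1L)
  expect_equal(pr$angle, 90)
  expect_equal(predict_rotation_class(model, f, f)$class, 0L)
  # predicted angles live on the class grid
  expect_true(pr$angle %in% seq(0, 270, by = 90))
})

test_that("rotation-invariant bases are rejected with a warning", {
  disk <- outer(1:33, 1:33, function(r, c) exp(-((r - 17)^2 + (c - 17)^2) / 50))
  expect_warning(make_rotation_dataset_check <- train_rotation_classifier(
    list(disk), n_classes = 2, input_side = 28, epochs = 1, seed = 1),
    "rotation-invariant")
})

test_that("checkpoints round-trip through save/load", {
  model <- tiny_cnn()
  path <- withr::local_tempfile(fileext = ".rds")
  save_cnn_model(model, path)
  m2 <- load_cnn_model(path)
  expect_equal(unclass(m2), unclass(model))
  img <- matrix(runif(64), 8, 8)
  expect_equal(forward_pass(m2, img), forward_pass(model, img))
})
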