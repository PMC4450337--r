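# Shared fixtures, built in code.  Phantoms are cached per test session.

phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(kind = "blobs", side = 64L, seed = 1L) {
  key <- paste(kind, side, seed, sep = "_")
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- make_phantom(kind, side, seed)
  phantom_cache[[key]]
}

constant_field <- function(h, w, dr, dc) {
  d <- array(0, dim = c(h, w, 2))
  d[, , 1] <- dr; d[, , 2] <- dc
  d
}

# maximum vector norm of a displacement field
field_max_norm <- function(d) sqrt(max(d[, , 1]^2 + d[, , 2]^2))

# tiny CNN used by gradient-check and update tests
tiny_cnn <- function(seed = 42L, n_classes = 3L) {
  arch <- cnn_architecture(8, n_classes, map_counts = c(2), kernel_sizes = c(3))
  new_cnn_model(arch, seed = seed)
}

tiny_batch <- function(n = 4L, seed = 7L) {
  withr::local_seed(seed)
  list(inputs = lapply(seq_len(n), function(i) matrix(runif(64), 8, 8)),
       labels = (seq_len(n) - 1L) %% 3L)
}
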