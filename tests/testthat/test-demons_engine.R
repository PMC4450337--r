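test_that("Thirion force matches hand-computed pixels and vanishes when F = M", {
  f <- cached_phantom("blobs", 32, 1)
  gf <- image_gradient(f)
  u0 <- demons_force_thirion(f, f, gf)
  expect_equal(u0, array(0, dim = c(32, 32, 2)))
  # single-pixel evaluation: f=0.2, m=0.7, grad_f=(0.5,0) -> u=(0.5,0)
  f1 <- matrix(0.2, 3, 3); m1 <- matrix(0.7, 3, 3)
  g1 <- array(0, dim = c(3, 3, 2)); g1[, , 1] <- 0.5
  u <- demons_force_thirion(f1, m1, g1)
  expect_equal(u[2, 2, 1], 0.5, tolerance = 1e-12)
  expect_equal(u[2, 2, 2], 0, tolerance = 1e-12)
  # zero gradient and m != f -> guarded to zero
  u <- demons_force_thirion(matrix(0, 3, 3), matrix(0, 3, 3) + 1e-20,
                            array(0, dim = c(3, 3, 2)))
  expect_equal(u, array(0, dim = c(3, 3, 2)))
})

test_that("symmetric force: hand-computed pixel, alpha damping, antisymmetry", {
  f1 <- matrix(0, 3, 3); m1 <- matrix(1, 3, 3)
  g1 <- array(0, dim = c(3, 3, 2)); g1[, , 1] <- 1
  u <- demons_force_symmetric(f1, m1, g1, g1, alpha = 1)
  expect_equal(u[2, 2, 1], 1, tolerance = 1e-12)   # 1/2 + 1/2
  # u -> 0 monotonically as alpha grows
  norms <- vapply(c(1, 2, 5, 10, 100), function(a)
    abs(demons_force_symmetric(f1, m1, g1, g1, alpha = a)[2, 2, 1]), numeric(1))
  expect_true(all(diff(norms) < 0))
  # with shared gradient input the force is exactly antisymmetric in (f, m)
  f <- cached_phantom("blobs", 32, 2); m <- cached_phantom("blobs", 32, 3)
  gshared <- image_gradient(f)
  u1 <- demons_force_symmetric(f, m, gshared, gshared, 1)
  u2 <- demons_force_symmetric(m, f, gshared, gshared, 1)
  expect_equal(u1, -u2, tolerance = 1e-12)
  expect_error(demons_force_symmetric(f, m, gshared, gshared, alpha = 0))
})

test_that("gaussian_regularize: identity at sigma 0, constants fixed, mass conserved", {
  fld <- array(rnorm(32 * 32 * 2), dim = c(32, 32, 2))
  expect_identical(gaussian_regularize(fld, 0), fld)
  cf <- constant_field(16, 16, 1.5, -2)
  expect_equal(gaussian_regularize(cf, 2), cf, tolerance = 1e-12)
  imp <- array(0, dim = c(21, 21, 2)); imp[11, 11, 1] <- 1
  sm <- gaussian_regularize(imp, 1)
  k <- deepdemons:::gaussian_kernel_1d(1)
  expect_equal(sm[11, 11, 1], max(k)^2, tolerance = 1e-12)
  expect_equal(sum(sm[, , 1]), 1, tolerance = 1e-6)
})

test_that("log-demons step: fixed point at F = M, descent from a shifted state", {
  f <- cached_phantom("blobs", 64, 4)
  v0 <- array(0, dim = c(64, 64, 2))
  st <- log_demons_step(f, f, v0)
  expect_equal(st$v, v0)
  expect_equal(st$energy, 0)
  m <- warp_image(f, constant_field(64, 64, 1, 0))
  st <- log_demons_step(f, m, v0)
  expect_lt(st$energy, ssd(f, m))
})

test_that("one step on identical images does not increase energy (20 seeded cases)", {
  f <- cached_phantom("brainlike", 64, 5)
  for (s in 1:20) {
    w <- make_smooth_warp(64, 2, 8, seed = 100 + s)
    e0 <- ssd(f, warp_image(f, exponential_map(w$v)))
    st <- log_demons_step(f, f, w$v)
    expect_lte(st$energy, e0 * (1 + 1e-9))
  }
})

test_that("multiresolution on identical images returns a near-zero field", {
  f <- cached_phantom("blobs", 64, 6)
  res <- multiresolution_register(f, f)
  expect_lt(field_max_norm(res$disp), 0.05)
  expect_equal(dice_overlap(otsu_mask(f), otsu_mask(res$m_warped)), 1)
})

test_that("multiresolution recovers a known 3 px translation", {
  f <- cached_phantom("brainlike", 64, 7)
  m <- warp_image(f, constant_field(64, 64, 3, 0))
  res <- multiresolution_register(f, m)
  fg <- otsu_mask(f)
  # the correcting displacement is the inverse of the generating one
  expect_lt(abs(mean(res$disp[, , 1][fg]) + 3), 0.5)
  expect_lt(abs(mean(res$disp[, , 2][fg])), 0.5)
})

test_that("multiresolution reduces SSD of a smooth synthetic warp by >= 80%", {
  f <- cached_phantom("brainlike", 128, 8)
  w <- make_smooth_warp(128, 5, 8, seed = 11)
  m <- warp_image(f, w$disp)
  res <- multiresolution_register(f, m)
  expect_lt(ssd(f, res$m_warped), 0.2 * ssd(f, m))
})

test_that("energy traces descend; Thirion traces are near-monotone; results diffeomorphic", {
  f <- cached_phantom("brainlike", 64, 9)
  for (s in 1:5) {
    w <- make_smooth_warp(64, 4, 8, seed = 200 + s)
    m <- warp_image(f, w$disp)
    # the single-force (Thirion) update is a conservative descent: per-level
    # traces are non-increasing up to <= 2% transients
    res_t <- multiresolution_register(f, m, demons_config("thirion"))
    for (tr in res_t$traces) {
      if (length(tr) > 1) expect_lt(max(diff(tr)), 0.02 * tr[1])
    }
    # the symmetric force takes larger steps and may oscillate around its
    # plateau; transients stay bounded and every level still descends
    res_s <- multiresolution_register(f, m)
    for (tr in res_s$traces) {
      if (length(tr) > 1) {
        expect_lt(max(diff(tr)), 0.25 * tr[1])
        expect_lt(min(tr), tr[1])
      }
    }
    for (res in list(res_t, res_s)) {
      J <- jacobian_determinant(res$disp)
      int <- 5:60
      expect_gte(mean(J[int, int] > 0), 0.999)
    }
  }
})

test_that("registration rejects images too small for the pyramid", {
  f <- cached_phantom("blobs", 32, 1)
  expect_error(multiresolution_register(f, f, demons_config(levels = 4)),
               "too small")
})
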