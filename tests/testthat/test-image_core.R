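test_that("normalize_image rescales min-max, maps constants to zero, resizes", {
  raw <- matrix(c(10, 12, 15, 20), 2, 2)
  expect_equal(normalize_image(raw), (raw - 10) / 10)
  expect_equal(normalize_image(matrix(7, 3, 3)), matrix(0, 3, 3))
  out <- normalize_image(matrix(runif(256 * 256), 256, 256), target_size = 128)
  expect_identical(dim(out), c(128L, 128L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(normalize_image(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("warp_image implements pull-back sampling with identity and constants", {
  img <- cached_phantom("blobs", 32, 1)
  zero <- constant_field(32, 32, 0, 0)
  expect_identical(warp_image(img, zero, "nearest"), img)
  expect_lt(max(abs(warp_image(img, zero) - img)), 1e-12)
  const <- matrix(0.4, 32, 32)
  expect_equal(warp_image(const, constant_field(32, 32, 3.7, -2.1)), const)
  # unit impulse at (8,8) under uniform shift (+2,0) appears at (6,8)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  out <- warp_image(imp, constant_field(16, 16, 2, 0))
  expect_equal(out[6, 8], 1)
  expect_equal(sum(out), 1)
})

test_that("image_gradient: central differences interior, exact on ramps", {
  expect_equal(image_gradient(matrix(5, 6, 6)),
               array(0, dim = c(6, 6, 2)))
  ramp <- matrix(seq_len(8), 8, 8, byrow = TRUE)  # img(r,c) = c
  g <- image_gradient(ramp)
  expect_equal(g[2:7, 2:7, 2], matrix(1, 6, 6))
  expect_equal(g[2:7, 2:7, 1], matrix(0, 6, 6))
  sq <- matrix((seq_len(8))^2, 8, 8, byrow = TRUE) # img(r,c) = c^2
  expect_equal(image_gradient(sq)[4, 3, 2], (16 - 4) / 2)
})

test_that("intensity_centroid: point mass, weighted mean, equivariance", {
  img <- matrix(0, 10, 10); img[3, 7] <- 2.5
  expect_equal(intensity_centroid(img), c(3, 7))
  img2 <- matrix(0, 9, 5); img2[1, 1] <- 1; img2[5, 1] <- 3
  expect_equal(intensity_centroid(img2), c(4, 1))
  expect_error(intensity_centroid(matrix(0, 4, 4)), "no mass")
  # integer-shift equivariance on compactly supported content
  base <- matrix(0, 40, 40); base[15:20, 12:18] <- matrix(runif(42), 6, 7)
  shifted <- warp_image(base, constant_field(40, 40, -4, -6), "nearest")
  expect_equal(intensity_centroid(shifted), intensity_centroid(base) + c(4, 6),
               tolerance = 1e-12)
})

test_that("dice_overlap: identity, disjoint, half, empty rule, symmetry", {
  A <- matrix(FALSE, 4, 4); A[1:2, 1:2] <- TRUE
  B <- matrix(FALSE, 4, 4); B[2:3, 1:2] <- TRUE
  expect_equal(dice_overlap(A, A), 1)
  expect_equal(dice_overlap(A, !A & FALSE), 0)      # disjoint with empty-ish
  D <- matrix(FALSE, 4, 4); D[3:4, 3:4] <- TRUE
  expect_equal(dice_overlap(A, D), 0)               # disjoint nonempty
  expect_equal(dice_overlap(A, B), 0.5)             # |A|=4,|B|=4,|int|=2
  expect_equal(dice_overlap(A, B), dice_overlap(B, A))
  expect_equal(dice_overlap(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice_overlap(A, matrix(TRUE, 2, 2)), "shape")
})

test_that("otsu threshold separates a bimodal image", {
  img <- matrix(c(rep(0.1, 60), rep(0.9, 40)) + runif(100, 0, 0.05), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0.2); expect_lt(thr, 0.9)
  expect_equal(sum(otsu_mask(img)), 40)
})

test_that("ssd basic cases", {
  expect_equal(ssd(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(ssd(matrix(0, 2, 5), matrix(1, 2, 5)), 10)
  expect_equal(ssd(matrix(c(0, 0.5), 1, 2), matrix(c(0.5, 1), 1, 2)), 0.5)
})

test_that("rotation by multiples of 90 degrees is exact up to cropping", {
  img <- cached_phantom("rings", 33, 2)   # odd side: center on a pixel
  r4 <- img
  for (i in 1:4) r4 <- rotate_image(r4, 90)
  expect_lt(max(abs(r4 - img)), 1e-9)
})
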