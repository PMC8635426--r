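test_that("the trichrome stain matrix has unit-norm rows and is invertible", {
  C <- trichrome_stain_matrix()
  expect_s3_class(C, "stain_matrix")
  expect_true(all(abs(sqrt(rowSums(C$values^2)) - 1) <= 0.001))
  expect_gt(abs(det(C$values)), 1e-3)
})

test_that("degenerate stain matrices are rejected with informative errors", {
  bad <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(stain_matrix(bad), "singular")
  expect_error(stain_matrix(matrix(-trichrome_stain_matrix()$values, 3)),
               "non-negative")
  expect_error(stain_matrix(diag(3) * 2), "unit-norm")
})

test_that("rgb_to_od matches its closed forms", {
  white <- array(255, dim = c(2, 2, 3))
  expect_equal(max(abs(rgb_to_od(white)$od)), 0)
  ## decade absorbance: I = i0/10 with eps = 0
  img <- array(25.5, dim = c(1, 1, 3))
  expect_equal(as.vector(rgb_to_od(img, i0 = 255, eps = 0)$od), rep(1, 3))
  ## black pixel with the default eps = 1 guard
  black <- array(0, dim = c(1, 1, 3))
  expect_equal(as.vector(rgb_to_od(black)$od), rep(log10(256), 3))
  expect_error(rgb_to_od(array(1, dim = c(2, 2, 2))), "3")
  expect_error(rgb_to_od(white, i0 = 0), "positive")
})

test_that("pure-stain pixels map to the matrix rows and back", {
  C <- trichrome_stain_matrix()
  for (s in 1:3) {
    d <- array(0, dim = c(1, 1, 3)); d[1, 1, s] <- 1
    od <- rgb_to_od(beer_lambert_forward(d, C), i0 = 255, eps = 0)
    expect_equal(as.vector(od$od), unname(C$values[s, ]), tolerance = 1e-10)
    rec <- deconvolve(od, C)
    expect_equal(as.vector(rec$density), as.vector(d), tolerance = 1e-10)
  }
})

test_that("deconvolve solves the linear system and clips negatives", {
  C <- trichrome_stain_matrix()
  zero <- array(0, dim = c(1, 1, 3))
  expect_equal(as.vector(deconvolve(zero, C)$density), rep(0, 3))
  ## an OD of minus one stain vector is entirely infeasible: clipped to zero
  neg <- array(-C$values[1, ], dim = c(1, 1, 3))
  res <- deconvolve(neg, C)
  expect_equal(as.vector(res$density), rep(0, 3))
  expect_equal(res$clip_fraction, 1)
})

test_that("forward model then deconvolution is the identity for random densities", {
  set.seed(42)
  C <- trichrome_stain_matrix()
  d <- array(runif(40 * 40 * 3, 0, 2), dim = c(40, 40, 3))
  od <- rgb_to_od(beer_lambert_forward(d, C), i0 = 255, eps = 0)
  rec <- deconvolve(od, C)
  expect_lt(max(abs(rec$density - d)), 1e-6)
  expect_equal(rec$clip_fraction, 0)
})

test_that("collagen content recovers phantom coverage and honours its rules", {
  ph <- make_trichrome_phantom(seed = 11, collagen_fraction = 0.3)
  od <- rgb_to_od(ph$image, i0 = ph$truth$i0, eps = 0)
  res <- collagen_content(deconvolve(od), density_threshold = 0.2)
  expect_equal(res$fraction, ph$truth$collagen_fraction, tolerance = 0.01)
  ## all-white image: no tissue at all
  white <- rgb_to_od(array(255, dim = c(32, 32, 3)))
  expect_error(collagen_content(deconvolve(white), tissue_mask_od(white)),
               "empty tissue")
  ## pure red stain: blue is never the arg-max stain
  dred <- array(0, dim = c(32, 32, 3)); dred[, , 1] <- 1
  odr <- rgb_to_od(beer_lambert_forward(dred), eps = 0)
  resr <- collagen_content(deconvolve(odr))
  expect_equal(resr$fraction, 0)
})

test_that("collagen fraction is invariant to global exposure rescaling", {
  ph <- make_trichrome_phantom(seed = 5, collagen_fraction = 0.25)
  base <- collagen_content(
    deconvolve(rgb_to_od(ph$image, i0 = 255, eps = 0)))
  for (alpha in c(0.5, 0.75, 1.0)) {
    res <- collagen_content(
      deconvolve(rgb_to_od(ph$image * alpha, i0 = 255 * alpha, eps = 0)))
    expect_equal(res$fraction, base$fraction)
  }
})
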