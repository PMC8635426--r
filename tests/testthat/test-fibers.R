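test_that("orientation field recovers a sinusoidal grating's direction", {
  nr <- 128; nc <- 128
  th0 <- pi / 6  # 30 degrees
  r <- matrix(1:nr, nr, nc); c <- matrix(1:nc, nr, nc, byrow = TRUE)
  ## stripes perpendicular to the 30-degree axis run along that axis
  img <- 0.5 + 0.5 * cos(2 * pi * (c * cos(th0 + pi / 2) +
                                     r * sin(th0 + pi / 2)) / 8)
  field <- orientation_field(img, sigma = 2)
  ang <- sample_orientations(field)
  a <- alignment_statistic(ang)
  expect_gt(a$r_bar, 0.95)
  expect_lt(abs(a$mean_angle - th0), 2 * pi / 180)
})

test_that("a constant image yields no retained orientation samples", {
  field <- orientation_field(matrix(0.4, 64, 64))
  expect_true(all(field$coherence == 0))
  expect_length(sample_orientations(field), 0)
})

test_that("orientation field finds the phantom's common fibre axis", {
  ph <- make_fiber_phantom(256, 256, seed = 5, n_fibers = 120,
                           kappa = 1e7, mu = 2.0)
  a <- alignment_statistic(sample_orientations(orientation_field(ph$image)))
  d <- abs(a$mean_angle - 2.0)
  expect_lt(min(d, pi - d), 2.5 * pi / 180)
  expect_gt(a$r_bar, 0.9)
})

test_that("alignment statistic obeys its closed-form anchors", {
  expect_equal(alignment_statistic(rep(0.8, 25))$r_bar, 1)
  expect_equal(alignment_statistic(c(0, pi / 2))$r_bar, 0, tolerance = 1e-12)
  expect_error(alignment_statistic(numeric(0)), "empty")
  ## rotation invariance of r_bar
  set.seed(14)
  th <- runif(200, 0, pi)
  r0 <- alignment_statistic(th)$r_bar
  for (rot in c(0.3, 1.2, 2.9)) {
    expect_equal(alignment_statistic((th + rot) %% pi)$r_bar, r0,
                 tolerance = 1e-9)
  }
})

test_that("alignment of von Mises draws matches the Bessel-ratio expectation", {
  set.seed(22)
  th <- (0.5 * rvonmises(500, 0, 2)) %% pi
  expect_equal(alignment_statistic(th)$r_bar, bessel_ratio(2),
               tolerance = 0.05)
})

test_that("Rayleigh test matches closed forms and rejects tiny samples", {
  rt <- rayleigh_test(rep(1.2, 10))
  expect_equal(rt$z, 10)
  expect_lt(rt$p, 0.001)
  expect_error(rayleigh_test(rep(1, 3)), "n >= 4")
  ## perpendicular pairs have z = 0, p capped at 1
  rt0 <- rayleigh_test(c(0, pi / 2, 0, pi / 2))
  expect_equal(rt0$z, 0, tolerance = 1e-20)
  expect_equal(rt0$p, 1)
  ## p is rotation invariant
  set.seed(2)
  th <- runif(50, 0, pi)
  expect_equal(rayleigh_test(th)$p, rayleigh_test((th + 0.7) %% pi)$p,
               tolerance = 1e-9)
})

test_that("alignment is monotone in the phantom concentration", {
  wins <- 0L
  for (s in 1:5) {
    r <- vapply(c(0.25, 1, 4), function(k) {
      ph <- make_fiber_phantom(256, 256, seed = s + 50, n_fibers = 150,
                               kappa = k)
      alignment_statistic(ph$truth$angles)$r_bar
    }, numeric(1))
    if (r[3] > r[2] && r[2] > r[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("PCA matches the dense eigendecomposition of the correlation matrix", {
  set.seed(33)
  x <- matrix(rnorm(10 * 3), 10, 3,
              dimnames = list(NULL, c("alignment", "width", "length")))
  res <- fiber_feature_pca(x)
  oracle <- pca_eigen_oracle(x)
  expect_equal(unname(res$loadings), oracle$loadings, tolerance = 1e-8)
  expect_equal(unname(res$scores), unname(oracle$scores), tolerance = 1e-8)
  expect_equal(res$explained_variance, oracle$explained_variance,
               tolerance = 1e-10)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)
  expect_equal(sum(res$eigenvalues), ncol(x), tolerance = 1e-9)
  expect_equal(colMeans(res$scores), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA reconstruction reproduces the standardized data", {
  set.seed(34)
  x <- matrix(rnorm(12 * 4), 12, 4)
  res <- fiber_feature_pca(x)
  expect_equal(res$scores %*% t(res$loadings), unclass(scale(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA guards its preconditions", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fiber_feature_pca(x[1:2, ]), ">= 3 samples")
  expect_error(fiber_feature_pca(cbind(x, const = 1)), "zero-variance")
  ## perfectly correlated pair: PC1 carries everything
  y <- rnorm(10)
  res <- fiber_feature_pca(cbind(a = y, b = 2 * y + 3))
  expect_equal(res$explained_variance[1], 1, tolerance = 1e-12)
})

test_that("box counts are monotone and the dimension stays in [0, 2]", {
  set.seed(44)
  m <- matrix(runif(128 * 128) < 0.2, 128, 128)
  bc <- box_count_dimension(m, c(2, 4, 8, 16, 32))
  expect_true(all(diff(bc$counts) <= 0))
  expect_gte(bc$dimension, 0)
  expect_lte(bc$dimension, 2)
  expect_error(box_count_dimension(matrix(FALSE, 16, 16), c(2, 4, 8, 16)),
               "empty")
  expect_error(box_count_dimension(m, c(2, 4, 8)), ">= 4")
})

test_that("box counting hits the analytic anchors", {
  sizes <- c(2, 4, 8, 16, 32)
  sq <- make_fractal_phantom("filled_square", depth = 7)
  expect_equal(box_count_dimension(sq$mask, sizes)$dimension, 2,
               tolerance = 0.05)
  ln <- make_fractal_phantom("line", depth = 7)
  expect_equal(box_count_dimension(ln$mask, sizes)$dimension, 1,
               tolerance = 0.05)
  sp <- make_fractal_phantom("sierpinski", depth = 7)
  bc <- box_count_dimension(sp$mask, sizes)
  expect_equal(bc$dimension, log(3) / log(2), tolerance = 0.03)
  expect_gt(bc$r_squared, 0.999)
})

test_that("quantify_fibers produces coherent per-image metrics", {
  ph <- make_fiber_phantom(256, 256, seed = 61, n_fibers = 150, kappa = 6)
  fm <- quantify_fibers(ph$image)
  expect_gt(fm$n_angles, 100)
  expect_gt(fm$alignment, 0.5)
  expect_lt(fm$rayleigh_p, 1e-6)
  expect_true(fm$fractal_dimension > 0 && fm$fractal_dimension <= 2)
})
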