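test_that("phantoms are bit-identical under the same seed and differ across seeds", {
  a <- make_if_phantom(seed = 3)
  b <- make_if_phantom(seed = 3)
  c <- make_if_phantom(seed = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$nucleus_centers, b$truth$nucleus_centers)
  expect_false(identical(a$image, c$image))
  expect_equal(a$truth$n_nuclei, c$truth$n_nuclei)  # requested counts invariant
})

test_that("zero-density trichrome phantom is uniformly white", {
  ph <- make_trichrome_phantom(seed = 1,
                               density = array(0, dim = c(32, 32, 3)))
  expect_true(all(ph$image == 255))
  expect_equal(ph$truth$collagen_fraction, 0)
})

test_that("trichrome phantom truth stores the exact density planes", {
  ph <- make_trichrome_phantom(seed = 2, collagen_fraction = 0.3)
  expect_equal(ph$truth$collagen_fraction, mean(ph$truth$density[, , 2] > 0))
  expect_gte(ph$truth$collagen_fraction, 0.29)  # coverage loop reaches target
  expect_error(make_trichrome_phantom(seed = 1, blue_density = -1),
               "non-negative")
})

test_that("if phantom ground truth matches an independent component recount", {
  ph <- make_if_phantom(seed = 9, n_nuclei = 10, noise_sd = 0)
  expect_equal(recount_components_4(ph$truth$nucleus_mask), 10)
  expect_equal(sum(ph$truth$nucleus_mask), ph$truth$nucleus_area)
  ## n = 0 gives a constant-background blue channel
  ph0 <- make_if_phantom(seed = 1, n_nuclei = 0, n_red_blobs = 0,
                         n_green_blobs = 0, noise_sd = 0)
  expect_equal(ph0$truth$n_nuclei, 0)
  expect_true(all(ph0$image[, , 3] == 0.05))
})

test_that("overcrowded placement errors instead of silently under-placing", {
  expect_error(make_if_phantom(width = 32, height = 32, seed = 1,
                               n_nuclei = 200),
               "placed only")
})

test_that("clone phantom realizes exact areas and the true clone split", {
  ph <- make_clone_phantom(seed = 6,
                           areas = list(red = c(2500, 1500),
                                        green = c(2000, 100)))
  expect_equal(ph$truth$areas$red, c(2500L, 1500L))
  expect_equal(sum(ph$truth$masks$red), 4000)
  ## the 2000-px rule: 2500 and exactly-2000 are clones, others singletons
  expect_equal(ph$truth$n_clones, 2)
  expect_equal(ph$truth$n_singletons, 2)
  expect_equal(recount_components_4(ph$truth$masks$red), 2)
  ## empty request leaves the channel blank
  ph0 <- make_clone_phantom(seed = 1, areas = list(red = numeric(0)))
  expect_equal(recount_components_4(ph0$truth$masks$red), 0)
})

test_that("von Mises sampler hits its limits and its Bessel-ratio mean", {
  set.seed(8)
  expect_true(all(rvonmises(10, mu = 0.7, kappa = 1e7) == 0.7))
  th <- rvonmises(4000, 0, 2)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_equal(rbar, bessel_ratio(2), tolerance = 0.03)
  u <- rvonmises(4000, 0, 0)
  expect_gt(stats::ks.test((u + pi) / (2 * pi), "punif")$p.value, 1e-3)
  expect_error(rvonmises(5, 0, -1), "kappa")
})

test_that("fiber phantom draws axial angles from the requested law", {
  ph <- make_fiber_phantom(seed = 2, n_fibers = 500, kappa = 2)
  expect_true(all(ph$truth$angles >= 0 & ph$truth$angles < pi))
  a <- alignment_statistic(ph$truth$angles)
  expect_equal(a$r_bar, bessel_ratio(2), tolerance = 0.06)
  ph0 <- make_fiber_phantom(seed = 2, n_fibers = 64, kappa = 1e7, mu = 1.1)
  expect_true(all(abs(ph0$truth$angles - 1.1) < 1e-12))
  expect_error(make_fiber_phantom(seed = 1, kappa = -2), "kappa")
})

test_that("fractal phantoms carry their analytic dimensions", {
  expect_equal(make_fractal_phantom("filled_square")$truth$dimension, 2)
  expect_equal(make_fractal_phantom("line")$truth$dimension, 1)
  sp <- make_fractal_phantom("sierpinski", depth = 7)
  expect_equal(sp$truth$dimension, log(3) / log(2))
  expect_equal(dim(sp$mask), c(128L, 128L))
  expect_equal(sum(sp$mask), 3^7)  # Pascal-mod-2 cell count
  expect_error(make_fractal_phantom("sierpinski", depth = 20), "depth")
})
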