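test_that("label_components matches connectivity semantics", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  expect_equal(label_components(m, connectivity = 8)$n, 1)
  expect_equal(label_components(m, connectivity = 4)$n, 2)
  expect_equal(label_components(matrix(FALSE, 5, 5))$n, 0)
  ## two disks separated by background
  m2 <- matrix(FALSE, 20, 20)
  m2[2:5, 2:5] <- TRUE; m2[10:13, 10:13] <- TRUE
  cc <- label_components(m2)
  expect_equal(cc$n, 2)
  expect_equal(sort(cc$areas), c(16L, 16L))
  expect_equal(cc$centroids[1, ], c(row = 3.5, col = 3.5))
})

test_that("4-connected labelling agrees with the EBImage reference labeller", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(runif(900) < 0.35, 30, 30)
    expect_equal(label_components(m, connectivity = 4)$n,
                 recount_components_4(m))
  }
})

test_that("classify_clones applies the inclusive 2000-px rule", {
  rep1 <- classify_clones(c(2500, 1500, 100))
  expect_equal(rep1$clone_count, 1)
  expect_equal(rep1$singleton_count, 2)
  expect_equal(classify_clones(2000)$clone_count, 1)   # boundary inclusive
  expect_equal(classify_clones(1999)$clone_count, 0)
  all_small <- classify_clones(rep(100, 20))
  expect_equal(all_small$clone_count, 0)
  expect_equal(all_small$singleton_count, 20)
  expect_equal(all_small$total_clone_area, 0)
})

test_that("classify_clones partitions components and orders clone areas", {
  set.seed(3)
  areas <- sample(c(50:300, 1900:2100, 2500:4000), 40)
  rep <- classify_clones(areas)
  expect_equal(rep$clone_count + rep$singleton_count, length(areas))
  expect_true(all(diff(rep$clone_areas) <= 0))
  expect_true(all(rep$clone_areas >= 2000))
  ## invariant under permutation of the component list
  rep2 <- classify_clones(rev(areas))
  expect_equal(rep2$clone_count, rep$clone_count)
  expect_equal(rep2$clone_areas, rep$clone_areas)
})

test_that("raising clone_min_area never increases the clone count", {
  ph <- make_clone_phantom(seed = 4,
                           areas = list(red = c(3000, 2100, 1950, 800),
                                        green = c(2600, 400)))
  comp <- label_components(binarize_fixed(ph$image[, , 1]))
  counts <- vapply(c(500, 1000, 2000, 2500, 5000),
                   function(a) classify_clones(comp, a)$clone_count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quantify_clones recovers phantom classification exactly", {
  for (s in 1:6) {
    ph <- make_clone_phantom(seed = s,
                             areas = list(red = c(2600, 2000, 1999),
                                          green = c(3200, 150)))
    rep <- quantify_clones(ph$image)
    expect_equal(rep$clone_count, ph$truth$n_clones)
    expect_equal(rep$singleton_count, ph$truth$n_singletons)
    truth_areas <- unname(unlist(ph$truth$areas))
    expect_equal(sort(rep$clone_areas), sort(truth_areas[truth_areas >= 2000]))
  }
})

test_that("compare_clone_groups contrasts clone counts across groups", {
  mk <- function(n_clones) {
    structure(list(clone_count = n_clones, total_clone_area = n_clones * 2500,
                   singleton_count = 5), class = "clone_report")
  }
  groups <- list(control = lapply(c(1, 2, 1), mk),
                 treated = lapply(c(6, 7, 8), mk))
  res <- compare_clone_groups(groups, metric = "clone_count")
  expect_lt(res$p, 0.01)
  expect_equal(res$summary$mean, c(4 / 3, 7))
  expect_error(compare_clone_groups(groups["control"]), ">= 2 groups")
})
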