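test_that("distance transform matches the exhaustive oracle", {
  set.seed(11)
  for (spacing in list(c(1, 1, 1), c(0.48, 0.48, 0.6))) {
    m <- array(runif(12^3) < 0.03, c(12, 12, 12))
    if (!any(m)) m[5, 5, 5] <- TRUE
    expect_equal(distance_transform(m, spacing), oracle_distance(m, spacing),
                 tolerance = 1e-12)
  }
})

test_that("slab depth follows the analytic ratio", {
  sl <- slab_anatomy()
  d <- normalized_depth(sl, domain = sl$wm)
  # x index i sits at (i-1) mm; depth = (i-1)/40
  expect_equal(d[21, 4, 4], 0.5)
  expect_equal(d[11, 4, 4], 0.25)
  expect_equal(d[31, 4, 4], 0.75)
  # non-decreasing along any ventricle-to-cortex path
  for (j in c(2, 4, 6)) expect_true(all(diff(d[2:40, j, j]) >= 0))
  expect_true(all(d[!is.na(d)] > 0 & d[!is.na(d)] < 1))
})

test_that("depth map rejects empty or overlapping surface masks", {
  sl <- slab_anatomy()
  broken <- sl; broken$ventricle[] <- FALSE
  expect_error(normalized_depth(broken), "empty")
  overlapping <- sl; overlapping$cortex <- overlapping$ventricle
  expect_error(normalized_depth(overlapping), "overlap")
})

test_that("depth layers use half-open bins with a closed top", {
  d <- array(c(0.10, 0.25, 0.5, 0.7499, 0.75, 1.0, 0, 0.9999), c(8, 1, 1))
  expect_equal(as.vector(depth_layers(d, 4L)),
               c(1L, 2L, 3L, 3L, 4L, 4L, 1L, 4L))
  expect_error(depth_layers(d, 0L), "n_layers")
})

test_that("slab layers are equidistant to within a voxel", {
  sl <- slab_anatomy()
  d <- normalized_depth(sl, domain = sl$wm)
  ly <- depth_layers(d)
  widths <- table(ly[2:40, 4, 4])
  expect_true(max(widths) - min(widths) <= 1)
})

test_that("lobe projection matches the brute-force nearest-label search", {
  set.seed(21)
  dm <- c(10, 10, 10)
  labels <- array(0L, dm)
  labels[1, , ] <- 1L
  labels[10, , ] <- 2L
  labels[, 1, 5] <- 3L
  domain <- array(TRUE, dm); domain[labels > 0] <- FALSE
  an <- list(dim = dm, spacing = c(1, 1, 1))
  got <- project_lobes(an, lobes = labels, domain = domain)
  want <- oracle_nearest_label(labels, domain, c(1, 1, 1))
  expect_equal(got[domain], want[domain])
})

test_that("lobe projection breaks exact ties toward the lowest label", {
  dm <- c(5, 3, 3)
  labels <- array(0L, dm)
  labels[1, , ] <- 7L
  labels[5, , ] <- 2L
  domain <- array(FALSE, dm); domain[3, , ] <- TRUE  # equidistant plane
  an <- list(dim = dm, spacing = c(1, 1, 1))
  got <- project_lobes(an, lobes = labels, domain = domain)
  expect_true(all(got[domain] == 2L))
  expect_error(project_lobes(an, lobes = array(0L, dm), domain = domain),
               "empty")
})
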