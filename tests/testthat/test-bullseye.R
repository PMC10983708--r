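test_that("bullseye scheme enumerates 38 parcels and partitions the domain", {
  pc <- small_parcellation()
  tab <- pc$parcel_table
  expect_equal(nrow(tab), 38L)
  expect_equal(sort(tab$id), 1:38)
  expect_equal(sum(tab$region == "BGT"), 4L)
  expect_true(all(c("CC_anterior", "CC_posterior") %in% tab$name))

  a <- small_phantom()
  domain <- a$wm | a$bgt | a$cc_anterior | a$cc_posterior
  expect_true(all(pc$labels[domain] %in% 1:38))
  expect_true(all(pc$labels[!domain] == 0L))
  # every parcel populated on the default phantom
  expect_true(all(tabulate(pc$labels[domain], 38L) > 0))
  # re-running is bit-identical
  expect_identical(pc$labels, assemble_bullseye(a)$labels)
})

test_that("corpus callosum masks override the lobe x layer assignment", {
  a <- small_phantom()
  pc <- small_parcellation()
  expect_true(all(pc$labels[a$cc_anterior] == 37L))
  expect_true(all(pc$labels[a$cc_posterior] == 38L))
  broken <- a; broken$bgt[] <- FALSE
  expect_error(assemble_bullseye(broken), "BGT")
})

test_that("parcel volumes are exact arithmetic and conserve total volume", {
  pc <- small_parcellation()
  empty <- array(FALSE, pc$dim)
  v0 <- parcel_volumes(empty, pc)
  expect_equal(as.vector(v0), rep(0, 38))

  # 100 voxels wholly inside one parcel at 1 mm^3 -> 0.1 ml there, 0 elsewhere
  big <- which.max(tabulate(pc$labels[pc$labels > 0], 38L))
  target <- which(pc$labels == big)[1:100]
  single <- array(FALSE, pc$dim); single[target] <- TRUE
  v1 <- parcel_volumes(single, pc)
  expect_equal(as.vector(v1[big]), 0.1)
  expect_equal(sum(v1), 0.1)
  expect_equal(attr(v1, "unassigned_volume"), 0)

  # random lesion incl. voxels outside the parcellation: conservation exact
  set.seed(31)
  les <- array(runif(prod(pc$dim)) < 0.05, pc$dim)
  v2 <- parcel_volumes(les, pc)
  expect_equal(sum(v2) + attr(v2, "unassigned_volume"),
               attr(v2, "total_volume"), tolerance = 1e-12)
  expect_error(parcel_volumes(array(FALSE, c(5, 5, 5)), pc), "grid mismatch")
})

test_that("volumes scale exactly with anisotropic voxel size", {
  a <- make_phantom(phantom_spec(grid_shape = 32L,
                                 voxel_size_mm = c(0.48, 0.48, 0.6)))
  pc <- assemble_bullseye(a)
  set.seed(32)
  les <- array(runif(prod(pc$dim)) < 0.05, pc$dim) & a$wm
  v <- parcel_volumes(les, pc)
  counts <- sapply(1:38, function(id) sum(les & pc$labels == id))
  expect_equal(as.vector(v), counts * 0.48 * 0.48 * 0.6 / 1000)
})
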