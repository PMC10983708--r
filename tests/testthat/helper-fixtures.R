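# Shared fixtures and independent oracles. Fixtures are built once per run
# and memoised in this environment.

.fix <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.fix$ph32)) .fix$ph32 <- make_phantom(phantom_spec(grid_shape = 32L))
  .fix$ph32
}

small_parcellation <- function() {
  if (is.null(.fix$pc32)) .fix$pc32 <- assemble_bullseye(small_phantom())
  .fix$pc32
}

# Slab geometry: ventricle plane at x = 0 mm, cortex plane at x = 40 mm,
# 1 mm voxels. Depth along x is analytically x/40.
slab_anatomy <- function(spacing = c(1, 1, 1), nx = 41L, ny = 7L, nz = 7L) {
  dm <- c(nx, ny, nz)
  ventricle <- array(FALSE, dm); ventricle[1, , ] <- TRUE
  cortex <- array(FALSE, dm); cortex[nx, , ] <- TRUE
  wm <- array(FALSE, dm); wm[2:(nx - 1), , ] <- TRUE
  empty <- array(FALSE, dm)
  list(ventricle = ventricle, cortex = cortex, wm = wm,
       bgt = empty, cc_anterior = empty, cc_posterior = empty,
       lobes = array(0L, dm), dim = dm, spacing = spacing)
}

# Exhaustive nearest-feature-voxel distance: the independent oracle for the
# separable distance transform. O(n_voxels * n_feature) - small grids only.
oracle_distance <- function(mask, spacing) {
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  feat <- sweep(idx - 1, 2, spacing, "*")
  all_idx <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                   z = seq_len(dm[3])))
  pts <- sweep(all_idx - 1, 2, spacing, "*")
  d <- vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min(colSums((t(feat) - pts[i, ])^2)))
  }, numeric(1))
  arr <- array(NA_real_, dm)
  arr[cbind(all_idx)] <- d
  arr
}

# Exhaustive nearest-labelled-voxel assignment (lowest label wins ties):
# oracle for project_lobes.
oracle_nearest_label <- function(labels, domain, spacing) {
  dm <- dim(labels)
  lab_idx <- which(labels > 0, arr.ind = TRUE)
  lab_val <- labels[labels > 0]
  ord <- order(lab_val)           # ascending so ties keep the lowest label
  lab_idx <- lab_idx[ord, , drop = FALSE]
  lab_val <- lab_val[ord]
  pts <- sweep(lab_idx - 1, 2, spacing, "*")
  out <- array(NA_integer_, dm)
  dom_idx <- which(domain, arr.ind = TRUE)
  for (i in seq_len(nrow(dom_idx))) {
    p <- (dom_idx[i, ] - 1) * spacing
    d2 <- colSums((t(pts) - p)^2)
    j <- which(d2 < d2[which.min(d2)] + 1e-12)[1]  # first = lowest label
    out[dom_idx[i, 1], dom_idx[i, 2], dom_idx[i, 3]] <- lab_val[j]
  }
  out
}
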