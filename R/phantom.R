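#' Specification of a synthetic anatomy phantom
#'
#' Defines the geometry of a digital head phantom built from nested
#' ellipsoidal shells: a central ventricle, a white-matter shell, and a
#' cortical ribbon, split into hemispheres by the mid-sagittal plane and into
#' four lobar sectors per hemisphere by angular wedges. Subcortical grey
#' matter (basal ganglia + thalamus, "BGT") sits as paired blobs lateral to
#' the ventricles; the corpus callosum (CC) is a midline structure split into
#' anterior and posterior parts. All shapes are analytic so that distances and
#' partitions can be checked against closed forms.
#'
#' @param grid_shape integer length-3 (or scalar) voxel counts per axis.
#' @param voxel_size_mm numeric length-3 (or scalar) voxel spacing in mm.
#'   Default 1 mm isotropic.
#' @param ventricle_extent normalized ellipsoidal radius of the ventricle
#'   surface (0 < `ventricle_extent` < 1 - `cortex_thickness`).
#' @param cortex_thickness normalized radial thickness of the cortical ribbon.
#' @param lobe_sector_angles numeric length-5 increasing vector of sector
#'   boundaries in degrees, from -180 to 180, cutting the sagittal
#'   (anterior/superior) angle into the occipital, temporal, frontal and
#'   parietal sectors, in that order.
#' @param seed integer stored with the spec (the geometry itself is
#'   deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = c(1, 1, 1),
                         ventricle_extent = 0.28,
                         cortex_thickness = 0.18,
                         lobe_sector_angles = c(-180, -90, 0, 90, 180),
                         seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive values")
  if (ventricle_extent <= 0 || cortex_thickness <= 0)
    stop("ventricle_extent and cortex_thickness must be positive")
  if (ventricle_extent >= 1 - cortex_thickness)
    stop("degenerate geometry: ventricle surface touches the cortex ",
         "(ventricle_extent >= 1 - cortex_thickness)")
  if (length(lobe_sector_angles) != 5L || is.unsorted(lobe_sector_angles) ||
      lobe_sector_angles[1] != -180 || lobe_sector_angles[5] != 180)
    stop("lobe_sector_angles must be 5 increasing values from -180 to 180")
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 ventricle_extent = ventricle_extent,
                 cortex_thickness = cortex_thickness,
                 lobe_sector_angles = as.numeric(lobe_sector_angles),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Lobe / sector naming used throughout the package
#'
#' Region IDs 1-8 are the lobar divisions (4 lobes x 2 hemispheres), ID 9 is
#' the subcortical grey matter (BGT).
#' @return character vector of the 9 region names, in ID order.
#' @export
region_names <- function() {
  c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
    "temporal_L", "temporal_R", "occipital_L", "occipital_R", "BGT")
}

#' Build a synthetic anatomy phantom
#'
#' Realises a [phantom_spec()] as a set of co-registered, pairwise-disjoint
#' 3-D masks: ventricle, white matter, cortical ribbon, BGT, anterior and
#' posterior corpus callosum, plus an 8-label lobe map over the cortical
#' ribbon. The parcellation domain (where depth and parcel labels are
#' defined) is white matter plus BGT plus the CC masks.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `anatomy_phantom`: a list with logical arrays
#'   `ventricle`, `wm`, `cortex`, `bgt`, `cc_anterior`, `cc_posterior`, an
#'   integer array `lobes` (0 outside the cortex, 1-8 on it), and fields
#'   `dim`, `spacing`, `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = 32L))
#' sum(ph$wm) > 0
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$voxel_size_mm
  extent <- dm * sp
  centre <- (dm - 1) * sp / 2
  semi <- 0.45 * extent   # outer (cortical) surface semi-axes, mm

  # normalized coordinates of voxel centres
  xs <- ((seq_len(dm[1]) - 1) * sp[1] - centre[1]) / semi[1]
  ys <- ((seq_len(dm[2]) - 1) * sp[2] - centre[2]) / semi[2]
  zs <- ((seq_len(dm[3]) - 1) * sp[3] - centre[3]) / semi[3]
  X <- array(rep(xs, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)
  R <- sqrt(X^2 + Y^2 + Z^2)

  r_vent <- spec$ventricle_extent
  r_wm <- 1 - spec$cortex_thickness
  ventricle <- R <= r_vent
  shell <- R > r_vent & R <= r_wm
  cortex <- R > r_wm & R <= 1

  if (!any(ventricle) || !any(cortex) || !any(shell))
    stop("degenerate geometry: a mask is empty at this grid resolution")

  # BGT: paired blobs lateral to the ventricles, clipped to the shell;
  # elongated radially so all four depth layers are represented
  bgt <- (((abs(X) - 0.52) / 0.30)^2 + (Y / 0.24)^2 +
            ((Z + 0.05) / 0.24)^2) <= 1 & shell

  # corpus callosum: midline band adjacent to the ventricle
  cc_band <- abs(X) <= 0.08 & R <= 0.55 & abs(Z) <= 0.35 & shell
  cc_anterior <- cc_band & Y > 0.05
  cc_posterior <- cc_band & Y < -0.05

  wm <- shell & !bgt & !cc_anterior & !cc_posterior

  # lobe labels over the cortical ribbon: hemisphere (sagittal split) x
  # angular sector in the (anterior, superior) plane
  phi <- atan2(Z, Y) * 180 / pi
  ang <- spec$lobe_sector_angles
  sector <- findInterval(phi, ang, rightmost.closed = TRUE)  # 1..4
  lobe_of_sector <- c(7L, 5L, 1L, 3L)  # occipital, temporal, frontal, parietal (L)
  lobes <- array(0L, dm)
  lobes[cortex] <- lobe_of_sector[sector[cortex]] + as.integer(X[cortex] >= 0)

  structure(list(ventricle = ventricle, wm = wm, cortex = cortex, bgt = bgt,
                 cc_anterior = cc_anterior, cc_posterior = cc_posterior,
                 lobes = lobes, dim = dm, spacing = sp, spec = spec),
            class = "anatomy_phantom")
}

#' @export
print.anatomy_phantom <- function(x, ...) {
  cat("Anatomy phantom", paste(x$dim, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  counts <- vapply(x[c("ventricle", "wm", "cortex", "bgt",
                       "cc_anterior", "cc_posterior")], sum, numeric(1))
  for (nm in names(counts)) cat(sprintf("  %-13s %8d voxels\n", nm, counts[nm]))
  invisible(x)
}

# parcellation domain: everything between ventricle and cortex surfaces
.phantom_domain <- function(anatomy) {
  anatomy$wm | anatomy$bgt | anatomy$cc_anterior | anatomy$cc_posterior
}
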