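#' Normalized ventricle-to-cortex depth map
#'
#' For every voxel of the parcellation domain computes
#' `d_vent / (d_vent + d_cortex)`, where `d_vent` and `d_cortex` are the
#' spacing-aware Euclidean distances (mm) to the nearest ventricle and
#' cortex voxel respectively. Values approach 0 at the ventricular surface
#' and 1 at the cortical surface.
#'
#' @param anatomy an `anatomy_phantom` or any list with logical arrays
#'   `ventricle`, `cortex` and fields `dim`, `spacing`, plus the masks that
#'   define the parcellation domain (`wm`, `bgt`, `cc_anterior`,
#'   `cc_posterior`).
#' @param domain optional logical array overriding the parcellation domain.
#' @return numeric array; `NA` outside the domain, depth in \[0, 1\] on it.
#' @export
normalized_depth <- function(anatomy, domain = NULL) {
  if (is.null(domain)) domain <- .phantom_domain(anatomy)
  if (!any(anatomy$ventricle)) stop("ventricle mask is empty")
  if (!any(anatomy$cortex)) stop("cortex mask is empty")
  if (any(anatomy$ventricle & anatomy$cortex))
    stop("ventricle and cortex masks overlap")
  dv <- distance_transform(anatomy$ventricle, anatomy$spacing)
  dc <- distance_transform(anatomy$cortex, anatomy$spacing)
  tot <- dv + dc
  if (any(tot[domain] == 0))
    stop("voxel with zero distance to both surfaces inside the domain; ",
         "masks overlap the domain")
  depth <- array(NA_real_, anatomy$dim)
  depth[domain] <- dv[domain] / tot[domain]
  depth
}

#' Equidistant depth layers
#'
#' Bins a normalized depth map into `n_layers` concentric, equidistant layers
#' around the ventricles. Bins are half-open with a closed top:
#' `[0, .25) [.25, .5) [.5, .75) [.75, 1]` for the default four layers, so a
#' depth exactly on a boundary falls in the upper layer.
#'
#' @param depth numeric array from [normalized_depth()] (NA outside domain).
#' @param n_layers integer >= 1, default 4.
#' @return integer array of layer indices 1..n_layers (NA outside domain).
#' @export
depth_layers <- function(depth, n_layers = 4L) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  layer <- pmin(floor(depth * n_layers) + 1L, n_layers)
  storage.mode(layer) <- "integer"
  layer
}

#' Project cortical lobe labels into the white matter
#'
#' Assigns to each voxel of the parcellation domain the label of the
#' Euclidean-nearest labelled cortical voxel (spacing-aware), i.e. the lobe
#' labels are pushed inward from the cortical ribbon until they reach the
#' ventricles. Exact distance ties are broken toward the lowest label ID.
#'
#' @inheritParams normalized_depth
#' @param lobes integer array of cortical labels (0 = unlabelled); defaults
#'   to `anatomy$lobes`.
#' @return integer array of lobe labels over the domain (NA outside).
#' @export
project_lobes <- function(anatomy, lobes = anatomy$lobes, domain = NULL) {
  if (is.null(domain)) domain <- .phantom_domain(anatomy)
  ids <- sort(unique(lobes[lobes > 0L]))
  if (length(ids) == 0L) stop("lobe label map is empty")
  best_d2 <- array(Inf, anatomy$dim)
  best_id <- array(NA_integer_, anatomy$dim)
  for (id in ids) {
    d2 <- .edt_squared(lobes == id, anatomy$spacing)
    take <- domain & d2 < best_d2   # strict < keeps the lowest ID on ties
    best_d2[take] <- d2[take]
    best_id[take] <- id
  }
  best_id
}

#' Parcel lookup table for the 38-parcel bullseye scheme
#'
#' Parcels 1-36 are the 9 regions (8 lobar divisions + BGT) crossed with the
#' 4 depth layers; parcels 37 and 38 are the anterior and posterior corpus
#' callosum, which are kept separate from the layer scheme.
#'
#' @param n_layers number of depth layers (default 4).
#' @return data.frame with columns `id`, `name`, `region`, `hemisphere`,
#'   `layer` (layer and hemisphere are `NA` for the CC parcels).
#' @export
parcel_table <- function(n_layers = 4L) {
  regions <- region_names()
  tab <- expand.grid(layer = seq_len(n_layers), region = regions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[order(match(tab$region, regions), tab$layer), ]
  tab$id <- seq_len(nrow(tab))
  hemi <- ifelse(grepl("_L$", tab$region), "L",
                 ifelse(grepl("_R$", tab$region), "R", NA))
  out <- data.frame(id = tab$id,
                    name = paste0(tab$region, "_", tab$layer),
                    region = sub("_[LR]$", "", tab$region),
                    hemisphere = hemi,
                    layer = tab$layer,
                    stringsAsFactors = FALSE)
  ncc <- nrow(out)
  out <- rbind(out,
               data.frame(id = ncc + 1L, name = "CC_anterior",
                          region = "CC_anterior", hemisphere = NA,
                          layer = NA_integer_, stringsAsFactors = FALSE),
               data.frame(id = ncc + 2L, name = "CC_posterior",
                          region = "CC_posterior", hemisphere = NA,
                          layer = NA_integer_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Assemble the bullseye parcellation
#'
#' Crosses the depth layers with the projected lobe labels and the BGT mask
#' (9 regions x 4 layers = 36 parcels) and adds the anterior and posterior
#' corpus callosum as two standalone parcels (38 in total). The CC masks take
#' precedence over any lobe x layer assignment.
#'
#' @param anatomy an `anatomy_phantom`.
#' @param layers integer array from [depth_layers()]; computed if `NULL`.
#' @param lobe_labels integer array from [project_lobes()]; computed if `NULL`.
#' @param n_layers number of depth layers (default 4).
#' @return object of class `parcellation_map`: list with integer array
#'   `labels` (0 = background), data.frame `parcel_table`, `dim`, `spacing`.
#' @export
assemble_bullseye <- function(anatomy, layers = NULL, lobe_labels = NULL,
                              n_layers = 4L) {
  if (!any(anatomy$bgt)) stop("BGT mask is empty or missing")
  if (!any(anatomy$cc_anterior) || !any(anatomy$cc_posterior))
    stop("corpus callosum masks are empty or missing")
  if (is.null(layers)) layers <- depth_layers(normalized_depth(anatomy), n_layers)
  if (is.null(lobe_labels)) lobe_labels <- project_lobes(anatomy)
  tab <- parcel_table(n_layers)
  labels <- array(0L, anatomy$dim)

  wmv <- anatomy$wm
  labels[wmv] <- (lobe_labels[wmv] - 1L) * n_layers + layers[wmv]
  bgtv <- anatomy$bgt
  labels[bgtv] <- 8L * n_layers + layers[bgtv]
  # CC override: these voxels are CC parcels regardless of depth layer
  labels[anatomy$cc_anterior] <- 8L * n_layers + n_layers + 1L
  labels[anatomy$cc_posterior] <- 8L * n_layers + n_layers + 2L

  structure(list(labels = labels, parcel_table = tab,
                 dim = anatomy$dim, spacing = anatomy$spacing),
            class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  cat("Bullseye parcellation:", nrow(x$parcel_table), "parcels on a",
      paste(x$dim, collapse = " x "), "grid\n")
  invisible(x)
}

#' Per-parcel lesion volumes for one subject
#'
#' @param lesion_mask logical/0-1 array on the same grid as the parcellation.
#' @param parcellation a `parcellation_map`.
#' @param voxel_size_mm voxel spacing (mm); defaults to the parcellation's.
#' @return named numeric vector of the parcel volumes in ml, plus attributes
#'   `total_volume` and `unassigned_volume` (ml). Lesion voxels outside every
#'   parcel are counted as unassigned.
#' @export
parcel_volumes <- function(lesion_mask, parcellation,
                           voxel_size_mm = parcellation$spacing) {
  if (!all(dim(lesion_mask) == parcellation$dim))
    stop("grid mismatch: lesion mask is ",
         paste(dim(lesion_mask), collapse = "x"), ", parcellation is ",
         paste(parcellation$dim, collapse = "x"))
  lesion <- lesion_mask > 0
  vox_ml <- prod(voxel_size_mm) / 1000
  tab <- parcellation$parcel_table
  lab <- parcellation$labels[lesion]
  counts <- tabulate(lab, nbins = nrow(tab))
  vols <- counts * vox_ml
  names(vols) <- tab$name
  n_lesion <- sum(lesion)
  # conservation is exact at the voxel-count level
  structure(vols, total_volume = n_lesion * vox_ml,
            unassigned_volume = (n_lesion - sum(counts)) * vox_ml)
}

#' Per-parcel lesion volumes for a list of subjects
#'
#' @param lesion_masks list of binary lesion arrays (one per subject).
#' @param parcellation a `parcellation_map`.
#' @param voxel_size_mm voxel spacing in mm.
#' @return data.frame (one row per subject): 38 parcel columns (ml) plus
#'   `total_volume` and `unassigned_volume`.
#' @export
parcel_volume_table <- function(lesion_masks, parcellation,
                                voxel_size_mm = parcellation$spacing) {
  rows <- lapply(lesion_masks, function(m) {
    v <- parcel_volumes(m, parcellation, voxel_size_mm)
    c(v, total_volume = attr(v, "total_volume"),
      unassigned_volume = attr(v, "unassigned_volume"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# column names of the parcel volumes inside a volume table
.parcel_cols <- function(volumes) {
  setdiff(colnames(volumes),
          c("subject", "total_volume", "unassigned_volume"))
}
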