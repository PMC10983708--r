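#' Read a mask or label volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @param binarize treat the volume as a (possibly probabilistic) mask and
#'   binarize at > 0.5 (with a warning when any value is neither 0 nor 1).
#'   Set `FALSE` for integer label maps.
#' @return list with `data` (logical or integer array), `spacing` (mm) and
#'   the underlying `niftiImage`.
#' @export
read_mask_volume <- function(path, binarize = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (binarize) {
    if (!all(arr %in% c(0, 1))) {
      warning("non-binary mask ", basename(path), ": binarized at > 0.5")
      arr <- arr > 0.5
    } else arr <- arr > 0.5
  } else {
    storage.mode(arr) <- "integer"
  }
  list(data = arr, spacing = as.numeric(spacing), image = img)
}

#' Write a mask or label volume as NIfTI-1
#'
#' @param data logical or integer 3-D array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param spacing voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(data, path, spacing = c(1, 1, 1)) {
  arr <- data
  storage.mode(arr) <- if (is.logical(data)) "integer" else storage.mode(arr)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble an anatomy object from mask files
#'
#' Reads the six masks plus the lobe label map and checks that all grids
#' match; errors listing the offending shapes otherwise.
#'
#' @param ventricle,cortex,bgt,cc_anterior,cc_posterior,wm paths to binary
#'   masks (`wm` optional: derived as the complement of the other masks
#'   within the lobes' bounding domain is not attempted — supply it).
#' @param lobes path to the integer lobe label map over the cortex.
#' @return an `anatomy_phantom`-compatible list.
#' @export
anatomy_from_files <- function(ventricle, cortex, wm, bgt,
                               cc_anterior, cc_posterior, lobes) {
  paths <- list(ventricle = ventricle, cortex = cortex, wm = wm, bgt = bgt,
                cc_anterior = cc_anterior, cc_posterior = cc_posterior)
  vols <- lapply(paths, read_mask_volume)
  lob <- read_mask_volume(lobes, binarize = FALSE)
  dims <- lapply(c(vols, list(lobes = lob)), function(v) dim(v$data))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("mismatched grids across inputs: ",
         paste(names(dims), vapply(dims, paste, "", collapse = "x"),
               sep = "=", collapse = ", "))
  out <- lapply(vols, `[[`, "data")
  out$lobes <- lob$data
  out$dim <- dim(lob$data)
  out$spacing <- vols$ventricle$spacing
  class(out) <- "anatomy_phantom"
  out
}

#' Simulate a full synthetic WMH study
#'
#' Builds the phantom anatomy and its bullseye parcellation, draws a cohort
#' with planted covariate and cognition effects, generates one lesion mask
#' per subject from the pattern templates and the subject's factor scores,
#' and tabulates per-parcel lesion volumes. This is the input-generating
#' stage of the pipeline and of every planted-recovery experiment.
#'
#' @param n_subjects number of subjects.
#' @param phantom a [phantom_spec()].
#' @param k number of planted pattern templates (2-4).
#' @param cohort_spec a [cohort_gen_spec()]; its `n_subjects` is overridden.
#' @param noise_sd,threshold,fwhm_mm lesion-field parameters (see
#'   [sample_subject_lesions()]).
#' @param seed RNG seed.
#' @param keep_masks keep the per-subject lesion masks in the result
#'   (memory-heavy; default `FALSE`).
#' @return list with `anatomy`, `parcellation`, `templates`, `volumes`
#'   (parcel-volume table), `cohort` (with planted `truth` attribute) and
#'   `truth` (the ground-truth list).
#' @export
simulate_wmh_study <- function(n_subjects = 300L,
                               phantom = phantom_spec(),
                               k = 4L,
                               cohort_spec = cohort_gen_spec(),
                               noise_sd = 0.6, threshold = 1.4,
                               fwhm_mm = 6, seed = NULL,
                               keep_masks = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cohort_spec$n_subjects <- as.integer(n_subjects)
  cohort_spec$seed <- NULL   # seeding handled here
  anatomy <- make_phantom(phantom)
  parcellation <- assemble_bullseye(anatomy)
  templates <- make_pattern_templates(anatomy, k, parcellation)

  cohort <- sample_cohort(cohort_spec)
  truth <- attr(cohort, "truth")
  fs <- truth$factor_scores[, names(templates), drop = FALSE]

  domain <- .phantom_domain(anatomy)
  didx <- which(domain)
  Tm <- vapply(templates, function(w) w[didx], numeric(length(didx)))
  labs <- parcellation$labels[didx]
  vox_ml <- prod(anatomy$spacing) / 1000
  ntab <- nrow(parcellation$parcel_table)

  masks <- if (keep_masks) vector("list", n_subjects) else NULL
  vols <- matrix(0, n_subjects, ntab)
  total <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    field <- as.vector(Tm %*% fs[i, ])
    if (noise_sd > 0)
      field <- field + .smooth_noise(anatomy$dim, anatomy$spacing,
                                     sd = noise_sd, fwhm_mm = fwhm_mm)[didx]
    lesion <- field > threshold
    vols[i, ] <- tabulate(labs[lesion], nbins = ntab) * vox_ml
    total[i] <- sum(lesion) * vox_ml
    if (keep_masks) {
      m <- array(FALSE, anatomy$dim)
      m[didx[lesion]] <- TRUE
      masks[[i]] <- m
    }
  }
  volumes <- as.data.frame(vols)
  names(volumes) <- parcellation$parcel_table$name
  volumes$total_volume <- total
  volumes$unassigned_volume <- total - rowSums(vols)

  list(anatomy = anatomy, parcellation = parcellation,
       templates = templates, volumes = volumes, cohort = cohort,
       truth = truth, masks = masks,
       params = list(noise_sd = noise_sd, threshold = threshold,
                     fwhm_mm = fwhm_mm, k = k, seed = seed))
}

#' Pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param k number of components (and planted templates).
#' @param grid_shape,voxel_size_mm phantom geometry.
#' @param centiloid_cutoff Centiloid cutoff for amyloid status.
#' @param loading_threshold display threshold for the bullseye export.
#' @param predictors risk-factor columns for the tiered models.
#' @param subgroup `"combined"`, `"CU"` or `"MCI"`.
#' @param seed RNG seed for the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 300L, k = 4L, grid_shape = 64L,
                            voxel_size_mm = 1, centiloid_cutoff = 12,
                            loading_threshold = 0.4,
                            predictors = c("hypertension", "abeta12",
                                           "apoe4", "sex", "renal"),
                            subgroup = "combined", seed = 1L) {
  structure(list(n_subjects = as.integer(n_subjects), k = as.integer(k),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 centiloid_cutoff = centiloid_cutoff,
                 loading_threshold = loading_threshold,
                 predictors = predictors, subgroup = subgroup,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> decompose -> associate and writes every table as
#' CSV (UTF-8, header row), the resolved configuration and a manifest with
#' an MD5 checksum per output as JSON. Deterministic given the seed.
#'
#' @param config a [pipeline_config()] (a plain list is coerced).
#' @param out output directory (created if needed).
#' @param from,to first/last stage to run, among
#'   `c("simulate", "decompose", "associate")`; later stages read the CSVs
#'   of earlier ones from `out`.
#' @return path of the manifest file, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out, from = "simulate",
                         to = "associate") {
  stages <- c("simulate", "decompose", "associate")
  from_i <- match(match.arg(from, stages), stages)
  to_i <- match(match.arg(to, stages), stages)
  if (from_i > to_i) stop("'from' stage is after 'to' stage")
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out, ...)
  written <- character(0)
  emit <- function(obj, name) {
    write.csv(obj, fp(name), row.names = FALSE)
    written <<- c(written, name)
  }

  if (from_i <= 1 && to_i >= 1) {
    sim <- simulate_wmh_study(n_subjects = config$n_subjects,
                              phantom = phantom_spec(
                                grid_shape = config$grid_shape,
                                voxel_size_mm = config$voxel_size_mm),
                              k = config$k, seed = config$seed)
    emit(sim$volumes, "volumes.csv")
    emit(sim$cohort, "cohort.csv")
    emit(sim$parcellation$parcel_table, "parcel_table.csv")
    for (m in c("ventricle", "wm", "cortex", "bgt",
                "cc_anterior", "cc_posterior")) {
      write_mask_volume(sim$anatomy[[m]], fp(paste0(m, ".nii.gz")),
                        sim$anatomy$spacing)
      written <- c(written, paste0(m, ".nii.gz"))
    }
    write_mask_volume(sim$anatomy$lobes, fp("lobes.nii.gz"),
                      sim$anatomy$spacing)
    write_mask_volume(sim$parcellation$labels, fp("parcellation.nii.gz"),
                      sim$anatomy$spacing)
    written <- c(written, "lobes.nii.gz", "parcellation.nii.gz")
    truth <- attr(sim$cohort, "truth")
    jsonlite::write_json(list(age_betas = truth$age_betas,
                              hyp_betas = truth$hyp_betas,
                              interaction_beta = truth$cognition$interaction_beta,
                              interaction_component = truth$cognition$interaction_component),
                         fp("truth.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, "truth.json")
  }

  if (to_i >= 2) {
    volumes <- read.csv(fp("volumes.csv"), check.names = FALSE)
    fit <- wmh_pca(volumes, k = config$k)
    if (from_i <= 2) {
      L <- data.frame(parcel = rownames(fit$loadings), fit$loadings,
                      check.names = FALSE)
      emit(L, "loadings.csv")
      emit(as.data.frame(fit$phi), "phi.csv")
      emit(as.data.frame(fit$scores), "scores.csv")
      emit(variance_explained(fit), "variance_explained.csv")
      emit(threshold_loadings(fit, config$loading_threshold),
           "bullseye_export.csv")
    }
  }

  if (to_i >= 3) {
    cohort <- read.csv(fp("cohort.csv"), check.names = FALSE)
    scores <- as.matrix(read.csv(fp("scores.csv"), check.names = FALSE))
    assoc <- do.call(rbind, lapply(config$predictors, function(pr) {
      do.call(rbind, lapply(colnames(scores), function(cc) {
        tiers <- fit_tiered_models(scores, cohort, pr, cc,
                                   subgroup = config$subgroup)
        do.call(rbind, lapply(tiers, function(m) {
          td <- m$terms
          td$predictor <- pr; td$component <- cc
          td$tier <- m$tier; td$n <- m$n; td$adj_r2 <- m$adj_r2
          td
        }))
      }))
    }))
    emit(assoc, "associations.csv")
    cog <- do.call(rbind, lapply(colnames(scores), function(cc) {
      m <- fit_cognition_models(scores, cohort, "episodic_memory", cc,
                                interaction = TRUE,
                                cutoff = config$centiloid_cutoff)
      it <- paste0(cc, ":abeta")
      row <- m$terms[m$terms$term == it, ]
      data.frame(component = cc, interaction_beta = row$estimate,
                 ci_lo = row$ci_lo, ci_hi = row$ci_hi, p = row$p,
                 robust_lo = row$robust_lo, robust_hi = row$robust_hi,
                 lrt_p = m$lrt_p, delta_adj_r2 = m$delta_adj_r2,
                 n = m$n, stringsAsFactors = FALSE)
    }))
    emit(cog, "cognition.csv")
    burden <- comorbidity_burden_analysis(scores, cohort)
    emit(burden$summary, "comorbidity_summary.csv")
    emit(burden$tests, "comorbidity_tests.csv")
  }

  jsonlite::write_json(unclass(config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, "config.json")
  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(fp(written))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(fp("manifest.json"))
}
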