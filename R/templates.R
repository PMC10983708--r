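#' Spatial lesion-pattern templates
#'
#' Builds up to four nonnegative weight volumes over the parcellation domain,
#' each concentrated in the region where one of the canonical WMH covariation
#' patterns lives: `posterior` (occipital white matter plus periventricular
#' parietal), `deep` (outer layers 3-4 of the frontal, parietal and temporal
#' white matter), `periventricular` (depth layer 1 of the lobar white
#' matter), and `BGT` (subcortical grey matter). Lesion fields are built as
#' weighted sums of these templates, so each template is the ground-truth
#' loading pattern of one planted component.
#'
#' @param anatomy an `anatomy_phantom`.
#' @param k number of templates, 2, 3 or 4. `k = 2` keeps
#'   posterior + deep, `k = 3` adds periventricular, `k = 4` adds BGT.
#' @param parcellation optional `parcellation_map` (computed if `NULL`).
#' @return list of class `pattern_templates`: elements are named nonnegative
#'   arrays; the parcellation used is attached as an attribute.
#' @export
make_pattern_templates <- function(anatomy, k = 4L, parcellation = NULL) {
  k <- as.integer(k)
  if (!k %in% 2:4) stop("k must be 2, 3 or 4")
  if (is.null(parcellation)) parcellation <- assemble_bullseye(anatomy)
  lab <- parcellation$labels
  tab <- parcellation$parcel_table

  ids_of <- function(regions, layers = 1:4) {
    idx <- which(tab$name %in% paste0(rep(regions, each = length(layers)), "_",
                                      rep(layers, times = length(regions))))
    tab$id[idx]
  }
  lobar <- c("frontal_L", "frontal_R", "parietal_L", "parietal_R",
             "temporal_L", "temporal_R")

  tmpl <- list()
  posterior <- array(0, anatomy$dim)
  posterior[lab %in% ids_of(c("occipital_L", "occipital_R"))] <- 1
  posterior[lab %in% ids_of(c("parietal_L", "parietal_R"), layers = 1L)] <- 0.6
  tmpl$posterior <- posterior

  deep <- array(0, anatomy$dim)
  deep[lab %in% ids_of(lobar, layers = 3:4)] <- 1
  tmpl$deep <- deep

  if (k >= 3L) {
    priv <- array(0, anatomy$dim)
    priv[lab %in% ids_of(lobar, layers = 1L)] <- 1
    tmpl$periventricular <- priv
  }
  if (k >= 4L) {
    bgt <- array(0, anatomy$dim)
    bgt[lab %in% ids_of("BGT")] <- 1
    tmpl$BGT <- bgt
  }
  structure(tmpl, class = "pattern_templates", parcellation = parcellation)
}

#' Ground-truth per-parcel profile of each template
#'
#' The mean template weight within each parcel, i.e. the planted spatial
#' pattern expressed on the 38-parcel grid. Used as the reference when
#' checking that the decomposition recovers the planted components.
#'
#' @param templates a `pattern_templates` object.
#' @param parcellation a `parcellation_map` (defaults to the one attached to
#'   the templates).
#' @return matrix, parcels x templates.
#' @export
template_parcel_profiles <- function(templates,
                                     parcellation = attr(templates, "parcellation")) {
  tab <- parcellation$parcel_table
  lab <- parcellation$labels
  sapply(templates, function(w) {
    m <- vapply(tab$id, function(id) {
      v <- w[lab == id]
      if (length(v)) mean(v) else 0
    }, numeric(1))
    names(m) <- tab$name
    m
  })
}

# spatially smoothed, variance-normalised Gaussian noise field
.smooth_noise <- function(dm, spacing, sd = 1, fwhm_mm = 6) {
  eps <- array(rnorm(prod(dm)), dm)
  if (fwhm_mm > 0) {
    sigma <- fwhm_mm / 2.3548 / spacing          # in voxels, per axis
    kern1 <- function(n, s) {
      x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # wrap-around offsets
      k <- exp(-x^2 / (2 * s^2))
      k / sum(k)
    }
    K <- outer(outer(kern1(dm[1], sigma[1]), kern1(dm[2], sigma[2])),
               kern1(dm[3], sigma[3]))
    eps <- Re(fft(fft(eps) * fft(K), inverse = TRUE)) / prod(dm)
  }
  eps * (sd / stats::sd(as.vector(eps)))
}

#' Sample a lesion mask for one subject
#'
#' The lesion field is the factor-score-weighted sum of the pattern
#' templates plus a spatially smoothed Gaussian noise field; the binary
#' lesion mask is the part of the parcellation domain where the field
#' exceeds `threshold`.
#'
#' @param anatomy an `anatomy_phantom`.
#' @param templates a `pattern_templates` object.
#' @param factor_scores numeric vector, one score per template.
#' @param noise_sd standard deviation of the spatial noise field (0 = none).
#' @param threshold field threshold above which a voxel is lesion.
#' @param fwhm_mm smoothing width (FWHM, mm) of the noise field.
#' @param noise_field optional pre-generated noise array (overrides
#'   `noise_sd`); used to hold noise fixed across calls.
#' @return logical lesion mask (subset of the parcellation domain).
#' @export
sample_subject_lesions <- function(anatomy, templates, factor_scores,
                                   noise_sd = 0.6, threshold = 1.4,
                                   fwhm_mm = 6, noise_field = NULL) {
  if (length(factor_scores) != length(templates))
    stop("factor_scores length must equal the number of templates")
  if (any(!is.finite(factor_scores))) stop("non-finite factor scores")
  field <- array(0, anatomy$dim)
  for (j in seq_along(templates))
    field <- field + factor_scores[j] * templates[[j]]
  if (!is.null(noise_field)) {
    field <- field + noise_field
  } else if (noise_sd > 0) {
    field <- field + .smooth_noise(anatomy$dim, anatomy$spacing,
                                   sd = noise_sd, fwhm_mm = fwhm_mm)
  }
  field > threshold & .phantom_domain(anatomy)
}

#' Draw correlated factor scores
#'
#' @param n number of subjects.
#' @param covariance k x k positive-definite factor covariance matrix.
#' @return n x k matrix of factor scores.
#' @export
sample_factor_scores <- function(n, covariance) {
  if (!isSymmetric(unname(covariance)) ||
      any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("covariance must be symmetric positive-definite")
  MASS::mvrnorm(n, mu = rep(0, ncol(covariance)), Sigma = covariance)
}

#' Default factor covariance
#'
#' Unit variances; the three white-matter patterns intercorrelate at 0.3 and
#' the BGT pattern correlates weakly (0.1) with the others, mirroring the
#' observation that subcortical grey matter hyperintensities covary less
#' with the lobar white-matter patterns.
#'
#' @param k number of factors (2-4).
#' @return k x k covariance matrix.
#' @export
default_factor_covariance <- function(k = 4L) {
  S <- matrix(0.3, k, k)
  diag(S) <- 1
  if (k >= 4L) {
    S[4, 1:3] <- S[1:3, 4] <- 0.1
  }
  S
}
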