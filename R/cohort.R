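#' Specification of a synthetic cohort
#'
#' Describes how to draw a per-subject covariate table with planted effects.
#' Default prevalences and moments emulate a memory-clinic research cohort of
#' older adults: median age in the mid-60s, about a third hypertensive,
#' roughly a quarter mildly cognitively impaired, and an amyloid-PET burden
#' distribution in Centiloid units with about 32% of subjects above the
#' 12-CL subtle-pathology cutoff.
#'
#' Planted structure (the ground truth returned with every generated table):
#' \itemize{
#'   \item factor scores: `f = age_z * age_betas + hypertension * hyp_betas +
#'     eta`, with `eta` drawn from `factor_covariance`;
#'   \item cognition: each domain's latent score is a linear model in
#'     standardized age, standardized education, sex, amyloid status and the
#'     factor scores, including an amyloid x factor interaction on episodic
#'     memory; observed test scores add independent test noise.
#' }
#'
#' @param n_subjects number of subjects.
#' @param prevalences named list of Bernoulli probabilities for the binary
#'   covariates (`hypertension`, `cardiac`, `vascular`, `renal`,
#'   `endocrine_metabolic`, `respiratory`, `sleep_disorder`, `alcohol_use`,
#'   `apoe4`, `male`, `smoking_current`, `smoking_former`, `amyloid_positive`).
#' @param age_mean,age_sd,age_range age distribution (years; truncated normal).
#' @param education_mean,education_sd years of education.
#' @param activity_mean,activity_sd physical-activity score (truncated at 0).
#' @param age_betas,hyp_betas planted effects of standardized age and of
#'   hypertension on the (named) spatial factors.
#' @param factor_covariance covariance of the latent factor residuals.
#' @param cognition list describing the cognition model; see Details in the
#'   package vignette. Fields: `domains` (named test counts), `betas` (named
#'   coefficient vectors `intercept`, `age`, `education`, `sex`, `abeta`),
#'   `component_betas` (domain x factor main effects), `interaction_beta`,
#'   `interaction_component`, `interaction_domain`, `noise_sd` (per domain),
#'   `test_noise_sd`.
#' @param missing_rates named list of per-subject missingness probabilities.
#' @param seed integer or `NULL` (use the current RNG state).
#' @return object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_subjects = 300L,
                            prevalences = list(),
                            age_mean = 66.2, age_sd = 8.1,
                            age_range = c(50, 89),
                            education_mean = 15.4, education_sd = 2.8,
                            activity_mean = 25.3, activity_sd = 17,
                            age_betas = c(posterior = 0.69, deep = 0.44,
                                          periventricular = 0.61, BGT = 0.15),
                            hyp_betas = c(posterior = 0, deep = 0.5,
                                          periventricular = 0, BGT = 0.5),
                            factor_covariance = default_factor_covariance(4L),
                            cognition = default_cognition_model(),
                            missing_rates = list(physical_activity = 0.050,
                                                 alcohol_use = 0.045,
                                                 episodic_memory = 0.014,
                                                 executive = 0.018,
                                                 processing_speed = 0.005),
                            seed = NULL) {
  prev <- modifyList(list(hypertension = 0.337, cardiac = 0.216,
                          vascular = 0.203, renal = 0.135,
                          endocrine_metabolic = 0.700, respiratory = 0.280,
                          sleep_disorder = 0.288, alcohol_use = 0.208,
                          apoe4 = 0.239, male = 0.532,
                          smoking_current = 0.158, smoking_former = 0.366,
                          amyloid_positive = 0.32),
                     prevalences)
  bad <- unlist(prev) < 0 | unlist(prev) > 1
  if (any(bad)) stop("prevalences must be probabilities in [0, 1]: ",
                     paste(names(prev)[bad], collapse = ", "))
  if (n_subjects < 1) stop("n_subjects must be positive")
  structure(list(n_subjects = as.integer(n_subjects), prevalences = prev,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 education_mean = education_mean, education_sd = education_sd,
                 activity_mean = activity_mean, activity_sd = activity_sd,
                 age_betas = age_betas, hyp_betas = hyp_betas,
                 factor_covariance = factor_covariance,
                 cognition = cognition, missing_rates = missing_rates,
                 seed = seed),
            class = "cohort_gen_spec")
}

#' Default planted cognition model
#'
#' Older age predicts worse performance in all domains, education protects,
#' male sex predicts slightly worse memory, amyloid status has no main
#' effect, and the only component effect is an amyloid x periventricular
#' interaction of -0.35 on episodic memory. Noise levels are chosen so each
#' domain's latent variance is close to 1: the observed tests are z-scored
#' before compositing, so this keeps the planted coefficients on the
#' composite z-scale (attenuation by cohort standardization stays within a
#' few percent).
#'
#' @param interaction_beta planted amyloid x component interaction.
#' @param interaction_component factor carrying the interaction.
#' @return list consumed by [cohort_gen_spec()].
#' @export
default_cognition_model <- function(interaction_beta = -0.35,
                                    interaction_component = "periventricular") {
  list(domains = list(episodic_memory = 3L, executive = 3L,
                      processing_speed = 2L),
       betas = list(
         episodic_memory = c(intercept = 0, age = -0.30, education = 0.15,
                             sex = -0.15, abeta = 0),
         executive = c(intercept = 0, age = -0.25, education = 0.15,
                       sex = -0.05, abeta = 0),
         processing_speed = c(intercept = 0, age = -0.30, education = 0.05,
                              sex = 0, abeta = 0)),
       component_betas = NULL,   # no main effects of the factors by default
       interaction_beta = interaction_beta,
       interaction_component = interaction_component,
       interaction_domain = "episodic_memory",
       noise_sd = c(episodic_memory = 0.91, executive = 0.95,
                    processing_speed = 0.95),
       test_noise_sd = 0.35)
}

# truncated-normal draw on [lo, hi]
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Centiloid values: a two-component mixture (amyloid-negative cluster near
# zero, amyloid-positive tail), calibrated so the median is ~8 CL, ~32% of
# draws exceed 12 CL and ~11% exceed 30 CL.
.rcentiloid <- function(n, p_pos = 0.32) {
  pos <- runif(n) < p_pos
  cl <- numeric(n)
  cl[!pos] <- pmax(.rtnorm(sum(!pos), 5, 5.5, hi = 12), -11.8)
  cl[pos] <- 12 + rgamma(sum(pos), shape = 1.3, scale = 12)
  cl
}

#' Draw a synthetic cohort with planted ground truth
#'
#' @param spec a [cohort_gen_spec()].
#' @param factor_scores optional n x k matrix of spatial-pattern factor
#'   scores (columns named after the factors). If `NULL`, scores are
#'   generated from the planted model in `spec`.
#' @return data.frame with covariates, Centiloid value, diagnosis and raw
#'   cognitive test scores. The planted ground truth (factor scores, all
#'   coefficients, the spec) is attached as `attr(x, "truth")`.
#' @export
sample_cohort <- function(spec = cohort_gen_spec(), factor_scores = NULL) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  prev <- spec$prevalences

  age <- .rtnorm(n, spec$age_mean, spec$age_sd,
                 spec$age_range[1], spec$age_range[2])
  age_z <- (age - spec$age_mean) / spec$age_sd
  sex <- rbinom(n, 1, prev$male)              # female = 0, male = 1
  education <- pmax(round(rnorm(n, spec$education_mean, spec$education_sd)), 8)
  edu_z <- (education - spec$education_mean) / spec$education_sd
  physical_activity <- pmax(rnorm(n, spec$activity_mean, spec$activity_sd), 0)

  u <- runif(n)
  smoking <- ifelse(u < prev$smoking_current, "current",
                    ifelse(u < prev$smoking_current + prev$smoking_former,
                           "former", "never"))
  flags <- c("hypertension", "cardiac", "vascular", "renal",
             "endocrine_metabolic", "respiratory", "sleep_disorder",
             "alcohol_use")
  flag_draws <- lapply(flags, function(f) rbinom(n, 1, prev[[f]]))
  names(flag_draws) <- flags

  centiloid <- .rcentiloid(n, prev$amyloid_positive)
  abeta <- as.integer(centiloid > 12)
  # APOE4 enriched among amyloid-positive subjects, marginal held at target
  p_pos <- prev$amyloid_positive
  p_apoe_pos <- min(0.40, 1)
  p_apoe_neg <- max((prev$apoe4 - p_pos * p_apoe_pos) / (1 - p_pos), 0)
  apoe4 <- rbinom(n, 1, ifelse(abeta == 1, p_apoe_pos, p_apoe_neg))
  diagnosis <- ifelse(runif(n) < stats::plogis(-1.45 + age_z), "MCI", "CU")

  fac_names <- names(spec$age_betas)
  k <- length(fac_names)
  if (is.null(factor_scores)) {
    eta <- sample_factor_scores(n, spec$factor_covariance)
    factor_scores <- outer(age_z, spec$age_betas) +
      outer(flag_draws$hypertension, spec$hyp_betas) + eta
    colnames(factor_scores) <- fac_names
  } else {
    if (nrow(factor_scores) != n)
      stop("factor_scores has ", nrow(factor_scores), " rows but n_subjects = ", n)
    if (is.null(colnames(factor_scores))) colnames(factor_scores) <- fac_names
  }

  cg <- spec$cognition
  tests <- list()
  latents <- list()
  for (dom in names(cg$domains)) {
    b <- cg$betas[[dom]]
    lat <- b["intercept"] + b["age"] * age_z + b["education"] * edu_z +
      b["sex"] * sex + b["abeta"] * abeta
    if (!is.null(cg$component_betas) && dom %in% rownames(cg$component_betas))
      lat <- lat + as.vector(factor_scores %*% cg$component_betas[dom, ])
    if (identical(dom, cg$interaction_domain) &&
        cg$interaction_component %in% colnames(factor_scores))
      lat <- lat + cg$interaction_beta * abeta *
        factor_scores[, cg$interaction_component]
    lat <- lat + rnorm(n, 0, cg$noise_sd[[dom]])
    latents[[dom]] <- as.numeric(lat)
    for (t in seq_len(cg$domains[[dom]]))
      tests[[paste0(dom, "_", t)]] <- latents[[dom]] +
        rnorm(n, 0, cg$test_noise_sd)
  }

  out <- data.frame(subject = seq_len(n), age = age, sex = sex,
                    education = education,
                    physical_activity = physical_activity,
                    smoking = smoking, stringsAsFactors = FALSE)
  for (f in flags) out[[f]] <- flag_draws[[f]]
  out$centiloid <- centiloid
  out$apoe4 <- apoe4
  out$diagnosis <- diagnosis
  for (nm in names(tests)) out[[nm]] <- tests[[nm]]

  # plant missingness
  mr <- spec$missing_rates
  if (!is.null(mr$physical_activity))
    out$physical_activity[runif(n) < mr$physical_activity] <- NA
  if (!is.null(mr$alcohol_use))
    out$alcohol_use[runif(n) < mr$alcohol_use] <- NA
  for (dom in names(cg$domains)) {
    rate <- mr[[dom]]
    if (is.null(rate) || rate <= 0) next
    hit <- which(runif(n) < rate)
    for (i in hit) {
      t <- sample.int(cg$domains[[dom]], 1)
      out[i, paste0(dom, "_", t)] <- NA
    }
  }

  attr(out, "truth") <- list(factor_scores = factor_scores,
                             latent_domains = latents,
                             age_betas = spec$age_betas,
                             hyp_betas = spec$hyp_betas,
                             cognition = cg, spec = spec)
  out
}
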