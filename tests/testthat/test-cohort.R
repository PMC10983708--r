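test_that("cohort generation is reproducible and validates its inputs", {
  a <- sample_cohort(cohort_gen_spec(n_subjects = 50, seed = 7))
  b <- sample_cohort(cohort_gen_spec(n_subjects = 50, seed = 7))
  expect_identical(a, b)
  expect_error(cohort_gen_spec(prevalences = list(hypertension = 1.5)),
               "probabilities")
  expect_error(sample_cohort(cohort_gen_spec(n_subjects = 10, seed = 1),
                             factor_scores = matrix(0, 5, 4)),
               "rows")
})

test_that("binary covariates hit their prevalence targets", {
  coh <- sample_cohort(cohort_gen_spec(n_subjects = 10000, seed = 13))
  # hypertension parameter 0.337: binomial 3-s.e. band at n = 10000
  p <- 0.337
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(coh$hypertension) - p), 3 * se)
  # remaining flags within a looser 4-s.e. band
  for (f in c("cardiac", "vascular", "renal", "respiratory",
              "sleep_disorder")) {
    pf <- cohort_gen_spec()$prevalences[[f]]
    expect_lt(abs(mean(coh[[f]]) - pf), 4 * sqrt(pf * (1 - pf) / 10000))
  }
  # amyloid scale: median near 8 CL, about a third above 12 CL
  expect_lt(abs(median(coh$centiloid) - 8.3), 1.5)
  expect_lt(abs(mean(coh$centiloid > 12) - 0.32), 0.02)
  expect_true(all(coh$age >= 50 & coh$age <= 89))
  expect_true(all(coh$smoking %in% c("never", "former", "current")))
})

test_that("zero-noise cognition reduces to the planted intercept", {
  cg <- default_cognition_model()
  cg$betas <- lapply(cg$betas, function(b) {
    b[] <- 0; b["intercept"] <- 2.5; b
  })
  cg$interaction_beta <- 0
  cg$noise_sd[] <- 0
  cg$test_noise_sd <- 0
  spec <- cohort_gen_spec(n_subjects = 40, cognition = cg, seed = 3,
                          missing_rates = list())
  coh <- sample_cohort(spec)
  for (col in grep("episodic_memory_|executive_|processing_speed_",
                   names(coh), value = TRUE))
    expect_equal(coh[[col]], rep(2.5, 40))
})

test_that("planted factor model links age and hypertension to the factors", {
  spec <- cohort_gen_spec(n_subjects = 8000, seed = 23)
  coh <- sample_cohort(spec)
  fs <- attr(coh, "truth")$factor_scores
  age_z <- (coh$age - spec$age_mean) / spec$age_sd
  # implied marginal age correlations approximate the planted values
  r_target <- spec$age_betas / sqrt(spec$age_betas^2 + 1)
  for (j in seq_along(r_target))
    expect_lt(abs(cor(fs[, j], age_z) - r_target[j]), 0.07)
  # hypertension shifts deep and BGT only
  d <- colMeans(fs[coh$hypertension == 1, ]) -
    colMeans(fs[coh$hypertension == 0, ])
  expect_lt(abs(d["deep"] - 0.5), 0.12)
  expect_lt(abs(d["BGT"] - 0.5), 0.12)
  expect_lt(abs(d["posterior"]), 0.12)
})
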