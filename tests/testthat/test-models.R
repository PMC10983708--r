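# small deterministic cohort + scores used across blocks
model_fixture <- function(n = 400, seed = 61) {
  coh <- sample_cohort(cohort_gen_spec(n_subjects = n, seed = seed,
                                       missing_rates = list()))
  list(cohort = coh, scores = attr(coh, "truth")$factor_scores)
}

test_that("amyloid dichotomization is strict at the cutoff", {
  expect_equal(dichotomize_amyloid(8.3, 12), 0L)   # the cohort-median value
  expect_equal(dichotomize_amyloid(12, 12), 0L)    # exactly 12 is negative
  expect_equal(dichotomize_amyloid(12.0001, 12), 1L)
  expect_equal(dichotomize_amyloid(30.5, 12), 1L)
  expect_equal(dichotomize_amyloid(30.5, 30), 1L)
  expect_error(dichotomize_amyloid(c(1, NA), 12), "non-finite")
})

test_that("composites are cohort z-score means with per-domain exclusion", {
  d <- data.frame(episodic_memory_1 = c(1, 2, 3, NA),
                  episodic_memory_2 = c(2, 2, 2, 2),
                  processing_speed_1 = c(0, 1, 2, 3))
  out <- build_composites(d)
  # subject 4 missing one memory test: excluded from memory, kept for speed
  expect_true(is.na(out$episodic_memory[4]))
  expect_false(anyNA(out$processing_speed))
  # single-test domain: composite equals that test's z-score
  expect_equal(out$processing_speed,
               as.vector(scale(d$processing_speed_1)), ignore_attr = TRUE)
  expect_equal(mean(out$processing_speed), 0, tolerance = 1e-12)
  expect_error(build_composites(d, domains = list(mem = character(0))),
               "empty domain")
})

test_that("tier-3 design holds exactly the documented covariates", {
  fx <- model_fixture()
  tiers <- fit_tiered_models(fx$scores, fx$cohort, "renal", "deep")
  expect_named(tiers, c("unadjusted", "age_adjusted", "fully_adjusted"))
  t3 <- colnames(model.matrix(tiers$fully_adjusted$fit))
  expect_setequal(t3, c("(Intercept)", "renal", "age", "hypertension",
                        "physical_activity", "education", "smoking_current",
                        "smoking_former", "alcohol_use"))
  # tier nesting
  t2 <- colnames(model.matrix(tiers$age_adjusted$fit))
  expect_true(all(setdiff(t2, "(Intercept)") %in% t3))
  # hypertension as predictor: no duplicated covariate in tier 3
  th <- fit_tiered_models(fx$scores, fx$cohort, "hypertension", "deep")
  t3h <- colnames(model.matrix(th$fully_adjusted$fit))
  expect_equal(sum(t3h == "hypertension"), 1L)
  # subgroup filtering restricts n
  tcu <- fit_tiered_models(fx$scores, fx$cohort, "renal", "deep",
                           subgroup = "CU")
  expect_equal(tcu$unadjusted$n, sum(fx$cohort$diagnosis == "CU"))
  expect_error(fit_tiered_models(fx$scores, fx$cohort, "nope", "deep"),
               "unknown predictor")
})

test_that("zero-noise planted outcome is recovered to machine precision", {
  fx <- model_fixture(n = 200)
  d <- fx$cohort
  d$episodic_memory <- 0.3 - 0.25 * fx$scores[, "periventricular"] +
    0.1 * d$age - 0.2 * dichotomize_amyloid(d$centiloid, 12) -
    0.4 * dichotomize_amyloid(d$centiloid, 12) * fx$scores[, "periventricular"]
  # summary.lm warns about the perfect fit; that is exactly the scenario
  m <- suppressWarnings(
    fit_cognition_models(fx$scores, d, "episodic_memory",
                         "periventricular", interaction = TRUE))
  est <- setNames(m$terms$estimate, m$terms$term)
  expect_equal(est[["periventricular"]], -0.25, tolerance = 1e-8)
  expect_equal(est[["abeta"]], -0.2, tolerance = 1e-8)
  expect_equal(est[["periventricular:abeta"]], -0.4, tolerance = 1e-8)
  expect_equal(est[["age"]], 0.1, tolerance = 1e-8)
  expect_equal(est[["education"]], 0, tolerance = 1e-8)
})

test_that("interaction models report LRT and adjusted-R2 gain", {
  fx <- model_fixture(n = 500, seed = 62)
  m <- fit_cognition_models(fx$scores, fx$cohort, "episodic_memory",
                            "periventricular", interaction = TRUE)
  expect_true(is.finite(m$lrt_p))
  expect_lt(m$lrt_p, 0.05)        # planted interaction present
  expect_gt(m$delta_adj_r2, 0)
  # removing the interaction reproduces the nested model exactly
  m0 <- fit_cognition_models(fx$scores, fx$cohort, "episodic_memory",
                             "periventricular", interaction = FALSE)
  expect_equal(coef(m$null_fit), coef(m0$fit), tolerance = 1e-12)
})

test_that("robust refit matches OLS on clean data and resists outliers", {
  set.seed(63)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n)
  m <- lm(y ~ x, d)
  r <- robust_refit(m)
  expect_lt(max(abs(r$terms$estimate - coef(m))), 0.02)
  # CI significance rule
  expect_true(r$terms$significant[r$terms$term == "x"])
  ci_rule <- function(lo, hi) lo > 0 | hi < 0
  expect_true(ci_rule(-0.35, -0.02))
  expect_false(ci_rule(-0.35, 0.02))

  # 5% gross y-outliers: robust slope closer to truth than OLS
  set.seed(64)
  wins <- replicate(150, {
    x <- rnorm(500); y <- 0.5 * x + rnorm(500)
    bad <- sample(500, 25); y[bad] <- y[bad] + rnorm(25, 0, 60)
    dd <- data.frame(x = x, y = y)
    mo <- lm(y ~ x, dd)
    ro <- robust_refit(mo)
    abs(ro$terms$estimate[2] - 0.5) < abs(coef(mo)[2] - 0.5)
  })
  expect_gte(mean(wins), 0.9)
  # bootstrap CI variant runs and brackets the estimate
  rb <- robust_refit(m, ci = "bootstrap", n_boot = 60)
  expect_true(all(rb$terms$ci_lo <= rb$terms$estimate + 1e-8 &
                    rb$terms$estimate <= rb$terms$ci_hi + 1e-8))
})

test_that("group comparison picks the right test family", {
  fx <- model_fixture(n = 300, seed = 65)
  gc1 <- group_compare(fx$cohort, "age", "diagnosis")
  expect_equal(gc1$type, "wilcoxon")
  gc2 <- group_compare(fx$cohort, "hypertension", "diagnosis")
  expect_equal(gc2$type, "chi-squared")
  # identical 2x2 proportions give a chi-square statistic of 0
  d <- data.frame(g = rep(c("a", "b"), each = 40),
                  v = rep(c(0, 1), times = 40))
  gc0 <- group_compare(d, "v", "g")
  expect_equal(gc0$statistic, 0)
  expect_error(group_compare(data.frame(g = "a", v = 1), "v", "g"),
               "two levels")
  # planted 0.5-sd shift: rank-sum power check at a fixed seed
  set.seed(66)
  hits <- replicate(200, {
    dd <- data.frame(g = rep(c("a", "b"), each = 200),
                     v = c(rnorm(200), rnorm(200, 0.5)))
    group_compare(dd, "v", "g")$p.value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("comorbidity burden counts six flags and partitions into bins", {
  fx <- model_fixture(n = 500, seed = 67)
  res <- suppressWarnings(comorbidity_burden_analysis(fx$scores, fx$cohort))
  flags <- c("vascular", "cardiac", "respiratory", "renal",
             "endocrine_metabolic", "sleep_disorder")
  expect_equal(res$counts, rowSums(fx$cohort[, flags]), ignore_attr = TRUE)
  # a subject with all six flags counts 6 and lands in bin 3+
  d <- fx$cohort; d[1, flags] <- 1
  res2 <- suppressWarnings(comorbidity_burden_analysis(fx$scores, d))
  expect_equal(res2$counts[1], 6, ignore_attr = TRUE)
  expect_equal(as.character(res2$bins[1]), "3+")
  # bins partition all subjects
  expect_equal(sum(table(res$bins)), nrow(fx$cohort))
  expect_false(anyNA(res$bins))
  # planted hypertension shift detectable within the count-0 stratum
  set.seed(68)
  n <- 400
  coh <- data.frame(hypertension = rep(c(0, 1), each = n / 2))
  for (f in flags) coh[[f]] <- 0
  sc <- matrix(rnorm(n) + 0.5 * coh$hypertension, ncol = 1,
               dimnames = list(NULL, "deep"))
  res3 <- suppressWarnings(comorbidity_burden_analysis(sc, coh))
  p0 <- res3$tests$p[res3$tests$count_bin == "0" &
                       res3$tests$component == "deep"]
  expect_lt(p0, 0.05)
  expect_error(comorbidity_burden_analysis(fx$scores,
                                           fx$cohort[, 1:4]), "missing")
})
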