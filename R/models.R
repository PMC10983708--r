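#' Dichotomize amyloid burden at a Centiloid cutoff
#'
#' Positive if and only if the Centiloid value strictly exceeds the cutoff
#' (12 CL marks the transition to subtle pathology, 30 CL established
#' pathology; exactly 12 CL is negative).
#'
#' @param centiloid numeric Centiloid values.
#' @param cutoff 12 (default) or 30 (any nonnegative value accepted).
#' @return integer vector of 0/1.
#' @export
dichotomize_amyloid <- function(centiloid, cutoff = 12) {
  if (any(!is.finite(centiloid)))
    stop("non-finite Centiloid value(s)")
  as.integer(centiloid > cutoff)
}

# add abeta12/abeta30 and smoking indicator columns where derivable
.augment_cohort <- function(cohort) {
  if ("centiloid" %in% names(cohort)) {
    if (!"abeta12" %in% names(cohort))
      cohort$abeta12 <- dichotomize_amyloid(cohort$centiloid, 12)
    if (!"abeta30" %in% names(cohort))
      cohort$abeta30 <- dichotomize_amyloid(cohort$centiloid, 30)
  }
  if ("smoking" %in% names(cohort)) {
    cohort$smoking_current <- as.integer(cohort$smoking == "current")
    cohort$smoking_former <- as.integer(cohort$smoking == "former")
  }
  cohort
}

#' Cognitive domain composites from individual test scores
#'
#' Converts each test to a z-score using the cohort mean and standard
#' deviation, then averages the z-scores within each domain. A subject
#' missing any constituent test of a domain gets `NA` for that domain's
#' composite (and is thereby excluded from that domain's models) but is
#' retained for domains where all tests are complete.
#'
#' @param cohort data.frame containing the test columns.
#' @param domains named list mapping each domain to its test column names;
#'   by default, columns are grouped by the prefixes `episodic_memory_`,
#'   `executive_` and `processing_speed_`.
#' @return `cohort` with one added composite column per domain.
#' @export
build_composites <- function(cohort, domains = NULL) {
  if (is.null(domains)) {
    domains <- lapply(c(episodic_memory = "episodic_memory",
                        executive = "executive",
                        processing_speed = "processing_speed"),
                      function(p) grep(paste0("^", p, "_\\d+$"),
                                       names(cohort), value = TRUE))
    domains <- domains[vapply(domains, length, 1L) > 0]
  }
  if (length(domains) == 0) stop("no cognitive test columns found")
  for (dom in names(domains)) {
    tests <- domains[[dom]]
    if (length(tests) == 0) stop("empty domain: ", dom)
    Z <- sapply(tests, function(t) {
      v <- cohort[[t]]
      (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    })
    Z <- matrix(Z, nrow = nrow(cohort))
    cohort[[dom]] <- ifelse(rowSums(is.na(Z)) > 0, NA, rowMeans(Z))
  }
  cohort
}

# merge component scores into the cohort table
.merge_scores <- function(scores, cohort) {
  if (inherits(scores, "wmh_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("C", seq_len(ncol(scores)))
  if (nrow(scores) != nrow(cohort))
    stop("scores (", nrow(scores), " rows) and cohort (", nrow(cohort),
         " rows) do not match")
  cohort[colnames(scores)] <- as.data.frame(scores)
  .augment_cohort(cohort)
}

.tier3_covariates <- c("age", "hypertension", "physical_activity",
                       "education", "smoking_current", "smoking_former",
                       "alcohol_use")

# one OLS fit summarised as a model-result row set
.model_result <- function(fit, tier, subgroup, n_total, robust = TRUE,
                          level = 0.95) {
  cf <- coef(summary(fit))
  ci <- confint(fit, level = level)
  terms_df <- data.frame(term = rownames(cf), estimate = cf[, 1],
                         ci_lo = ci[, 1], ci_hi = ci[, 2],
                         p = cf[, 4], stringsAsFactors = FALSE)
  if (robust) {
    rb <- robust_refit(fit)
    idx <- match(terms_df$term, rb$terms$term)
    terms_df$robust_lo <- rb$terms$ci_lo[idx]
    terms_df$robust_hi <- rb$terms$ci_hi[idx]
    terms_df$robust_significant <- rb$terms$significant[idx]
  }
  rownames(terms_df) <- NULL
  n_used <- length(resid(fit))
  structure(list(terms = terms_df,
                 adj_r2 = summary(fit)$adj.r.squared,
                 loglik = as.numeric(logLik(fit)),
                 n = n_used, n_dropped = n_total - n_used,
                 tier = tier, subgroup = subgroup,
                 formula = formula(fit), fit = fit),
            class = "wmh_model")
}

#' @export
print.wmh_model <- function(x, ...) {
  cat(sprintf("Linear model [%s, %s]: %s  (n = %d, %d dropped, adj R2 = %.3f)\n",
              x$tier, x$subgroup, deparse(x$formula), x$n, x$n_dropped,
              x$adj_r2))
  td <- x$terms
  td[, -1] <- round(td[, -1, drop = FALSE], 3)
  print(td, row.names = FALSE)
  if (!is.null(x$lrt_p))
    cat(sprintf("Interaction LRT: chi2 = %.2f, p = %.4g; delta adj R2 = %.3f\n",
                x$lrt_stat, x$lrt_p, x$delta_adj_r2))
  invisible(x)
}

#' Tiered association models of a component score on a risk factor
#'
#' Fits the three nested ordinary-least-squares tiers used for every
#' risk-factor association: (1) unadjusted, (2) age-adjusted, and (3) fully
#' adjusted for age, hypertension, physical activity, education, current and
#' former smoking, and alcohol use. When the predictor is itself one of the
#' tier-3 covariates (hypertension, alcohol use), the duplicate covariate is
#' omitted from tier 3. Each tier is refit robustly ([robust_refit()]) and
#' the robust 95% CI reported per term. Missing covariates are handled by
#' listwise deletion within each tier; the number of dropped subjects is
#' recorded in the result.
#'
#' @param scores component scores: matrix/data.frame with named columns, or
#'   a `wmh_pca` fit.
#' @param cohort the covariate table.
#' @param predictor name of the risk-factor column (e.g. `"hypertension"`,
#'   `"abeta12"`, `"sex"`).
#' @param component name of the component score column to model.
#' @param subgroup `"combined"` (default), `"CU"` or `"MCI"` — filter on the
#'   `diagnosis` column before fitting.
#' @param robust also compute the robust refit per tier (default `TRUE`;
#'   turn off in large simulation loops where only the OLS inference is
#'   examined).
#' @return list of three `wmh_model` objects named `unadjusted`,
#'   `age_adjusted`, `fully_adjusted`.
#' @export
fit_tiered_models <- function(scores, cohort, predictor, component,
                              subgroup = c("combined", "CU", "MCI"),
                              robust = TRUE) {
  subgroup <- match.arg(subgroup)
  dat <- .merge_scores(scores, cohort)
  if (!predictor %in% names(dat)) stop("unknown predictor: ", predictor)
  if (!component %in% names(dat)) stop("unknown component: ", component)
  if (subgroup != "combined") dat <- dat[dat$diagnosis == subgroup, ]
  tiers <- list(unadjusted = character(0),
                age_adjusted = "age",
                fully_adjusted = setdiff(.tier3_covariates, predictor))
  out <- lapply(names(tiers), function(tn) {
    rhs <- paste(c(predictor, tiers[[tn]]), collapse = " + ")
    fml <- as.formula(paste(component, "~", rhs))
    mm_terms <- c(predictor, tiers[[tn]])
    fit <- lm(fml, data = dat)
    if (fit$rank < ncol(model.matrix(fit))) {
      alias <- colnames(model.matrix(fit))[is.na(coef(fit))]
      stop("rank-deficient design; collinear term(s): ",
           paste(alias, collapse = ", "))
    }
    .model_result(fit, tier = tn, subgroup = subgroup, n_total = nrow(dat),
                  robust = robust)
  })
  names(out) <- names(tiers)
  out
}

#' Cognition models with an optional amyloid interaction
#'
#' Regresses a cognitive domain composite on a component score, amyloid
#' status (Centiloid > `cutoff`), education, age and sex in the combined
#' sample. With `interaction = TRUE`, adds the amyloid x component term and
#' reports the likelihood-ratio test against the nested main-effects model
#' (fit on the same subjects) and the change in adjusted R-squared.
#'
#' @inheritParams fit_tiered_models
#' @param domain composite column name (created by [build_composites()] if
#'   the test columns are present).
#' @param interaction add the amyloid x component interaction term?
#' @param cutoff Centiloid cutoff for amyloid status (default 12).
#' @param robust also compute the robust refit (default `TRUE`).
#' @return a `wmh_model`; with `interaction = TRUE` it carries `lrt_stat`,
#'   `lrt_p` and `delta_adj_r2` fields.
#' @export
fit_cognition_models <- function(scores, cohort, domain = "episodic_memory",
                                 component, interaction = FALSE,
                                 cutoff = 12, robust = TRUE) {
  dat <- .merge_scores(scores, cohort)
  if (!domain %in% names(dat)) dat <- build_composites(dat)
  if (!domain %in% names(dat)) stop("unknown cognitive domain: ", domain)
  dat$abeta <- dichotomize_amyloid(dat$centiloid, cutoff)
  base <- as.formula(paste(domain, "~", component,
                           "+ abeta + education + age + sex"))
  keep <- complete.cases(dat[, c(domain, component, "abeta", "education",
                                 "age", "sex")])
  dat <- dat[keep, ]
  m0 <- lm(base, data = dat)
  if (!interaction)
    return(.model_result(m0, tier = "cognition", subgroup = "combined",
                         n_total = nrow(dat), robust = robust))
  m1 <- update(m0, as.formula(paste(". ~ . +", component, ":abeta")))
  res <- .model_result(m1, tier = "cognition_interaction",
                       subgroup = "combined", n_total = nrow(dat),
                       robust = robust)
  lrt <- lmtest::lrtest(m0, m1)
  res$lrt_stat <- lrt$Chisq[2]
  res$lrt_p <- lrt$`Pr(>Chisq)`[2]
  res$delta_adj_r2 <- summary(m1)$adj.r.squared - summary(m0)$adj.r.squared
  res$null_fit <- m0
  res
}

#' Robust refit of a linear model
#'
#' Repeats an OLS fit as a Huber M-estimate (tuning constant 1.345) and
#' reports sandwich-type 95% confidence intervals; an effect is flagged
#' significant if its robust CI excludes 0. A case-resampling bootstrap CI
#' is available as an alternative.
#'
#' @param model an `lm` fit (or a `wmh_model`).
#' @param ci `"sandwich"` (default) or `"bootstrap"`.
#' @param level confidence level.
#' @param k_huber Huber tuning constant.
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @return list with `terms` (term, estimate, se, ci_lo, ci_hi,
#'   significant) and the underlying `rlm` fit.
#' @export
robust_refit <- function(model, ci = c("sandwich", "bootstrap"),
                         level = 0.95, k_huber = 1.345, n_boot = 500L) {
  ci <- match.arg(ci)
  if (inherits(model, "wmh_model")) model <- model$fit
  stopifnot(inherits(model, "lm"))
  X <- model.matrix(model)
  y <- stats::model.response(stats::model.frame(model))
  n <- nrow(X)
  ols_resid_sd <- sd(resid(model))
  if (is.na(ols_resid_sd) || ols_resid_sd < 1e-10) {
    # exact fit: the robust refit coincides with OLS, CIs degenerate
    b <- coef(model)
    terms_df <- data.frame(term = names(b), estimate = unname(b), se = 0,
                           ci_lo = unname(b), ci_hi = unname(b),
                           significant = unname(b != 0),
                           stringsAsFactors = FALSE)
    return(list(terms = terms_df, fit = model, method = ci))
  }
  rfit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = k_huber, maxit = 200)
  if (!rfit$converged)
    stop("robust fit did not converge; IRLS criterion trace tail: ",
         paste(signif(utils::tail(rfit$conv, 5), 6), collapse = ", "))
  b <- coef(rfit)
  if (ci == "sandwich") {
    s <- rfit$s
    u <- residuals(rfit) / s
    psi_u <- u * MASS::psi.huber(u, k_huber)          # psi(u)
    dpsi <- MASS::psi.huber(u, k_huber, deriv = 1)    # psi'(u), 0/1
    A <- crossprod(X * dpsi, X) / n
    B <- crossprod(X * psi_u) / n                     # sum psi^2 x x' / n
    Ainv <- solve(A)
    V <- s^2 * (Ainv %*% B %*% Ainv) / n
    se <- sqrt(diag(V))
    z <- qnorm(1 - (1 - level) / 2)
    lo <- b - z * se
    hi <- b + z * se
  } else {
    bs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      coef(MASS::rlm(X[idx, , drop = FALSE], y[idx], psi = MASS::psi.huber,
                     k = k_huber, maxit = 200))
    })
    if (is.null(dim(bs))) bs <- matrix(bs, nrow = 1)
    a <- (1 - level) / 2
    lo <- apply(bs, 1, quantile, probs = a)
    hi <- apply(bs, 1, quantile, probs = 1 - a)
    se <- apply(bs, 1, sd)
  }
  terms_df <- data.frame(term = names(b), estimate = unname(b),
                         se = unname(se), ci_lo = unname(lo),
                         ci_hi = unname(hi),
                         significant = unname(lo > 0 | hi < 0),
                         stringsAsFactors = FALSE)
  list(terms = terms_df, fit = rfit, method = ci)
}

#' Two-group comparison of a cohort characteristic
#'
#' Continuous variables are compared with the Wilcoxon rank-sum test (with
#' continuity correction); categorical variables with the chi-squared test
#' (Yates continuity correction for 2x2 tables only).
#'
#' @param cohort the cohort table.
#' @param variable column to compare.
#' @param grouping binary grouping column (default `diagnosis`).
#' @return list with `statistic`, `p.value`, `method`, `type`.
#' @export
group_compare <- function(cohort, variable, grouping = "diagnosis") {
  g <- cohort[[grouping]]
  v <- cohort[[variable]]
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  lev <- unique(g)
  if (length(lev) != 2) stop("grouping must have exactly two levels")
  if (any(table(g) == 0)) stop("empty group")
  continuous <- is.numeric(v) && length(unique(v)) > 5
  if (continuous) {
    ht <- wilcox.test(v ~ factor(g), exact = FALSE, correct = TRUE)
    type <- "wilcoxon"
  } else {
    tab <- table(v, g)
    ht <- suppressWarnings(
      chisq.test(tab, correct = all(dim(tab) == c(2, 2))))
    type <- "chi-squared"
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method, type = type)
}

#' Comorbidity burden versus component scores, stratified by hypertension
#'
#' Counts, per subject, the six comorbidity flags (vascular, cardiac,
#' respiratory, renal, endocrine-metabolic, sleep disorder; hypertension is
#' excluded from the count and used as the stratifier), bins the count into
#' \{0, 1, 2, 3+\}, and summarises each component score per count-bin x
#' hypertension stratum (n, median, IQR). Within each count bin, subjects
#' with and without hypertension are compared by the Wilcoxon rank-sum
#' test. Small strata (n < 10) trigger a warning but are still reported.
#'
#' @inheritParams fit_tiered_models
#' @return object of class `comorbidity_burden`: list with `summary`
#'   (per-stratum medians/IQRs), `tests` (per-bin Wilcoxon p-values per
#'   component) and `counts`.
#' @export
comorbidity_burden_analysis <- function(scores, cohort) {
  flags <- c("vascular", "cardiac", "respiratory", "renal",
             "endocrine_metabolic", "sleep_disorder")
  miss <- setdiff(flags, names(cohort))
  if (length(miss)) stop("missing comorbidity flags: ",
                         paste(miss, collapse = ", "))
  dat <- .merge_scores(scores, cohort)
  comp_cols <- colnames(if (inherits(scores, "wmh_pca")) scores$scores
                        else as.matrix(scores))
  if (is.null(comp_cols)) comp_cols <- paste0("C", seq_len(ncol(as.matrix(scores))))
  count <- rowSums(dat[, flags])
  bin <- cut(count, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  hyp <- dat$hypertension
  summ <- do.call(rbind, lapply(levels(bin), function(bb) {
    do.call(rbind, lapply(c(0, 1), function(h) {
      sel <- bin == bb & hyp == h
      do.call(rbind, lapply(comp_cols, function(cc) {
        v <- dat[[cc]][sel]
        data.frame(component = cc, count_bin = bb, hypertension = h,
                   n = sum(sel),
                   median = if (sum(sel)) median(v) else NA_real_,
                   q1 = if (sum(sel)) unname(quantile(v, 0.25)) else NA_real_,
                   q3 = if (sum(sel)) unname(quantile(v, 0.75)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(summ) <- NULL
  small <- unique(summ[summ$n < 10, c("count_bin", "hypertension", "n")])
  if (nrow(small))
    warning("small strata (n < 10): ",
            paste(sprintf("bin %s/hyp %d (n=%d)", small$count_bin,
                          small$hypertension, small$n), collapse = "; "))
  tests <- do.call(rbind, lapply(levels(bin), function(bb) {
    do.call(rbind, lapply(comp_cols, function(cc) {
      v0 <- dat[[cc]][bin == bb & hyp == 0]
      v1 <- dat[[cc]][bin == bb & hyp == 1]
      p <- if (length(v0) >= 2 && length(v1) >= 2)
        wilcox.test(v0, v1, exact = FALSE, correct = TRUE)$p.value
      else NA_real_
      data.frame(component = cc, count_bin = bb, p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  structure(list(summary = summ, tests = tests, counts = count, bins = bin),
            class = "comorbidity_burden")
}

#' @export
print.comorbidity_burden <- function(x, ...) {
  cat("Comorbidity burden analysis (count of 6 flags, hypertension-stratified)\n")
  cat("bin sizes:", paste(sprintf("%s: %d", levels(x$bins), table(x$bins)),
                          collapse = ", "), "\n")
  s <- x$summary
  s[, c("median", "q1", "q3")] <- round(s[, c("median", "q1", "q3")], 2)
  print(s, row.names = FALSE)
  invisible(x)
}
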