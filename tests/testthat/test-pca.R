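# planted oblique two-block factor model used in several blocks
planted_block_data <- function(n = 2000, noise = 0.05, rho = 0.3, seed = 101) {
  set.seed(seed)
  P <- matrix(0, 12, 2)
  P[1:6, 1] <- 0.9
  P[7:12, 2] <- 0.9
  Phi <- matrix(c(1, rho, rho, 1), 2)
  Fs <- MASS::mvrnorm(n, c(0, 0), Phi)
  X <- Fs %*% t(P) + matrix(rnorm(n * 12, 0, noise), n, 12)
  colnames(X) <- paste0("p", 1:12)
  list(X = X, P = P, Phi = Phi, Fs = Fs)
}

test_that("preprocessing matches the log(volume + 0.01) z-score recipe", {
  set.seed(51)
  V <- matrix(rexp(60 * 5), 60, 5, dimnames = list(NULL, paste0("p", 1:5)))
  V[1, 1] <- 0
  pr <- preprocess_volumes(V)
  # a zero volume enters the log as log(0.01) = -4.60517
  raw <- log(V + 0.01)
  expect_equal(unname(raw[1, 1]), -4.60517, tolerance = 1e-5)
  expect_equal(unname(pr$X[1, 1]),
               unname((raw[1, 1] - mean(raw[, 1])) / sd(raw[, 1])))
  expect_equal(unname(colMeans(pr$X)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(pr$X, 2, sd)), rep(1, 5), tolerance = 1e-10)

  Vdeg <- V; Vdeg[, 3] <- 2
  expect_error(preprocess_volumes(Vdeg), "p3")
  expect_error(preprocess_volumes(-V), "nonnegative")
})

test_that("decomposition is invariant to the log base", {
  set.seed(52)
  V <- matrix(rexp(150 * 10), 150, 10, dimnames = list(NULL, paste0("p", 1:10)))
  f_e <- wmh_pca(preprocess_volumes(V, log_base = exp(1)), k = 3)
  f_10 <- wmh_pca(preprocess_volumes(V, log_base = 10), k = 3)
  expect_equal(f_e$loadings, f_10$loadings, tolerance = 1e-8)
  expect_equal(f_e$phi, f_10$phi, tolerance = 1e-8)
  expect_equal(f_e$scores, f_10$scores, tolerance = 1e-8)
})

test_that("regression scores demand an invertible correlation matrix", {
  set.seed(59)
  V <- matrix(rexp(15 * 25), 15, 25, dimnames = list(NULL, paste0("p", 1:25)))
  expect_error(wmh_pca(V, k = 2), "singular")
})

test_that("k = 1 leaves the first principal component unrotated", {
  set.seed(53)
  V <- matrix(rexp(80 * 6), 80, 6, dimnames = list(NULL, paste0("p", 1:6)))
  fit <- wmh_pca(V, k = 1)
  R <- fit$R
  ev <- eigen(R, symmetric = TRUE)
  a1 <- ev$vectors[, 1] * sqrt(ev$values[1])
  a1 <- a1 * sign(a1[which.max(abs(a1))])
  expect_equal(unname(fit$loadings[, 1]), unname(a1), tolerance = 1e-10)
  expect_equal(unname(fit$phi), matrix(1, 1, 1))
})

test_that("oblimin recovers a planted oblique simple structure", {
  pd <- planted_block_data()
  fit <- wmh_pca(preprocess_volumes(exp(pd$X)), k = 2)
  al <- align_components(fit, pd$P)
  expect_true(all(al$congruence >= 0.99))
  expect_lt(abs(fit$phi[1, 2] - 0.3), 0.05)
})

test_that("rotation preserves the reproduced correlation matrix", {
  set.seed(54)
  V <- matrix(rexp(120 * 9), 120, 9, dimnames = list(NULL, paste0("p", 1:9)))
  for (k in 2:4) {
    fit <- wmh_pca(V, k = k)
    A <- fit$unrotated
    err <- max(abs(fit$loadings %*% fit$phi %*% t(fit$loadings) - A %*% t(A)))
    expect_lt(err, 1e-8)
    expect_true(all(diff(fit$rotation_history) <= 1e-10))
    expect_equal(diag(fit$phi), rep(1, k), ignore_attr = TRUE)
    expect_true(isSymmetric(fit$phi, tol = 1e-12))
  }
})

test_that("component scores are centred and recover planted factors", {
  pd <- planted_block_data(noise = 0.05)
  fit <- wmh_pca(preprocess_volumes(exp(pd$X)), k = 2)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
  al <- align_components(fit, pd$P)
  sc <- fit$scores[, al$permutation] %*% diag(al$signs)
  for (j in 1:2) expect_gte(cor(sc[, j], pd$Fs[, j]), 0.95)
  # inter-score correlation near phi on low-noise data
  expect_lt(abs(cor(sc)[1, 2] - fit$phi[al$permutation[1], al$permutation[2]]),
            0.05)
})

test_that("variance-explained proportions behave as documented", {
  set.seed(55)
  V <- matrix(rexp(100 * 6), 100, 6, dimnames = list(NULL, paste0("p", 1:6)))
  # full unrotated solution: proportions sum to 1
  fit_full <- wmh_pca(V, k = 6, rotation = "none")
  expect_equal(sum(fit_full$eigen_proportions), 1, tolerance = 1e-10)
  ve <- variance_explained(fit_full)
  expect_true(all(ve$proportion >= 0 & ve$proportion <= 1))
  # a single dominant planted direction captures nearly everything
  set.seed(56)
  f <- rnorm(500)
  X1 <- f %*% t(rep(1, 6)) + matrix(rnorm(3000, 0, 0.01), 500, 6)
  colnames(X1) <- paste0("p", 1:6)
  fit1 <- wmh_pca(preprocess_volumes(exp(X1)), k = 1)
  expect_gte(fit1$variance_explained[1], 0.95)
})

test_that("loading threshold is strict and the export is reproducible", {
  L <- matrix(c(0.4, 0.41, 0.39, 0.8), 4, 1,
              dimnames = list(paste0("p", 1:4), "C1"))
  fit <- structure(list(loadings = L, k = 1L), class = "wmh_pca")
  tab <- threshold_loadings(fit, 0.4)
  expect_equal(tab$shown, c(FALSE, TRUE, FALSE, TRUE))
  tab0 <- threshold_loadings(fit, 0)
  expect_equal(tab0$shown, L[, 1] > 0, ignore_attr = TRUE)
  expect_identical(tab, threshold_loadings(fit, 0.4))
  expect_error(threshold_loadings(fit, -1), "nonnegative")
})

test_that("tucker congruence and alignment resolve permutation and sign", {
  set.seed(57)
  P <- matrix(rnorm(30), 10, 3)
  shuffled <- P[, c(3, 1, 2)] %*% diag(c(-1, 1, -1))
  al <- align_components(shuffled, P)
  expect_equal(al$permutation, c(2, 3, 1))
  expect_equal(al$aligned, P, ignore_attr = TRUE)
  expect_true(all(al$congruence > 0.999))
  expect_equal(tucker_congruence(P[, 1], P[, 1]), 1)
  expect_equal(tucker_congruence(P[, 1], -P[, 1]), -1)
})

test_that("prediction projects new volumes with the training scaling", {
  set.seed(58)
  V <- matrix(rexp(100 * 8), 100, 8, dimnames = list(NULL, paste0("p", 1:8)))
  fit <- wmh_pca(V, k = 2)
  # projecting the training data reproduces the stored scores up to centring
  raw <- predict(fit, V)
  expect_equal(sweep(raw, 2, colMeans(raw)), fit$scores, tolerance = 1e-10)
  expect_equal(coef(fit), fit$loadings)
})
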