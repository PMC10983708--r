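#' Preprocess a parcel-volume table for decomposition
#'
#' Adds 0.01 ml to every parcel volume (so that empty parcels remain
#' log-transformable), takes the natural logarithm, and standardizes each
#' parcel column to mean 0 and standard deviation 1. The column means and
#' standard deviations are retained so that new subjects can be projected
#' onto a fitted solution. The log base is immaterial: switching base
#' rescales columns, which standardization removes.
#'
#' @param volumes data.frame or matrix of per-parcel lesion volumes (ml);
#'   `subject`, `total_volume` and `unassigned_volume` columns are ignored.
#' @param log_base base of the logarithm (default `exp(1)`).
#' @param offset constant added before the log (default 0.01 ml).
#' @return object of class `wmh_preprocessed`: list with the standardized
#'   matrix `X` and the retained `log_means`, `log_sds`, `offset`,
#'   `log_base`.
#' @export
preprocess_volumes <- function(volumes, log_base = exp(1), offset = 0.01) {
  cols <- if (is.data.frame(volumes)) .parcel_cols(volumes) else colnames(volumes)
  V <- as.matrix(if (is.data.frame(volumes)) volumes[, cols, drop = FALSE]
                 else volumes)
  if (any(V < 0)) stop("volumes must be nonnegative")
  if (any(!is.finite(V))) stop("volumes contain non-finite values")
  L <- log(V + offset) / log(log_base)
  sds <- apply(L, 2, sd)
  if (any(sds == 0))
    stop("zero-variance parcel column(s): ",
         paste(colnames(L)[sds == 0], collapse = ", "))
  mus <- colMeans(L)
  X <- sweep(sweep(L, 2, mus, "-"), 2, sds, "/")
  structure(list(X = X, log_means = mus, log_sds = sds,
                 offset = offset, log_base = log_base),
            class = "wmh_preprocessed")
}

# quartimin / oblimin criterion value and gradient at pattern matrix L
.oblimin_criterion <- function(L, gamma = 0) {
  p <- nrow(L); k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  M <- L2
  if (gamma != 0) M <- M - (gamma / p) * matrix(colSums(L2), p, k, byrow = TRUE)
  X <- M %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Gradient-projection algorithm for oblique rotation (Jennrich 2002).
# A: unrotated loadings. Returns pattern L, rotation T, phi, criterion trace.
.gpa_oblimin <- function(A, gamma = 0, max_iter = 1000L, tol = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  Ti <- Tmat                             # inverse of Tmat
  L <- A
  vg <- .oblimin_criterion(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  history <- f
  al <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:50) {
      Xn <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(Xn^2))
      Tt <- Xn %*% diag(v, k)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      vgt <- .oblimin_criterion(Lt, gamma)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Tti; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
    history <- c(history, f)
  }
  if (!converged)
    stop("oblimin rotation did not converge in ", max_iter,
         " iterations; criterion trace tail: ",
         paste(signif(utils::tail(history, 5), 6), collapse = ", "))
  list(pattern = L, Tmat = Tmat, phi = crossprod(Tmat), history = history)
}

#' Correlated (oblimin-rotated) principal component analysis of parceled
#' WMH volumes
#'
#' Fits the package's core model: the parcel x parcel correlation structure
#' of log-transformed, standardized lesion volumes is decomposed by
#' principal components, and the retained components are rotated obliquely
#' (oblimin, default gamma = 0 = quartimin) by gradient projection so that
#' they may correlate. Per-subject component scores are computed by the
#' regression method. Components are ordered by explained variance
#' (structure-based sum of squares) and signed so that each component's
#' largest-magnitude loading is positive.
#'
#' @param volumes a parcel-volume table (see [parcel_volume_table()]), a
#'   plain matrix of volumes, or a `wmh_preprocessed` object.
#' @param k number of components to retain (default 4).
#' @param rotation `"oblimin"` or `"none"`.
#' @param gamma oblimin family parameter (0 = quartimin).
#' @param scores `"regression"` (default) or `"least-squares"`.
#' @param max_iter,tol gradient-projection iteration cap and convergence
#'   tolerance on the projected-gradient norm.
#' @return object of class `wmh_pca` with elements `loadings` (pattern
#'   matrix, parcels x k), `structure`, `phi` (component correlations),
#'   `scores` (subjects x k), `variance_explained` (structure-based
#'   proportions; non-additive for oblique solutions), `eigen_proportions`
#'   (unrotated), `rotation_history`, `unrotated` loadings, and the
#'   preprocessing parameters.
#' @examples
#' set.seed(1)
#' V <- matrix(rexp(50 * 8), 50, 8,
#'             dimnames = list(NULL, paste0("p", 1:8)))
#' fit <- wmh_pca(V, k = 2)
#' fit
#' @export
wmh_pca <- function(volumes, k = 4L, rotation = c("oblimin", "none"),
                    gamma = 0, scores = c("regression", "least-squares"),
                    max_iter = 1000L, tol = 1e-6) {
  rotation <- match.arg(rotation)
  scores <- match.arg(scores)
  prep <- if (inherits(volumes, "wmh_preprocessed")) volumes
          else preprocess_volumes(volumes)
  X <- prep$X
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k > min(n, p)) stop("k must be in 1..min(subjects, parcels)")

  R <- crossprod(X) / (n - 1)
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  rownames(A) <- colnames(X)

  if (rotation == "oblimin" && k > 1L) {
    rot <- .gpa_oblimin(A, gamma = gamma, max_iter = max_iter, tol = tol)
    pattern <- rot$pattern
    phi <- rot$phi
    history <- rot$history
  } else {
    pattern <- A
    phi <- diag(k)
    history <- .oblimin_criterion(A, gamma)$f
  }

  # sign convention: largest-magnitude loading of each component positive
  sgn <- apply(pattern, 2, function(l) sign(l[which.max(abs(l))]))
  sgn[sgn == 0] <- 1
  pattern <- sweep(pattern, 2, sgn, "*")
  phi <- diag(sgn, k) %*% phi %*% diag(sgn, k)

  # order components by structure-based explained variance
  struct <- pattern %*% phi
  ss <- colSums(struct^2)
  ord <- order(ss, decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  struct <- struct[, ord, drop = FALSE]
  ss <- ss[ord]

  comp_names <- paste0("C", seq_len(k))
  colnames(pattern) <- colnames(struct) <- comp_names
  dimnames(phi) <- list(comp_names, comp_names)

  # component scores
  W <- switch(scores,
              "regression" = tryCatch(solve(R, struct), error = function(e)
                stop("singular parcel correlation matrix; ",
                     "component scores are not identifiable (",
                     conditionMessage(e), ")", call. = FALSE)),
              "least-squares" = pattern %*% solve(crossprod(pattern)))
  S <- X %*% W
  S <- sweep(S, 2, colMeans(S), "-")
  colnames(S) <- comp_names

  structure(list(loadings = pattern, structure = struct, phi = phi,
                 scores = S, weights = W,
                 variance_explained = ss / p,
                 eigen_proportions = ev$values[seq_len(k)] / p,
                 eigenvalues = ev$values,
                 rotation_history = history,
                 unrotated = A, R = R,
                 k = k, n = n, p = p,
                 rotation = rotation, gamma = gamma,
                 score_method = scores,
                 preprocessing = prep[c("log_means", "log_sds",
                                        "offset", "log_base")],
                 call = match.call()),
            class = "wmh_pca")
}

#' Variance explained by each component
#'
#' For oblique solutions the proportion is the sum of squared structure
#' loadings divided by the number of parcels; because components correlate,
#' these proportions are not additive. The unrotated eigenvalue proportions
#' are reported alongside.
#'
#' @param fit a `wmh_pca` object.
#' @return data.frame with `component`, `proportion` (structure-based) and
#'   `eigen_proportion` (unrotated).
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "wmh_pca"))
  data.frame(component = colnames(fit$loadings),
             proportion = unname(fit$variance_explained),
             eigen_proportion = unname(fit$eigen_proportions))
}

#' Threshold loadings for bullseye display
#'
#' Flags, per component, the parcels whose pattern loading strictly exceeds
#' `thr` (a loading of exactly `thr` is not shown), and returns an export
#' table suitable for bullseye plotting.
#'
#' @param fit a `wmh_pca` object.
#' @param thr threshold (default 0.4).
#' @param parcels optional [parcel_table()] supplying region/layer metadata;
#'   matched by parcel name.
#' @return data.frame with one row per parcel x component: `parcel`,
#'   `region`, `hemisphere`, `layer`, `component`, `loading`, `shown`.
#' @export
threshold_loadings <- function(fit, thr = 0.4, parcels = NULL) {
  stopifnot(inherits(fit, "wmh_pca"))
  if (thr < 0) stop("thr must be nonnegative")
  L <- fit$loadings
  pn <- rownames(L)
  if (is.null(parcels) && !is.null(pn) &&
      all(pn %in% parcel_table()$name)) parcels <- parcel_table()
  meta <- if (!is.null(parcels)) parcels[match(pn, parcels$name), ]
          else data.frame(region = NA, hemisphere = NA,
                          layer = NA, row.names = NULL)[rep(1, length(pn)), ]
  out <- do.call(rbind, lapply(colnames(L), function(cc) {
    data.frame(parcel = pn, region = meta$region,
               hemisphere = meta$hemisphere, layer = meta$layer,
               component = cc, loading = L[, cc],
               shown = L[, cc] > thr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between loading vectors; for matrices, the k x k matrix
#' of column-pair congruences.
#'
#' @param x,y numeric vectors or matrices with matching row dimension.
#' @return scalar or matrix of congruence coefficients in \[-1, 1\].
#' @export
tucker_congruence <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  num <- crossprod(x, y)
  den <- sqrt(outer(colSums(x^2), colSums(y^2)))
  out <- num / den
  if (length(out) == 1L) as.numeric(out) else out
}

#' Align components with a reference solution
#'
#' Resolves the permutation and sign indeterminacy of a rotated solution by
#' exhaustive search over column permutations and signs, maximizing the mean
#' absolute Tucker congruence with the reference. Never applied silently:
#' the chosen permutation and signs are part of the return value.
#'
#' @param loadings parcels x k matrix (or a `wmh_pca` fit).
#' @param reference parcels x k reference matrix.
#' @return list with `aligned` (reordered, resigned loadings),
#'   `permutation`, `signs`, and `congruence` (per reference column, after
#'   alignment).
#' @export
align_components <- function(loadings, reference) {
  if (inherits(loadings, "wmh_pca")) loadings <- loadings$loadings
  L <- as.matrix(loadings); Rf <- as.matrix(reference)
  k <- ncol(Rf)
  if (ncol(L) < k) stop("fewer fitted components than reference columns")
  if (k > 7L) stop("exhaustive alignment supports at most 7 components")
  C <- tucker_congruence(L, Rf)          # fitted x reference
  perms <- .permutations(ncol(L), k)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    val <- mean(abs(C[cbind(pm, seq_len(k))]))
    if (val > best_val) { best_val <- val; best <- pm }
  }
  cong <- C[cbind(best, seq_len(k))]
  signs <- ifelse(cong < 0, -1, 1)
  aligned <- sweep(L[, best, drop = FALSE], 2, signs, "*")
  colnames(aligned) <- colnames(Rf)
  list(aligned = aligned, permutation = best, signs = signs,
       congruence = abs(cong))
}

# all ordered selections of m items from 1..n (n^(m) rows)
.permutations <- function(n, m = n) {
  if (m == 1L) return(matrix(seq_len(n), ncol = 1))
  sub <- .permutations(n, m - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- sub[rowSums(sub == i) == 0, , drop = FALSE]
    cbind(i, keep)
  }))
  unname(out)
}

#' Project new subjects onto a fitted decomposition
#'
#' @param object a `wmh_pca` fit.
#' @param newdata a parcel-volume table with the same parcel columns.
#' @param ... unused.
#' @return matrix of component scores for the new subjects (computed with
#'   the training standardization and score weights; not re-centred).
#' @export
predict.wmh_pca <- function(object, newdata, ...) {
  cols <- rownames(object$loadings)
  V <- as.matrix(if (is.data.frame(newdata)) newdata[, cols, drop = FALSE]
                 else newdata[, cols, drop = FALSE])
  L <- log(V + object$preprocessing$offset) / log(object$preprocessing$log_base)
  X <- sweep(sweep(L, 2, object$preprocessing$log_means, "-"),
             2, object$preprocessing$log_sds, "/")
  X %*% object$weights
}

#' @export
coef.wmh_pca <- function(object, ...) object$loadings

#' @export
print.wmh_pca <- function(x, ...) {
  cat("Oblimin-rotated PCA of parceled WMH volumes\n")
  cat(sprintf("  %d subjects, %d parcels, %d components (%s rotation)\n",
              x$n, x$p, x$k, x$rotation))
  ve <- x$variance_explained
  cat("  variance explained (structure-based): ",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * ve),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.wmh_pca <- function(object, thr = 0.4, ...) {
  structure(list(fit = object, thr = thr,
                 top = threshold_loadings(object, thr)),
            class = "summary.wmh_pca")
}

#' @export
print.summary.wmh_pca <- function(x, ...) {
  print(x$fit)
  cat("\nComponent correlations (phi):\n")
  print(round(x$fit$phi, 2))
  cat(sprintf("\nParcels with loading > %.2f:\n", x$thr))
  shown <- x$top[x$top$shown, c("component", "parcel", "loading")]
  if (nrow(shown) == 0) cat("  (none)\n") else {
    shown$loading <- round(shown$loading, 2)
    print(shown, row.names = FALSE)
  }
  invisible(x)
}
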