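#' Fit a PCA identification model
#'
#' Centered principal component analysis via singular value decomposition
#' of the training feature matrix. The retained subspace (default 4
#' components: the two blend-composition degrees of freedom plus the
#' baseline offset and slope directions of the raw spectral block)
#' defines the "accepted product" region; acceptance thresholds are set
#' at fit time:
#' a score (Mahalanobis) distance cut-off at the square root of the
#' chi-square quantile `score_quantile` with `n_components` degrees of
#' freedom, and an orthogonal-residual cut-off at the training mean plus
#' `resid_sd_mult` standard deviations.
#'
#' Loadings follow a deterministic sign convention: the largest-magnitude
#' element of each loading vector is positive.
#'
#' @param X training feature matrix (e.g. the `features` element of
#'   [apply_plan()] output).
#' @param n_components retained components (< number of training samples).
#' @param score_quantile chi-square probability for the score-distance
#'   threshold (default 0.999).
#' @param resid_sd_mult multiplier on the training residual SD (default 5).
#' @return A `pca_model`: `loadings` (features x k), `scores`,
#'   `eigenvalues` (all, for variance accounting), `explained` and
#'   `cum_explained` (%), `center`, score covariance, thresholds
#'   `d_max`, `q_max`.
#' @export
fit_pca <- function(X, n_components = 4, score_quantile = 0.999,
                    resid_sd_mult = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_components >= n)
    stop("n_components must be smaller than the number of samples",
         call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  k <- n_components
  L <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: dominant loading element positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) L[, j] <- -L[, j]
  }
  scores <- Xc %*% L
  explained <- 100 * eig / sum(eig)
  S <- stats::cov(scores)
  tr <- sum(diag(S))
  if (rcond_safe(S) < 1e-10) S <- S + diag(1e-10 * tr, k)
  resid <- Xc - scores %*% t(L)
  rnorm_tr <- sqrt(rowSums(resid^2))
  model <- structure(
    list(n_components = k, loadings = L, scores = scores,
         eigenvalues = eig, explained = explained,
         cum_explained = cumsum(explained), center = center,
         score_mean = colMeans(scores), score_cov = S,
         d_max = sqrt(stats::qchisq(score_quantile, df = k)),
         q_max = mean(rnorm_tr) + resid_sd_mult * stats::sd(rnorm_tr),
         train_resid = rnorm_tr),
    class = "pca_model")
  model
}

rcond_safe <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  max(min(e), 0) / max(e)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components, PC1..%d explain %.3f%% of variance\n",
              x$n_components, x$n_components,
              x$cum_explained[x$n_components]))
  cat(sprintf("  thresholds: score distance %.3f, residual %.4g\n",
              x$d_max, x$q_max))
  invisible(x)
}

#' Score distance and orthogonal residual of new spectra
#'
#' Projects feature vectors onto the model subspace and returns, per
#' sample, the Mahalanobis distance of the scores from the training score
#' cloud and the norm of the out-of-plane residual.
#'
#' @param model a `pca_model`.
#' @param X feature matrix or single feature vector (same pre-processing
#'   and length as the training features).
#' @return data.frame with columns `distance` and `residual`.
#' @export
score_distance <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$center))
    stop("feature length mismatch with PCA model", call. = FALSE)
  Xc <- sweep(X, 2, model$center)
  sc <- Xc %*% model$loadings
  d2 <- stats::mahalanobis(sc, model$score_mean, model$score_cov)
  resid <- Xc - sc %*% t(model$loadings)
  data.frame(distance = sqrt(pmax(d2, 0)),
             residual = sqrt(rowSums(resid^2)))
}

#' Accept/reject spectra against a PCA identification model
#'
#' A sample is accepted iff its score distance is within `d_max` and its
#' orthogonal residual within `q_max` (both stored in the model at fit
#' time, unless overridden).
#'
#' @param model a `pca_model`.
#' @param X feature matrix (possibly 0-row).
#' @param d_max,q_max optional threshold overrides.
#' @return data.frame with `distance`, `residual`, `accept` (logical).
#' @export
classify <- function(model, X, d_max = model$d_max, q_max = model$q_max) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) == 0)
    return(data.frame(distance = numeric(0), residual = numeric(0),
                      accept = logical(0)))
  sd_ <- score_distance(model, X)
  sd_$accept <- sd_$distance <= d_max & sd_$residual <= q_max
  sd_
}
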