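#' Fit a PLS1 model by NIPALS
#'
#' Single-response partial least squares with sequential deflation. Each
#' factor takes the weight vector w = E'f / ||E'f|| (E, f the deflated
#' feature and response blocks), scores t = E w, X-loadings p = E't / t't,
#' y-loading q = f't / t't, then deflates E <- E - t p' and f <- f - t q.
#' The regression vector is b = W (P'W)^-1 q. For PLS1 each factor is a
#' single exact step; no inner iteration is required.
#'
#' @param X feature matrix (samples x features), e.g. from [apply_plan()].
#' @param y numeric response (percent of label content).
#' @param n_factors number of latent factors (>= 1).
#' @return A `pls1_model`: weights `W`, loadings `P`, y-loadings `q`,
#'   training scores `T`, regression vector `b`, stored feature/response
#'   means, `rmsec` and Pearson `r` on the training set.
#' @export
fit_pls1 <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must match length of y", call. = FALSE)
  if (n_factors < 1) stop("n_factors must be >= 1", call. = FALSE)
  if (n < n_factors + 1)
    stop("need at least n_factors + 1 samples", call. = FALSE)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_means)
  f <- y - y_mean
  scale0 <- sqrt(sum(E * E))
  p_feat <- ncol(X)
  W <- P <- matrix(0, p_feat, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12 * max(scale0, 1))
      stop(sprintf(
        "rank deficiency: no PLS factor %d extractable (X'y ~ 0)", a),
        call. = FALSE)
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < .Machine$double.eps * scale0^2)
      stop(sprintf("rank deficiency: degenerate scores at factor %d", a),
           call. = FALSE)
    p <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- y_mean + drop(sweep(X, 2, x_means) %*% b)
  structure(
    list(n_factors = n_factors, W = W, P = P, q = q, T = Tm, b = b,
         x_means = x_means, y_mean = y_mean,
         rmsec = rmse(y, fitted), r = stats::cor(y, fitted)),
    class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d factors, %d features; RMSEC %.4g, r %.5f\n",
              x$n_factors, length(x$b), x$rmsec, x$r))
  invisible(x)
}

#' Predict content from a fitted PLS1 model
#'
#' y-hat = y_mean + (x - x_means) b, using the means stored at fit time.
#'
#' @param object a `pls1_model`.
#' @param newdata feature matrix or vector with the training feature length.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$b))
    stop("feature length mismatch with model", call. = FALSE)
  object$y_mean + drop(sweep(newdata, 2, object$x_means) %*% object$b)
}

#' Root mean square error and set-specific wrappers
#'
#' `rmse(y, yhat)` = sqrt(mean((yhat - y)^2)); `rmsec` and `rmsep` are the
#' same quantity named for the calibration and independent prediction
#' sets. When `y` is percent of label, the error is in percent of label.
#'
#' @param y reference values; `yhat` predictions, same length >= 1.
#' @param yhat predicted values.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must be non-empty and of equal length", call. = FALSE)
  sqrt(mean((yhat - y)^2))
}

#' @rdname rmse
#' @export
rmsec <- function(y, yhat) rmse(y, yhat)

#' @rdname rmse
#' @export
rmsep <- function(y, yhat) rmse(y, yhat)

#' Pearson correlation between reference and predicted content
#'
#' @param y,yhat equal-length vectors with non-zero variance.
#' @return Correlation coefficient r.
#' @export
correlation <- function(y, yhat) {
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(y, yhat)
}

#' Extremes of the prediction residuals
#'
#' @param y,yhat equal-length non-empty vectors.
#' @return `c(min, max)` of yhat - y (percent of label when y is).
#' @export
error_interval <- function(y, yhat) {
  if (!length(y)) stop("empty input", call. = FALSE)
  r <- yhat - y
  c(min(r), max(r))
}

# venetian-blinds fold assignment, optionally stratified
vb_folds <- function(n, folds, strata = NULL) {
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  fold
}

#' Cross-validated factor selection for PLS1
#'
#' Venetian-blinds cross-validation (interleaved folds, optionally
#' stratified by concentration level): for each fold, a model is fitted on
#' the remaining samples at 1..max_factors factors and the held-out
#' samples are predicted. RMSECV per factor count is the pooled root mean
#' square of all held-out residuals; the selected count is the global
#' minimum, ties resolved toward fewer factors.
#'
#' @param X feature matrix; `y` response.
#' @param y numeric response.
#' @param max_factors largest factor count evaluated (>= 1).
#' @param folds number of interleaved folds (default 6).
#' @param strata optional per-sample stratum (e.g. level) balanced across
#'   folds.
#' @return A `pls_cv` object: `rmsecv` (named vector over factor counts),
#'   `selected`, `scheme`.
#' @export
cross_validate <- function(X, y, max_factors, folds = 6, strata = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_factors < 1) stop("max_factors must be >= 1", call. = FALSE)
  if (folds < 2 || folds > n) stop("invalid fold count", call. = FALSE)
  fold <- vb_folds(n, folds, strata)
  if (any(tabulate(fold, folds) == 0))
    stop("cross-validation scheme produced an empty fold", call. = FALSE)
  sse <- numeric(max_factors)
  for (k in seq_len(folds)) {
    tr <- fold != k
    max_k <- min(max_factors, sum(tr) - 1L)
    # cap at the rank actually extractable from this training fold
    model <- NULL
    while (is.null(model) && max_k >= 1) {
      model <- tryCatch(fit_pls1(X[tr, , drop = FALSE], y[tr], max_k),
                        error = function(e) {
                          if (grepl("rank deficiency", conditionMessage(e)))
                            NULL else stop(e)
                        })
      if (is.null(model)) max_k <- max_k - 1L
    }
    if (is.null(model)) stop("cross-validation fold with no signal",
                             call. = FALSE)
    for (a in seq_len(max_factors)) {
      aa <- min(a, max_k)
      b_a <- drop(model$W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(model$P[, 1:aa, drop = FALSE],
                        model$W[, 1:aa, drop = FALSE]), model$q[1:aa]))
      pred <- model$y_mean +
        drop(sweep(X[!tr, , drop = FALSE], 2, model$x_means) %*% b_a)
      sse[a] <- sse[a] + sum((pred - y[!tr])^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  names(rmsecv) <- seq_len(max_factors)
  structure(list(rmsecv = rmsecv, selected = unname(which.min(rmsecv)),
                 scheme = sprintf("venetian blinds, %d folds%s", folds,
                                  if (is.null(strata)) "" else ", stratified")),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat("PLS cross-validation (", x$scheme, ")\n", sep = "")
  print(round(x$rmsecv, 4))
  cat("selected factors:", x$selected, "\n")
  invisible(x)
}
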