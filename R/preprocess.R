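#' Standard normal variate transform
#'
#' Per-spectrum standardization: (x - mean(x)) / sd(x) with the sample
#' (n-1) standard deviation. Removes a per-spectrum multiplicative gain
#' and additive offset, the classic scatter correction for
#' diffuse-reflectance powders.
#'
#' @param x numeric vector (one spectrum) or matrix (samples in rows).
#' @return Transformed vector/matrix with per-spectrum mean 0 and SD 1.
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  if (length(x) < 2) stop("SNV needs at least 2 points", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate spectrum: zero variance under SNV", call. = FALSE)
  (x - mean(x)) / s
}

# Savitzky-Golay convolution coefficients for the interior (center) point,
# scaled so the derivative is per x-unit given sampling interval ts.
sg_coefficients <- function(window, polyorder, deriv, ts) {
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = ts)
  F[(window + 1) / 2, ]
}

#' Savitzky-Golay derivative of spectra
#'
#' Local least-squares polynomial convolution. Only interior points are
#' returned: (window-1)/2 points are dropped at each edge so every output
#' value uses the exact central-window coefficients. The derivative is
#' reported per cm^-1 (coefficients scaled by the grid spacing), making
#' results invariant to the digitization interval.
#'
#' @param x spectrum vector or matrix (samples in rows).
#' @param spacing grid spacing in cm^-1.
#' @param window odd window length (points), default 11.
#' @param polyorder fitted polynomial order, default 2.
#' @param deriv derivative order, default 1.
#' @return Vector/matrix of length (points - window + 1).
#' @export
savgol_derivative <- function(x, spacing, window = 11, polyorder = 2,
                              deriv = 1) {
  if (window %% 2 != 1 || window <= polyorder)
    stop("invalid parameters: window must be odd and > polyorder",
         call. = FALSE)
  np <- if (is.matrix(x)) ncol(x) else length(x)
  if (np < window)
    stop("invalid parameters: spectrum shorter than window", call. = FALSE)
  co <- rev(sg_coefficients(window, polyorder, deriv, ts = spacing))
  if (is.matrix(x)) {
    out <- matrix(0, nrow(x), np - window + 1)
    for (i in seq_len(nrow(x))) out[i, ] <- drop(stats::embed(x[i, ], window) %*% co)
    rownames(out) <- rownames(x)
    return(out)
  }
  drop(stats::embed(x, window) %*% co)
}

#' Select grid indices inside a wavenumber region
#'
#' Closed interval on the digitized grid: indices with lo <= nu <= hi.
#'
#' @param grid a [wavenumber_grid].
#' @param lo,hi region bounds in cm^-1, lo < hi.
#' @return Integer index vector.
#' @export
select_region <- function(grid, lo, hi) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  idx <- which(grid$points >= lo & grid$points <= hi)
  if (!length(idx))
    stop(sprintf("region %g-%g cm-1 lies outside the grid", lo, hi),
         call. = FALSE)
  idx
}

#' Dual-region pre-processing plan
#'
#' An ordered recipe of spectral regions, each with its own treatment
#' chain, concatenated into one feature vector and (optionally)
#' mean-centered across samples. The default is the method's retained
#' combination: SNV followed by a first Savitzky-Golay derivative
#' (11-point window, second-order polynomial) on 5311-6811 cm^-1, raw
#' absorbance on 7200-9999 cm^-1, mean-centered.
#'
#' @param regions list of region specs, each
#'   `list(lo =, hi =, snv = TRUE/FALSE, sg = NULL | c(window, polyorder, deriv))`.
#' @param center logical: mean-center the concatenated feature matrix
#'   (means learned on the training set only).
#' @return A `preprocess_plan` object.
#' @export
preprocess_plan <- function(regions, center = TRUE) {
  for (r in regions) stopifnot(is.numeric(r$lo), is.numeric(r$hi), r$lo < r$hi)
  los <- vapply(regions, `[[`, numeric(1), "lo")
  his <- vapply(regions, `[[`, numeric(1), "hi")
  o <- order(los)
  if (any(los[o][-1] < his[o][-length(his)]))
    stop("regions must not overlap", call. = FALSE)
  structure(list(regions = regions, center = center),
            class = "preprocess_plan")
}

#' @rdname preprocess_plan
#' @export
dual_region_plan <- function(center = TRUE) {
  preprocess_plan(list(
    list(lo = 5311, hi = 6811, snv = TRUE, sg = c(window = 11, polyorder = 2, deriv = 1)),
    list(lo = 7200, hi = 9999, snv = FALSE, sg = NULL)),
    center = center)
}

#' Identity plan over the full grid (no treatment)
#' @param grid a [wavenumber_grid].
#' @param center logical, mean-center features.
#' @return A `preprocess_plan`.
#' @export
identity_plan <- function(grid, center = TRUE) {
  preprocess_plan(list(list(lo = min(grid$points), hi = max(grid$points),
                            snv = FALSE, sg = NULL)), center = center)
}

region_features <- function(A, grid, region) {
  idx <- select_region(grid, region$lo, region$hi)
  X <- A[, idx, drop = FALSE]
  if (isTRUE(region$snv)) X <- snv(X)
  if (!is.null(region$sg)) {
    sg <- region$sg
    X <- savgol_derivative(X, spacing = grid$spacing, window = sg[[1]],
                           polyorder = sg[[2]], deriv = sg[[3]])
  }
  X
}

#' Apply a pre-processing plan (fit or transform)
#'
#' Fitting mode (`plan` is a [preprocess_plan]): treats each region,
#' concatenates the feature blocks, computes and stores the training
#' column means, and subtracts them. Transform mode (`plan` is the fitted
#' `nir_features` object from a previous call): applies the identical
#' chain and subtracts the *stored* training means — centering is never
#' re-learned from test spectra.
#'
#' @param spectra a [spectra_set].
#' @param plan a `preprocess_plan` (fit) or `nir_features` (transform).
#' @return Fit mode: an `nir_features` object with elements `features`
#'   (matrix), `means`, `plan`. Transform mode: the feature matrix.
#' @export
apply_plan <- function(spectra, plan) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (inherits(plan, "nir_features")) {
    fitted <- plan
    blocks <- lapply(fitted$plan$regions, region_features,
                     A = spectra$absorbance, grid = spectra$grid)
    X <- do.call(cbind, blocks)
    if (ncol(X) != length(fitted$means) && fitted$plan$center)
      stop("feature length mismatch with fitted plan", call. = FALSE)
    if (fitted$plan$center) X <- sweep(X, 2, fitted$means)
    return(X)
  }
  stopifnot(inherits(plan, "preprocess_plan"))
  blocks <- lapply(plan$regions, region_features,
                   A = spectra$absorbance, grid = spectra$grid)
  X <- do.call(cbind, blocks)
  means <- if (plan$center) colMeans(X) else numeric(ncol(X))
  if (plan$center) X <- sweep(X, 2, means)
  structure(list(features = X, means = means, plan = plan),
            class = "nir_features")
}
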