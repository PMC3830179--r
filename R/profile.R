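#' Relative recovery errors
#'
#' 100 * (recovered - level) / level: the signed percent deviation of the
#' recovered content from the (gravimetric) true level, the scale on
#' which accuracy profiles and the +/- lambda acceptance limits live.
#'
#' @param level true content (percent of label), > 0 (scalar or vector).
#' @param recovered recovered content (percent of label).
#' @return Relative errors in percent.
#' @export
relative_results <- function(level, recovered) {
  if (any(level <= 0)) stop("level must be > 0", call. = FALSE)
  100 * (recovered - level) / level
}

#' One-way random-effects variance components
#'
#' Method-of-moments decomposition of a balanced p-series x n-replicates
#' table of errors into within-series variance s_W^2 = MS_within and
#' between-series variance s_B^2 = max(0, (MS_between - MS_within)/n),
#' with the grand mean as the bias estimate. Mean squares come from a
#' one-way ANOVA on the series factor.
#'
#' @param errors numeric vector of (relative) errors.
#' @param series parallel vector of series identifiers.
#' @return List with `s2_within`, `s2_between`, `bias`, `p` (series),
#'   `n` (replicates per series).
#' @export
variance_components <- function(errors, series) {
  if (length(errors) != length(series)) stop("length mismatch", call. = FALSE)
  series <- factor(series)
  p <- nlevels(series)
  counts <- table(series)
  if (p < 2) stop("need at least 2 series", call. = FALSE)
  if (length(unique(counts)) != 1L)
    stop("unbalanced design: equal replicates per series required",
         call. = FALSE)
  n <- as.integer(counts[1])
  if (n < 2) stop("need at least 2 replicates per series", call. = FALSE)
  # aov warns about unreliable F-tests when the fit is exact; only the
  # mean squares are used here, so that warning is irrelevant
  aovtab <- withCallingHandlers(
    stats::anova(stats::aov(errors ~ series)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ms_between <- aovtab["series", "Mean Sq"]
  ms_within <- aovtab["Residuals", "Mean Sq"]
  list(s2_within = ms_within,
       s2_between = max(0, (ms_between - ms_within) / n),
       bias = mean(errors), p = p, n = n)
}

#' Beta-expectation tolerance interval
#'
#' The interval expected to contain a fraction beta of future individual
#' measurements, built from the bias and the one-way variance components
#' (Mee-type limits with Satterthwaite degrees of freedom). With
#' R = s_B^2/s_W^2, B^2 = (R + 1)/(nR + 1) and
#' nu = (R + 1)^2 / \[ (R + 1/n)^2/(p - 1) + (1 - 1/n)/(p n) \], the
#' limits are bias +/- t(nu, (1+beta)/2) * s_IP * sqrt(1 + 1/(p n B^2))
#' with s_IP^2 = s_W^2 + s_B^2 the intermediate-precision variance.
#'
#' Degenerate cases: both variances zero gives the point interval
#' (bias, bias); s_W^2 = 0 with s_B^2 > 0 uses the R -> Inf limits
#' B^2 = 1/n, nu = p - 1.
#'
#' @param bias mean (relative) error.
#' @param s2_within,s2_between variance components (>= 0).
#' @param p,n series count and replicates per series.
#' @param beta expectation proportion in (0, 1), default 0.95.
#' @return List with `lower`, `upper`, `s_ip`, `df`.
#' @export
tolerance_interval <- function(bias, s2_within, s2_between, p, n,
                               beta = 0.95) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)", call. = FALSE)
  if (s2_within < 0 || s2_between < 0)
    stop("variances must be >= 0", call. = FALSE)
  s_ip <- sqrt(s2_within + s2_between)
  if (s_ip == 0)
    return(list(lower = bias, upper = bias, s_ip = 0, df = Inf))
  if (s2_within == 0) {
    B2 <- 1 / n
    df <- p - 1
  } else {
    R <- s2_between / s2_within
    B2 <- (R + 1) / (n * R + 1)
    df <- (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  }
  half <- stats::qt((1 + beta) / 2, df) * s_ip * sqrt(1 + 1 / (p * n * B2))
  list(lower = bias - half, upper = bias + half, s_ip = s_ip, df = df)
}

#' Accuracy profile of a validation study
#'
#' Per concentration level: mean relative bias, within/between-series
#' standard deviations, intermediate precision, and the beta-expectation
#' tolerance interval, judged against fixed acceptance limits
#' +/- lambda. The procedure is declared valid when every level's
#' tolerance interval lies inside (-lambda, +lambda).
#'
#' @param data data.frame with columns `level_percent`, `series_id`,
#'   `replicate_id`, `recovered_percent` (long format, balanced within
#'   level). An optional `true_percent` column gives the per-sample
#'   gravimetric reference; when absent the nominal `level_percent` is
#'   the reference.
#' @param beta expectation proportion (default 0.95).
#' @param lambda acceptance limit in percent (default 5).
#' @return An `accuracy_profile`: `table` (one row per level with bias,
#'   s_w, s_b, s_ip, df, lower, upper), `beta`, `lambda`, `pass`.
#' @export
accuracy_profile <- function(data, beta = 0.95, lambda = 5) {
  need <- c("level_percent", "series_id", "recovered_percent")
  if (!all(need %in% names(data)))
    stop("data must have columns level_percent, series_id, recovered_percent",
         call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  levels_ <- sort(unique(data$level_percent))
  rows <- lapply(levels_, function(L) {
    d <- data[data$level_percent == L, ]
    ref <- if (is.null(d$true_percent)) L else d$true_percent
    err <- relative_results(ref, d$recovered_percent)
    vc <- variance_components(err, d$series_id)
    ti <- tolerance_interval(vc$bias, vc$s2_within, vc$s2_between,
                             vc$p, vc$n, beta)
    data.frame(level_percent = L, bias = vc$bias,
               s_w = sqrt(vc$s2_within), s_b = sqrt(vc$s2_between),
               s_ip = ti$s_ip, df = ti$df,
               lower = ti$lower, upper = ti$upper)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, beta = beta, lambda = lambda,
                 pass = all(tab$lower > -lambda & tab$upper < lambda)),
            class = "accuracy_profile")
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat(sprintf("Accuracy profile (beta = %.2f, acceptance +/- %g%%): %s\n",
              x$beta, x$lambda, if (x$pass) "PASS" else "FAIL"))
  print(cbind(round(x$table[, c("level_percent", "bias", "s_ip")], 3),
              tolerance = sprintf("[%.2f; %.2f]", x$table$lower,
                                  x$table$upper)),
        row.names = FALSE)
  invisible(x)
}

#' Plot an accuracy profile
#'
#' Bias line with the beta-expectation tolerance band against the
#' +/- lambda acceptance rails.
#'
#' @param x an `accuracy_profile`.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.accuracy_profile <- function(x, main = "Accuracy profile", ...) {
  tab <- x$table
  ylim <- range(c(tab$lower, tab$upper, -x$lambda, x$lambda)) * 1.15
  graphics::plot(tab$level_percent, tab$bias, type = "o", pch = 16,
                 ylim = ylim, xlab = "Level (% of label)",
                 ylab = "Relative error (%)", main = main, ...)
  graphics::polygon(c(tab$level_percent, rev(tab$level_percent)),
                    c(tab$lower, rev(tab$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(tab$level_percent, tab$lower, lty = 2, col = "steelblue4")
  graphics::lines(tab$level_percent, tab$upper, lty = 2, col = "steelblue4")
  graphics::abline(h = c(-x$lambda, x$lambda), col = "red3", lty = 3)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Mean content and relative standard deviation
#'
#' @param x replicate content determinations (>= 2 values, non-zero mean).
#' @return `c(mean =, rsd =)` with RSD = 100 * SD / mean, in percent.
#' @export
content_summary <- function(x) {
  if (length(x) < 2) stop("need at least 2 determinations", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("zero mean content", call. = FALSE)
  c(mean = m, rsd = 100 * stats::sd(x) / m)
}
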