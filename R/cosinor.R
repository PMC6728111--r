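# Single-cosinor rhythmometry with a fixed 24-h period. The model
#   y(t) = M + A * cos(2*pi*t/period + phi),  A >= 0, phi in (-2*pi, 0],
# is linearized as y = M + beta*cos(w t) + gamma*sin(w t) and solved by
# least squares, which is exact for a fixed period. Rhythm detection uses
# the zero-amplitude F-test, F = (MSS/2) / (RSS/(n-3)) on (2, n-3) df.

#' Fit the single-cosinor model to a temperature series
#'
#' Times are hours since local midnight (for a [cbt_series()] the recording
#' start hour is applied automatically), so the reported acrophase follows
#' the convention that acrophase 0 corresponds to a peak at local midnight.
#' Missing values are simply omitted from the design; no imputation is
#' needed for fitting.
#'
#' @param x a [cbt_series()] or a numeric vector of temperatures.
#' @param t observation times in hours since local midnight (ignored when
#'   `x` is a `cbt_series`; defaults to `0, 1, ...` otherwise).
#' @param period fixed rhythm period in hours (24 for circadian).
#' @param alpha significance level for the rhythm-detection gate.
#' @return object of class `cosinor_fit`: `mesor` (degC), `amplitude`
#'   (degC, >= 0), `acrophase_rad` (radians, in (-2*pi, 0]), `peak_time`
#'   (clock hours in [0, 24); `NA` when the amplitude is zero), `period`,
#'   `n`, `F_stat`, `p_value`, `percent_rhythm`, `model_data_correlation`,
#'   `rhythm_detected` (`p_value <= alpha`), plus observed/fitted values.
#' @examples
#' t <- 0:23
#' fit_cosinor(37 + 0.5 * cos(2 * pi * (t - 19) / 24), t = t)
#' @export
fit_cosinor <- function(x, t = NULL, period = 24, alpha = 0.05) {
  if (inherits(x, "cbt_series")) {
    y <- x$values
    t <- abs_time_h(x)
    id <- x$patient_id; group <- x$group; phase <- x$phase
  } else {
    y <- as.numeric(x)
    if (is.null(t)) t <- seq_along(y) - 1
    id <- NA_character_; group <- NA_character_; phase <- NA_character_
  }
  keep <- !is.na(y)
  y <- y[keep]; t <- t[keep]
  n <- length(y)
  if (n < 4) stop("cosinor fit requires at least 4 non-missing points")
  if (length(unique(t)) == 1L) stop("all observation times are identical")
  w <- 2 * pi / period
  X <- cbind(mesor = 1, cosw = cos(w * t), sinw = sin(w * t))
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stop("singular cosinor design: observations cover a single phase of the cycle")
  }
  cf <- qr.coef(qrX, y)
  M <- unname(cf[1]); beta <- unname(cf[2]); gamma <- unname(cf[3])
  A <- sqrt(beta^2 + gamma^2)
  zero_amp <- A < 1e-12 * max(1, abs(M))
  acr <- atan2(-gamma, beta) %% (2 * pi)
  if (acr > 0) acr <- acr - 2 * pi            # map into (-2*pi, 0]
  if (acr <= -2 * pi + 1e-9) acr <- acr + 2 * pi  # snap boundary wrap to 0
  peak <- if (zero_amp) NA_real_ else (-acr * period / (2 * pi)) %% period
  if (!is.na(peak) && peak >= period - 1e-9) peak <- 0
  fitted <- drop(X %*% cf)

  fit <- structure(
    list(mesor = M, amplitude = if (zero_amp) 0 else A,
         acrophase_rad = if (zero_amp) 0 else acr,
         peak_time = peak, period = period, n = n,
         coefficients = c(mesor = M, cosw = beta, sinw = gamma),
         observed = y, fitted = fitted, t = t, alpha = alpha,
         patient_id = id, group = group, phase = phase),
    class = "cosinor_fit"
  )
  zt <- zero_amplitude_test(fit, alpha = alpha)
  pr <- percent_rhythm(fit)
  fit$F_stat <- zt$F
  fit$p_value <- zt$p
  fit$rhythm_detected <- zt$rhythm_detected
  fit$model_data_correlation <- pr$correlation
  fit$percent_rhythm <- pr$percent_rhythm
  fit
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> n=%d, period=%g h\n", x$n, x$period))
  cat(sprintf("  mesor %.3f degC, amplitude %.3f degC, peak %s\n",
              x$mesor, x$amplitude,
              if (is.na(x$peak_time)) "undefined (zero amplitude)"
              else sprintf("%05.2f h", x$peak_time)))
  cat(sprintf("  rhythm detection: F=%.3g, p=%.3g -> %s\n",
              x$F_stat, x$p_value,
              if (isTRUE(x$rhythm_detected)) "rhythm detected" else "no rhythm"))
  if (!is.na(x$percent_rhythm)) {
    cat(sprintf("  model-data correlation %.3f, percent rhythm %.3f\n",
                x$model_data_correlation, x$percent_rhythm))
  }
  invisible(x)
}

#' Zero-amplitude rhythm-detection test
#'
#' Tests the fitted cosine against a flat mean:
#' `F = (MSS/2) / (RSS/(n-3))` with `MSS = sum((fitted - mean)^2)` and
#' `RSS = sum((observed - fitted)^2)`, referred to the F(2, n-3) upper
#' tail. A perfect fit (RSS = 0) reports `F = Inf`, `p = 0`. Fits with
#' `p > alpha` are flagged so their rhythm parameters are not employed in
#' cohort statistics.
#'
#' @param fit a `cosinor_fit`.
#' @param alpha significance level of the gate.
#' @return list: `F`, `p`, `df` (c(2, n-3)), `rhythm_detected`.
#' @export
zero_amplitude_test <- function(fit, alpha = fit$alpha %||% 0.05) {
  stopifnot(inherits(fit, "cosinor_fit"))
  n <- fit$n
  if (n <= 3) stop("zero-amplitude test requires n > 3")
  y <- fit$observed; yhat <- fit$fitted
  MSS <- sum((yhat - mean(y))^2)
  RSS <- sum((y - yhat)^2)
  tot <- MSS + RSS
  if (RSS <= 1e-12 * max(tot, 1)) {
    if (MSS <= 1e-12 * max(tot, 1)) {        # constant series: no variance at all
      return(list(F = 0, p = 1, df = c(2, n - 3), rhythm_detected = FALSE))
    }
    return(list(F = Inf, p = 0, df = c(2, n - 3), rhythm_detected = TRUE))
  }
  Fv <- (MSS / 2) / (RSS / (n - 3))
  p <- pf(Fv, 2, n - 3, lower.tail = FALSE)
  list(F = Fv, p = p, df = c(2, n - 3), rhythm_detected = p <= alpha)
}

#' Percent rhythm (coefficient of determination of the cosinor fit)
#'
#' The correlation between observed and cosinor-fitted values, and its
#' square: the fraction of variance explained by the rhythm. Undefined for
#' a zero-amplitude fit (constant fitted values), in which case both are
#' `NA` with a `reason`.
#'
#' @param fit a `cosinor_fit`.
#' @return list: `correlation`, `percent_rhythm`, and `reason` (only when
#'   undefined).
#' @export
percent_rhythm <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (sd(fit$fitted) < 1e-12 * max(1, abs(fit$mesor))) {
    return(list(correlation = NA_real_, percent_rhythm = NA_real_,
                reason = "zero-amplitude fit: fitted values are constant"))
  }
  if (sd(fit$observed) == 0) {
    return(list(correlation = NA_real_, percent_rhythm = NA_real_,
                reason = "observed values are constant"))
  }
  r <- cor(fit$observed, fit$fitted)
  list(correlation = r, percent_rhythm = r^2)
}

#' Peak clock time of the fitted rhythm
#'
#' The clock time (hours in [0, 24)) at which the fitted cosine attains its
#' maximum; acrophase 0 corresponds to a peak at local midnight. Because
#' fitting uses absolute clock time, the result does not depend on when
#' within the day the recording started.
#'
#' @param fit a `cosinor_fit`.
#' @return peak clock time in hours.
#' @export
peak_clock_time <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$amplitude == 0) {
    stop("peak time is undefined for a zero-amplitude fit")
  }
  fit$peak_time
}

#' Cosinor fits for a list of series, as a table
#'
#' @param series_list list of hourly [cbt_series()].
#' @param alpha rhythm-detection significance level.
#' @return data.frame with one row per (patient, phase): mesor, amplitude,
#'   peak_time, acrophase_rad, F_stat, p_value, percent_rhythm,
#'   model_data_correlation, rhythm_detected, n.
#' @export
cosinor_table <- function(series_list, alpha = 0.05) {
  rows <- lapply(series_list, function(s) {
    fit <- fit_cosinor(s, alpha = alpha)
    data.frame(
      patient_id = s$patient_id, group = s$group, phase = s$phase,
      mesor = fit$mesor, amplitude = fit$amplitude,
      peak_time = fit$peak_time, acrophase_rad = fit$acrophase_rad,
      F_stat = fit$F_stat, p_value = fit$p_value,
      percent_rhythm = fit$percent_rhythm,
      model_data_correlation = fit$model_data_correlation,
      rhythm_detected = fit$rhythm_detected, n = fit$n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
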