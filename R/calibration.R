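#' Calibration model linking RSS to distance
#'
#' Container for the fitted log-linear path-loss relationship
#' `log10(distance) = b0 + b1 * RSS`. `resid_sd` is the residual SD on the
#' log10 scale; `d_max` is the truncation ceiling: distances predicted
#' beyond the largest calibrated distance are truncated to it, because the
#' relationship is unvalidated out there.
#'
#' @param b0 Intercept, log10-metres.
#' @param b1 Slope, log10-metres per dB (non-zero).
#' @param resid_sd Residual SD on the log10(distance) scale (>= 0).
#' @param d_max Truncation ceiling in metres (default 150).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(b0, b1, resid_sd = 0, d_max = 150) {
  check_number(b0, "b0")
  check_number(b1, "b1")
  if (b1 == 0) stop("`b1` must be non-zero", call. = FALSE)
  check_number(resid_sd, "resid_sd", nonneg = TRUE)
  check_number(d_max, "d_max", positive = TRUE)
  structure(list(b0 = b0, b1 = b1, resid_sd = resid_sd, d_max = d_max),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "RSS-distance calibration: distance = 10^(%.5f %+.5f * RSS) m\n  residual SD %.4g (log10 scale), truncation at %.0f m\n",
    x$b0, x$b1, x$resid_sd, x$d_max))
  invisible(x)
}

#' Fit the RSS-distance calibration
#'
#' Ordinary least squares of `log10(distance)` on RSS over calibration
#' observations. The truncation ceiling `d_max` is set to the largest
#' calibrated distance, beyond which predictions are not trusted.
#'
#' @param calib Data frame with columns `distance_m` and `rss`; at least two
#'   distinct distances are required.
#' @return A [calibration_model()].
#' @export
fit_calibration <- function(calib) {
  check_columns(calib, c("distance_m", "rss"), "calib")
  calib <- calib[is.finite(calib$distance_m) & is.finite(calib$rss), ]
  if (any(calib$distance_m <= 0))
    stop("calibration distances must be positive", call. = FALSE)
  if (length(unique(calib$distance_m)) < 2L)
    stop("need at least two distinct calibration distances", call. = FALSE)
  if (diff(range(calib$rss)) < 1e-12)
    stop("all RSS values identical: calibration fit is singular",
         call. = FALSE)

  fit <- lm(log10(distance_m) ~ rss, data = calib)
  res <- stats::residuals(fit)
  df <- stats::df.residual(fit)
  resid_sd <- if (df > 0) sqrt(sum(res^2) / df) else 0
  calibration_model(
    b0 = unname(coef(fit)[1L]),
    b1 = unname(coef(fit)[2L]),
    resid_sd = resid_sd,
    d_max = max(calib$distance_m)
  )
}

#' Convert RSS to a distance estimate
#'
#' Evaluates the calibration `d = 10^(b0 + b1 * RSS)`, truncating at the
#' model's ceiling `d_max`. The standard error is propagated from the
#' calibration residual SD by the delta method on the log10 scale,
#' `d_se = d * ln(10) * resid_sd`, computed from the untruncated distance
#' and carried unchanged through truncation.
#'
#' @param rss RSS value(s) in dB; must be finite.
#' @param model A [calibration_model()].
#' @return Data frame with columns `d_hat` (metres, `<= d_max`) and `d_se`.
#' @export
rss_to_distance <- function(rss, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!length(rss) || !all(is.finite(rss)))
    stop("`rss` must be finite", call. = FALSE)
  d_raw <- 10^(model$b0 + model$b1 * rss)
  data.frame(
    d_hat = pmin(d_raw, model$d_max),
    d_se = d_raw * log(10) * model$resid_sd
  )
}
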