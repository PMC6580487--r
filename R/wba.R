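# Whole-body autoradiography: standard-curve fit and raw-signal -> dpm
# transformation.

#' Fit the WBA radioactivity standard curve
#'
#' Ordinary least-squares line `dpm = slope * raw_signal + intercept`
#' through the calibration standards (known radioactive concentration
#' spots imaged alongside the tissue sections). The regression is in the
#' prediction direction because the transform maps raw signal to dpm.
#'
#' @param standards Data frame with numeric columns `raw_signal` and
#'   `known_dpm`; at least 2 rows with non-identical `raw_signal`.
#' @return An object of class `cdp_standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `n_standards`.
#' @export
#' @examples
#' fit_standard_curve(data.frame(raw_signal = 0:3, known_dpm = 2 * (0:3) + 1))
fit_standard_curve <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("raw_signal", "known_dpm") %in% names(standards))) {
    stop("`standards` needs columns raw_signal and known_dpm",
         call. = FALSE)
  }
  x <- as.numeric(standards$raw_signal)
  y <- as.numeric(standards$known_dpm)
  if (length(x) < 2L) {
    stop("at least 2 standards are required", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("standards must be finite", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("standards have zero variance in raw_signal", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_standards = length(x)),
            class = "cdp_standard_curve")
}

#' @export
print.cdp_standard_curve <- function(x, ...) {
  cat(sprintf(
    "<cdp_standard_curve> dpm = %.6g * raw + %.6g (r2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

#' Transform raw tissue signals to decays per minute
#'
#' Applies the fitted standard curve to each tissue measurement. Negative
#' predictions (raw signal below the calibration line's zero crossing) are
#' clamped to 0 and flagged `below_curve`, since radioactivity cannot be
#' negative.
#'
#' @param measurements Data frame with columns `tissue` and `raw_signal`.
#' @param curve A [fit_standard_curve()] result.
#' @return The input data frame with added columns `dpm` and `flag`
#'   (`""` or `"below_curve"`).
#' @export
to_dpm <- function(measurements, curve) {
  stopifnot(inherits(curve, "cdp_standard_curve"))
  measurements <- as.data.frame(measurements)
  if (!all(c("tissue", "raw_signal") %in% names(measurements))) {
    stop("`measurements` needs columns tissue and raw_signal",
         call. = FALSE)
  }
  dpm <- curve$slope * as.numeric(measurements$raw_signal) +
    curve$intercept
  below <- dpm < 0
  measurements$dpm <- ifelse(below, 0, dpm)
  measurements$flag <- ifelse(below, "below_curve", "")
  measurements
}
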