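# Blank-subtraction normalization and robust noise estimation.

#' Subtract a blank run from a sample trace
#'
#' The blank absorbance is linearly interpolated onto the sample's RT grid
#' and subtracted pointwise; this removes the system/gradient baseline that
#' the blank injection captures. The blank may fall short of the sample
#' domain by at most `edge_steps` sample grid steps at each end, over which
#' the nearest blank value is held flat.
#'
#' @param sample A [trace()] (treatment `intact` or `reduced`).
#' @param blank A [trace()] with treatment `blank`.
#' @param edge_steps Allowed shortfall of the blank domain, in sample grid
#'   steps at each end (default 2).
#' @return A normalized trace: class `cdp_trace_normalized`/`cdp_trace`,
#'   same RT grid as `sample`, with `blank_id` recording the subtracted
#'   blank.
#' @export
subtract_blank <- function(sample, blank, edge_steps = 2) {
  stopifnot(inherits(sample, "cdp_trace"), inherits(blank, "cdp_trace"))
  step <- stats::median(diff(sample$rt))
  tol <- edge_steps * step * (1 + 1e-9)  # slack for grid-arithmetic fp
  if (blank$rt[1L] > sample$rt[1L] + tol ||
      blank$rt[length(blank$rt)] < sample$rt[length(sample$rt)] - tol) {
    stop(sprintf(
      "blank '%s' RT domain [%.3f, %.3f] does not cover sample '%s' domain [%.3f, %.3f]",
      blank$sample_id, blank$rt[1L], blank$rt[length(blank$rt)],
      sample$sample_id, sample$rt[1L], sample$rt[length(sample$rt)]),
      call. = FALSE)
  }
  base <- stats::approx(blank$rt, blank$absorbance, xout = sample$rt,
                        method = "linear", rule = 2)$y
  out <- trace(sample$sample_id, sample$treatment, sample$rt,
               sample$absorbance - base)
  out$blank_id <- blank$sample_id
  class(out) <- c("cdp_trace_normalized", class(out))
  out
}

#' Estimate baseline noise of a normalized trace
#'
#' The default estimator is `1.4826 * MAD` of the trace restricted to a
#' peak-free region, which is robust to a small fraction of outlying
#' points. With `region = "auto"` the region is the flanks outside the
#' peak search window `[min_rt, max_rt]`; if that leaves fewer than 10
#' points the estimate falls back to the lower quartile of the absolute
#' first differences of the full trace divided by `sqrt(2)` (a
#' conservative, peak-insensitive fallback).
#'
#' @param x A normalized (or plain) [trace()] object.
#' @param region `"auto"` or a numeric length-2 RT interval.
#' @param peak_window Numeric length-2 `[min_rt, max_rt]` peak search
#'   window used by `"auto"`; required then.
#' @return Non-negative noise sigma in absorbance units.
#' @export
estimate_noise <- function(x, region = "auto", peak_window = NULL) {
  stopifnot(inherits(x, "cdp_trace"))
  y <- x$absorbance
  if (is.numeric(region)) {
    if (length(region) != 2L || region[2L] <= region[1L]) {
      stop("`region` must be an increasing RT interval", call. = FALSE)
    }
    if (region[2L] < x$rt[1L] || region[1L] > x$rt[length(x$rt)]) {
      stop("noise region lies outside the trace RT domain", call. = FALSE)
    }
    sel <- x$rt >= region[1L] & x$rt <= region[2L]
    if (sum(sel) < 10L) {
      stop("noise region contains fewer than 10 points", call. = FALSE)
    }
    return(stats::mad(y[sel]))
  }
  if (!identical(region, "auto")) {
    stop("`region` must be \"auto\" or a numeric interval", call. = FALSE)
  }
  if (is.null(peak_window)) {
    stop("`peak_window` is required when region = \"auto\"", call. = FALSE)
  }
  sel <- x$rt < peak_window[1L] | x$rt > peak_window[2L]
  if (sum(sel) >= 10L) {
    return(stats::mad(y[sel]))
  }
  unname(stats::quantile(abs(diff(y)), 0.25, names = FALSE) / sqrt(2))
}
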