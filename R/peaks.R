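# SNR-gated peak and shoulder detection inside a retention-time window.

#' Peak detection parameters
#'
#' Mirrors the classifier application's tunables: the signal-to-noise gate
#' (`-SN`) and the retention-time search window (`-MinRTForPeak`,
#' `-MaxRTForPeak`), plus the smoothing width and the valley-fraction
#' criterion that separates shoulder peaks from resolved peaks.
#'
#' @param sn Signal-to-noise threshold (> 0). A local maximum counts as a
#'   peak only if both its height and its prominence reach `sn * sigma`.
#' @param min_rt,max_rt Retention-time window (minutes) searched for peaks.
#' @param smooth_window Moving-average width in points; odd, >= 1.
#' @param shoulder_valley_frac Fraction in (0, 1]: a secondary feature whose
#'   separating valley stays at or above this fraction of the smaller apex
#'   height is a shoulder; below it, a resolved peak.
#' @return An object of class `cdp_peak_params`.
#' @export
peak_params <- function(sn = 10, min_rt = 5, max_rt = 12,
                        smooth_window = 5, shoulder_valley_frac = 0.7) {
  if (!is.numeric(sn) || sn <= 0) stop("`sn` must be > 0", call. = FALSE)
  if (min_rt >= max_rt) stop("`min_rt` must be < `max_rt`", call. = FALSE)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("`smooth_window` must be odd and >= 1", call. = FALSE)
  }
  if (shoulder_valley_frac <= 0 || shoulder_valley_frac > 1) {
    stop("`shoulder_valley_frac` must be in (0, 1]", call. = FALSE)
  }
  structure(list(sn = sn, min_rt = min_rt, max_rt = max_rt,
                 smooth_window = smooth_window,
                 shoulder_valley_frac = shoulder_valley_frac),
            class = "cdp_peak_params")
}

# Moving average with shrinking windows at the edges.
.runmean <- function(y, w) {
  if (w <= 1L) return(y)
  n <- length(y)
  k <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Interior local maxima with plateau midpoints. Returns integer indices.
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  if (m < 3L) return(integer(0))
  out <- integer(0)
  for (g in 2:(m - 1L)) {
    if (v[g] > v[g - 1L] && v[g] > v[g + 1L]) {
      out <- c(out, (starts[g] + ends[g]) %/% 2L)
    }
  }
  out
}

# Topographic prominence of maxima at indices `idx` on curve y.
.prominences <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    # left: min until a strictly higher point (or start)
    j <- i
    lmin <- h
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      if (y[j] < lmin) lmin <- y[j]
    }
    j <- i
    rmin <- h
    n <- length(y)
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      if (y[j] < rmin) rmin <- y[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

.empty_peaks <- function() {
  data.frame(apex_rt = numeric(0), apex_height = numeric(0),
             left_rt = numeric(0), right_rt = numeric(0),
             is_shoulder = logical(0), prominence = numeric(0))
}

.snr_threshold <- function(params, sigma, ys) {
  if (sigma > 0) params$sn * sigma else 1e-8 * max(ys, 1e-300)
}

#' Detect peaks in a blank-normalized trace
#'
#' The trace is smoothed with a centered moving average; local maxima with
#' both height and topographic prominence at or above `sn * sigma` and apex
#' inside `[min_rt, max_rt]` are reported as peaks. The apex is refined to
#' the unsmoothed maximum within the smoothed peak's support, and plateau
#' maxima report their midpoint. Shoulder peaks (partially resolved
#' features) are then added and flagged via [detect_shoulders()]. With
#' `sigma = 0` (noise-free input) the SNR gate degrades to a machine-scale
#' fraction of the trace maximum.
#'
#' @param x A normalized [trace()] object.
#' @param params A [peak_params()] object.
#' @param sigma Noise estimate from [estimate_noise()]; >= 0.
#' @return A data frame with one row per peak, ordered by `apex_rt`:
#'   `apex_rt`, `apex_height`, `left_rt`, `right_rt`, `is_shoulder`,
#'   `prominence`.
#' @export
detect_peaks <- function(x, params = peak_params(), sigma) {
  stopifnot(inherits(x, "cdp_trace"), inherits(params, "cdp_peak_params"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  rt <- x$rt
  y <- x$absorbance
  n <- length(y)
  if (params$max_rt < rt[1L] || params$min_rt > rt[n]) {
    stop("peak window [min_rt, max_rt] lies outside the trace RT domain",
         call. = FALSE)
  }
  ys <- .runmean(y, params$smooth_window)
  thr <- .snr_threshold(params, sigma, ys)
  cand <- .local_maxima(ys)
  if (length(cand)) {
    cand <- cand[.prominences(ys, cand) >= thr]
  }
  if (length(cand) == 0L) {
    return(detect_shoulders(x, .empty_peaks(), params, sigma))
  }
  # supports: split at the smoothed minimum between consecutive kept maxima
  cuts <- integer(length(cand) + 1L)
  cuts[1L] <- 1L
  cuts[length(cand) + 1L] <- n
  if (length(cand) > 1L) {
    for (j in seq_len(length(cand) - 1L)) {
      seg <- cand[j]:cand[j + 1L]
      cuts[j + 1L] <- seg[which.min(ys[seg])]
    }
  }
  rows <- lapply(seq_along(cand), function(j) {
    lo <- cuts[j]
    hi <- cuts[j + 1L]
    seg <- lo:hi
    ties <- seg[y[seg] == max(y[seg])]
    apex <- ties[(length(ties) + 1L) %/% 2L]  # plateau midpoint
    data.frame(apex_rt = rt[apex], apex_height = y[apex],
               left_rt = rt[lo], right_rt = rt[hi],
               is_shoulder = FALSE,
               prominence = .prominences(ys, cand[j]))
  })
  peaks <- do.call(rbind, rows)
  keep <- peaks$apex_rt >= params$min_rt & peaks$apex_rt <= params$max_rt &
    peaks$apex_height >= thr
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  detect_shoulders(x, peaks, params, sigma)
}

#' Flag and recruit shoulder peaks
#'
#' Applies the valley-fraction criterion to a detected peak list. Two
#' mechanisms produce shoulders: (1) among adjacent detected maxima, if the
#' smoothed valley between them does not descend below
#' `shoulder_valley_frac * min(apex heights)`, the smaller apex is flagged
#' `is_shoulder = TRUE` (a partially resolved doublet); (2) overlapping
#' components too close to produce a second local maximum are recruited
#' from local maxima of the negative second derivative (curvature) of the
#' smoothed trace, subject to the same SNR height gate and the same
#' valley-fraction criterion against the nearest accepted apex. Fully
#' resolved peaks keep `is_shoulder = FALSE`.
#'
#' @inheritParams detect_peaks
#' @param peaks Data frame from [detect_peaks()] on the same trace.
#' @return The augmented peak data frame, ordered by `apex_rt`.
#' @export
detect_shoulders <- function(x, peaks, params = peak_params(), sigma) {
  stopifnot(inherits(x, "cdp_trace"), inherits(params, "cdp_peak_params"))
  rt <- x$rt
  y <- x$absorbance
  n <- length(y)
  ys <- .runmean(y, params$smooth_window)
  thr <- .snr_threshold(params, sigma, ys)
  frac <- params$shoulder_valley_frac
  if (nrow(peaks) == 0L) return(peaks)
  peaks <- peaks[order(peaks$apex_rt), , drop = FALSE]
  apex_idx <- vapply(peaks$apex_rt, function(a) which.min(abs(rt - a)),
                     integer(1))

  # (1) valley-fraction flagging among adjacent detected maxima
  if (nrow(peaks) > 1L) {
    for (j in seq_len(nrow(peaks) - 1L)) {
      seg <- apex_idx[j]:apex_idx[j + 1L]
      valley <- min(ys[seg])
      hmin <- min(peaks$apex_height[j], peaks$apex_height[j + 1L])
      if (valley >= frac * hmin) {
        smaller <- if (peaks$apex_height[j] <= peaks$apex_height[j + 1L])
          j else j + 1L
        peaks$is_shoulder[smaller] <- TRUE
      }
    }
  }

  # (2) curvature-based recruitment of unresolved shoulders: a wide-stencil
  # negative second derivative, heavily smoothed, gated against its own
  # robust noise level so that flank wiggles do not spawn false shoulders
  k <- max(2L, params$smooth_window)
  if (n >= 2L * k + 3L) {
    i_mid <- (k + 1L):(n - k)
    curv <- rep(0, n)
    curv[i_mid] <- -(ys[i_mid - k] - 2 * ys[i_mid] + ys[i_mid + k])
    curv <- .runmean(curv, 2L * params$smooth_window + 1L)
    cthr <- max(0.02 * max(curv), 5 * stats::mad(curv))
    cmax <- .local_maxima(curv)
    cmax <- cmax[curv[cmax] >= cthr]
    min_sep <- 2L * k + 1L
    for (i in cmax) {
      if (min(abs(i - apex_idx)) <= min_sep) next
      if (rt[i] < params$min_rt || rt[i] > params$max_rt) next
      if (y[i] < thr) next
      near <- apex_idx[which.min(abs(apex_idx - i))]
      if (y[i] >= y[near]) next  # a shoulder sits below its parent apex
      seg <- min(i, near):max(i, near)
      valley <- min(ys[seg])
      hmin <- min(y[i], y[near])
      if (valley < frac * hmin) next
      # curvature support: nearest curvature minima flanking the candidate
      lo <- i
      while (lo > 1L && curv[lo - 1L] <= curv[lo]) lo <- lo - 1L
      hi <- i
      while (hi < n && curv[hi + 1L] <= curv[hi]) hi <- hi + 1L
      peaks <- rbind(peaks, data.frame(
        apex_rt = rt[i], apex_height = y[i],
        left_rt = rt[lo], right_rt = rt[hi],
        is_shoulder = TRUE, prominence = ys[i] - valley))
      apex_idx <- c(apex_idx, i)
    }
  }
  peaks <- peaks[order(peaks$apex_rt), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}
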