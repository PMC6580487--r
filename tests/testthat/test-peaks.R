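sim_norm <- function(spec_df, noise_sd = 0, seed = NULL) {
  tr <- simulate_trace(spec_df, noise_sd = noise_sd, seed = seed)
  class(tr) <- c("cdp_trace_normalized", class(tr))
  tr
}

test_that("peak_params validates its fields", {
  expect_error(peak_params(sn = 0), "sn")
  expect_error(peak_params(min_rt = 12, max_rt = 5), "min_rt")
  expect_error(peak_params(smooth_window = 4), "odd")
  expect_error(peak_params(shoulder_valley_frac = 0), "valley_frac")
  expect_s3_class(peak_params(), "cdp_peak_params")
})

test_that("a single Gaussian peak is found at the generator apex", {
  spec <- data.frame(apex_rt = 8, height = 100, width_sd = 0.1)
  tr <- sim_norm(spec, noise_sd = 1, seed = 101)
  pk <- detect_peaks(tr, peak_params(sn = 10), sigma = 1)
  expect_equal(nrow(pk), 1L)
  # oracle: argmax of the noise-free generator curve
  rt <- tr$rt
  oracle_apex <- rt[which.max(gauss_mix(rt, 8, 100, 0.1))]
  expect_lt(abs(pk$apex_rt - oracle_apex), 0.05)
  expect_false(pk$is_shoulder)

  # window excluding the apex -> no peaks
  pk2 <- detect_peaks(tr, peak_params(sn = 10, min_rt = 10, max_rt = 15),
                      sigma = 1)
  expect_equal(nrow(pk2), 0L)

  # window fully outside the trace domain -> error
  expect_error(
    detect_peaks(tr, peak_params(min_rt = 20, max_rt = 25), sigma = 1),
    "outside")
})

test_that("two resolved Gaussians give two non-shoulder peaks", {
  spec <- data.frame(apex_rt = c(7, 9), height = c(100, 100),
                     width_sd = c(0.1, 0.1))
  tr <- sim_norm(spec, noise_sd = 1, seed = 102)
  pk <- detect_peaks(tr, peak_params(sn = 10), sigma = 1)
  expect_equal(nrow(pk), 2L)
  expect_false(any(pk$is_shoulder))
  # oracle: local maxima of the noise-free curve
  rt <- tr$rt
  y0 <- gauss_mix(rt, c(7, 9), c(100, 100), c(0.1, 0.1))
  idx <- which(diff(sign(diff(y0))) == -2) + 1
  expect_equal(pk$apex_rt, rt[idx], tolerance = 0.05)
  # ordered by apex_rt, invariants hold
  expect_true(!is.unsorted(pk$apex_rt))
  expect_true(all(pk$left_rt <= pk$apex_rt & pk$apex_rt <= pk$right_rt))
  expect_true(all(pk$apex_height >= 10 * 1))
})

test_that("an unresolved secondary component is reported as a shoulder", {
  # 2.5-sd apex separation: the noise-free mixture is unimodal (no second
  # local maximum), so any flank minimum stays above the valley fraction
  spec <- data.frame(apex_rt = c(8, 8.25), height = c(100, 60),
                     width_sd = c(0.1, 0.1))
  rt <- seq(0, 15, 0.01)
  y0 <- gauss_mix(rt, spec$apex_rt, spec$height, spec$width_sd)
  n_max <- sum(diff(sign(diff(y0))) == -2)
  expect_equal(n_max, 1L)  # oracle: unimodal in spite of two components

  for (nsd in c(0, 1)) {
    tr <- sim_norm(spec, noise_sd = nsd, seed = 103)
    pk <- detect_peaks(tr, peak_params(sn = 10), sigma = nsd)
    expect_equal(nrow(pk), 2L)
    expect_equal(pk$is_shoulder, c(FALSE, TRUE))
    expect_lt(abs(pk$apex_rt[2] - 8.25), 0.1)
  }

  # a partially resolved doublet (second maximum, shallow valley) is also
  # flagged as a shoulder
  spec2 <- data.frame(apex_rt = c(8, 8.3), height = c(100, 60),
                      width_sd = c(0.1, 0.1))
  y2 <- gauss_mix(rt, spec2$apex_rt, spec2$height, spec2$width_sd)
  idx <- which(diff(sign(diff(y2))) == -2) + 1
  expect_equal(length(idx), 2L)              # oracle: bimodal
  valley <- min(y2[idx[1]:idx[2]])
  expect_gt(valley, 0.7 * y2[idx[2]])        # oracle: valley above fraction
  pk2 <- detect_peaks(sim_norm(spec2), peak_params(sn = 10), 0)
  expect_equal(pk2$is_shoulder, c(FALSE, TRUE))

  # single symmetric Gaussian: no shoulder invented
  pk1 <- detect_peaks(sim_norm(data.frame(apex_rt = 8, height = 100,
                                          width_sd = 0.1)),
                      peak_params(), 0)
  expect_equal(nrow(pk1), 1L)
  expect_false(any(pk1$is_shoulder))

  # well-separated doublet (valley ~ 0): both resolved
  spec3 <- data.frame(apex_rt = c(7, 9), height = c(100, 60),
                      width_sd = c(0.1, 0.1))
  pk3 <- detect_peaks(sim_norm(spec3), peak_params(), 0)
  expect_equal(pk3$is_shoulder, c(FALSE, FALSE))
})

test_that("peak count is non-increasing in the SNR threshold", {
  set.seed(104)
  for (rep in 1:8) {
    n_comp <- sample(1:4, 1)
    spec <- data.frame(apex_rt = sort(runif(n_comp, 5.5, 11.5)),
                       height = runif(n_comp, 30, 120),
                       width_sd = runif(n_comp, 0.05, 0.15))
    tr <- sim_norm(spec, noise_sd = 1, seed = 2000 + rep)
    counts <- vapply(c(3, 5, 10, 20, 50), function(sn) {
      nrow(detect_peaks(tr, peak_params(sn = sn), sigma = 1))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection is invariant to a common scale factor", {
  spec <- data.frame(apex_rt = c(7.5, 8.6), height = c(100, 45),
                     width_sd = c(0.1, 0.1))
  tr <- sim_norm(spec, noise_sd = 1, seed = 105)
  pk1 <- detect_peaks(tr, peak_params(sn = 10), sigma = 1)
  a <- 37.5
  tr2 <- tr
  tr2$absorbance <- a * tr2$absorbance
  pk2 <- detect_peaks(tr2, peak_params(sn = 10), sigma = a * 1)
  expect_equal(pk2$apex_rt, pk1$apex_rt)
  expect_equal(pk2$is_shoulder, pk1$is_shoulder)
  expect_equal(pk2$apex_height, a * pk1$apex_height, tolerance = 1e-12)
})

test_that("noise-free component count is recovered when all gates pass", {
  set.seed(106)
  for (rep in 1:6) {
    n_comp <- sample(1:3, 1)
    spec <- data.frame(apex_rt = 5.5 + (seq_len(n_comp) - 1) * 2 +
                         runif(1, 0, 0.5),
                       height = runif(n_comp, 50, 120),
                       width_sd = 0.1)
    pk <- detect_peaks(sim_norm(spec), peak_params(), sigma = 0)
    expect_equal(nrow(pk), n_comp)
  }
})

test_that("plateau maxima report the plateau midpoint", {
  rt <- seq(0, 15, 0.01)
  y <- numeric(length(rt))
  y[rt >= 7.95 & rt <= 8.05] <- 50  # flat-topped peak
  tr <- trace("S", "intact", rt, y)
  class(tr) <- c("cdp_trace_normalized", class(tr))
  pk <- detect_peaks(tr, peak_params(smooth_window = 1), sigma = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_rt, 8, tolerance = 0.011)
})
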