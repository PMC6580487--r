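# Labeled synthetic chromatogram batches: Gaussian elution peaks over a
# retention-time grid with baseline drift and additive Gaussian noise,
# organized as blank-every-three-pairs acquisitions.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a single chromatogram trace
#'
#' The signal is a sum of Gaussian elution peaks
#' `height * exp(-(t - apex_rt)^2 / (2 * width_sd^2))` plus a linear
#' baseline drift plus i.i.d. Gaussian noise.
#'
#' @param peaks Data frame (possibly 0-row) with columns `apex_rt`
#'   (minutes), `height` (absorbance units, > 0), `width_sd` (minutes,
#'   > 0).
#' @param rt_grid Numeric `c(start, stop, step)` in minutes; default
#'   `c(0, 15, 0.01)`, a typical analytical gradient window.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param drift Numeric `c(slope, intercept)` of the linear baseline.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param sample_id,treatment Identity carried on the returned trace.
#' @return A [trace()] object.
#' @export
simulate_trace <- function(peaks, rt_grid = c(0, 15, 0.01), noise_sd = 0,
                           drift = c(0, 0), seed = NULL,
                           sample_id = "SYN", treatment = "intact") {
  if (length(rt_grid) != 3L || rt_grid[3L] <= 0 ||
      rt_grid[2L] <= rt_grid[1L]) {
    stop("`rt_grid` must be c(start, stop, step) with step > 0",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) &&
      (any(peaks$height <= 0) || any(peaks$width_sd <= 0))) {
    stop("peak heights and widths must be > 0", call. = FALSE)
  }
  rt <- seq(rt_grid[1L], rt_grid[2L], by = rt_grid[3L])
  y <- drift[2L] + drift[1L] * rt
  for (j in seq_len(nrow(peaks))) {
    y <- y + peaks$height[j] *
      exp(-(rt - peaks$apex_rt[j])^2 / (2 * peaks$width_sd[j]^2))
  }
  .with_seed(seed, {
    if (noise_sd > 0) y <- y + stats::rnorm(length(rt), 0, noise_sd)
    trace(sample_id, treatment, rt, y)
  })
}

.class_peakspecs <- function(label, r, shift, width_sd) {
  spec <- function(rt, h) data.frame(apex_rt = rt, height = h,
                                     width_sd = width_sd)
  switch(label,
    Perfect = list(
      intact = spec(r, 100),
      reduced = spec(r - shift, 100)),
    PerfectPartial = list(
      intact = spec(r, 100),
      reduced = rbind(spec(r, 60), spec(r - shift, 100))),
    Simple = list(
      intact = rbind(spec(r, 100), spec(r + 1.5, 80)),
      reduced = spec(r - shift, 100)),
    Complex = list(
      intact = spec(r, 100),
      reduced = rbind(spec(r - shift, 100), spec(r + 0.9, 80),
                      spec(r + 1.8, 70))),
    stop(sprintf("unknown class label '%s'", label), call. = FALSE))
}

#' Simulate a labeled acquisition batch
#'
#' Builds an injection sequence with a blank run before every three sample
#' pairs, then one intact/reduced trace pair per requested class, each
#' constructed to satisfy the corresponding decision rule of
#' [classify_pair()] by a comfortable margin:
#' * `Perfect` — one intact peak, one reduced peak shifted by
#'   `shift` (default 0.8 min, far above `overlap_tol`);
#' * `PerfectPartial` — one intact peak; reduced trace with one
#'   overlapping and one shifted peak;
#' * `Simple` — two well-separated intact peaks (the `-Classification`
#'   default of 2), one shifted reduced peak;
#' * `Complex` — three reduced peaks.
#'
#' Peak apexes are drawn uniformly in `[6, 10]` min so that every
#' constructed peak stays inside the default `[5, 12]` min search window.
#' All traces share the batch's linear baseline drift, which the blank
#' subtraction removes.
#'
#' @param class_counts Named integer vector over
#'   `Perfect`, `PerfectPartial`, `Simple`, `Complex` (missing names mean
#'   0).
#' @param noise_sd Additive noise sd in absorbance units (default 0;
#'   apex heights are 60-100, so 2 corresponds to 2% of the main apex).
#' @param seed Optional integer seed (global RNG state restored).
#' @param rt_grid As in [simulate_trace()].
#' @param shift DTT retention shift in minutes (default 0.8).
#' @param width_sd Gaussian peak sd in minutes (default 0.08).
#' @param drift Baseline `c(slope, intercept)` shared by all runs
#'   (default `c(0.3, 2)` mAU).
#' @return An object of class `cdp_synthetic_batch`: list with `layout`
#'   ([build_batch_layout()] result), `traces` (named by run index),
#'   `labels` (named character, sample id -> class), `seed`.
#' @export
simulate_batch <- function(class_counts = c(Perfect = 1, PerfectPartial = 1,
                                            Simple = 1, Complex = 1),
                           noise_sd = 0, seed = NULL,
                           rt_grid = c(0, 15, 0.01), shift = 0.8,
                           width_sd = 0.08, drift = c(0.3, 2)) {
  counts <- stats::setNames(integer(4), .categories)
  if (length(class_counts)) {
    bad <- setdiff(names(class_counts), .categories)
    if (length(bad)) {
      stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    counts[names(class_counts)] <- as.integer(class_counts)
  }
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  labels <- rep(names(counts), counts)
  n_pairs <- length(labels)

  runs <- data.frame(run_index = integer(0), sample_id = character(0),
                     treatment = character(0), stringsAsFactors = FALSE)
  traces <- list()
  true_labels <- character(0)
  .with_seed(seed, {
    run_i <- 0L
    blank_i <- 0L
    add_run <- function(sample_id, treatment, tr_peaks, nsd) {
      run_i <<- run_i + 1L
      runs[nrow(runs) + 1L, ] <<- list(run_i, sample_id, treatment)
      traces[[as.character(run_i)]] <<- simulate_trace(
        tr_peaks, rt_grid = rt_grid, noise_sd = nsd, drift = drift,
        sample_id = sample_id, treatment = treatment)
    }
    no_peaks <- data.frame(apex_rt = numeric(0), height = numeric(0),
                           width_sd = numeric(0))
    for (p in seq_len(n_pairs)) {
      if ((p - 1L) %% 3L == 0L) {
        blank_i <- blank_i + 1L
        add_run(sprintf("BLK%03d", blank_i), "blank", no_peaks, noise_sd)
      }
      id <- sprintf("SYN%04d", p)
      r <- stats::runif(1, 6, 10)
      ps <- .class_peakspecs(labels[p], r, shift, width_sd)
      add_run(id, "intact", ps$intact, noise_sd)
      add_run(id, "reduced", ps$reduced, noise_sd)
      true_labels[[id]] <- labels[p]
    }
  })
  layout <- if (n_pairs > 0L) build_batch_layout(runs) else
    structure(list(runs = runs,
                   pairs = data.frame(sample_id = character(0),
                                      intact_run = integer(0),
                                      reduced_run = integer(0),
                                      blank_run = integer(0))),
              class = "cdp_batch_layout")
  structure(list(layout = layout, traces = traces, labels = true_labels,
                 seed = seed),
            class = "cdp_synthetic_batch")
}

#' Write a synthetic batch to a directory
#'
#' Emits one trace file per run (named `<sample_id>_<TOKEN>.<ext>` per the
#' default filename convention), a `manifest.csv`
#' (`run_index,sample_id,treatment,path`) and a `labels.csv`
#' (`sample_id,label`).
#'
#' @param batch A [simulate_batch()] result.
#' @param dir Output directory (created if needed).
#' @param dialect `"csv"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir, dialect = c("csv", "tsv")) {
  stopifnot(inherits(batch, "cdp_synthetic_batch"))
  dialect <- match.arg(dialect)
  ext <- dialect
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- batch$layout$runs
  token <- c(blank = "BLANK", intact = "INTACT", reduced = "DTT")
  paths <- character(nrow(runs))
  for (j in seq_len(nrow(runs))) {
    fn <- sprintf("%s_%s.%s", runs$sample_id[j],
                  token[[runs$treatment[j]]], ext)
    write_trace(batch$traces[[as.character(runs$run_index[j])]],
                file.path(dir, fn), dialect)
    paths[j] <- fn
  }
  manifest <- cbind(runs, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  labels <- data.frame(sample_id = names(batch$labels),
                       label = unname(batch$labels))
  utils::write.csv(labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
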