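# Four-category decision rule over an intact/reduced peak-list pair and
# batch orchestration.

.categories <- c("Perfect", "PerfectPartial", "Simple", "Complex")

#' Classification parameters
#'
#' @param overlap_tol Maximum apex RT difference (minutes) for two peaks to
#'   count as overlapping; equivalently, the minimum shift for a reduced
#'   peak to count as shifted. Must be > 0.
#' @param simple_max_peaks The `-Classification` count: largest number of
#'   peaks in either trace still acceptable as "Simple"; more is "Complex".
#'   Must be >= 2.
#' @return An object of class `cdp_classify_params`.
#' @export
classify_params <- function(overlap_tol = 0.1, simple_max_peaks = 2) {
  if (!is.numeric(overlap_tol) || overlap_tol <= 0) {
    stop("`overlap_tol` must be > 0", call. = FALSE)
  }
  simple_max_peaks <- as.integer(simple_max_peaks)
  if (simple_max_peaks < 2L) {
    stop("`simple_max_peaks` must be >= 2", call. = FALSE)
  }
  structure(list(overlap_tol = overlap_tol,
                 simple_max_peaks = simple_max_peaks),
            class = "cdp_classify_params")
}

#' Classify one intact/reduced peak-list pair
#'
#' Applies the four-category decision rule, in order:
#' 1. more than `simple_max_peaks` peaks in either trace -> `Complex`;
#' 2. one peak in each trace with the reduced apex shifted by more than
#'    `overlap_tol` -> `Perfect` (disulfide bonds formed and fully
#'    reduced by DTT);
#' 3. one intact peak and two reduced peaks of which exactly one overlaps
#'    the intact apex -> `PerfectPartial` (partial DTT reduction);
#' 4. everything else -> `Simple`, with diagnostic flag
#'    `"no_reduction_shift"` for a 1/1 pair without a shift (DTT-resistant
#'    profile) and `"no_peaks"` when either list is empty.
#'
#' Shoulder peaks count toward the peak totals.
#'
#' @param intact_peaks,reduced_peaks Peak data frames from
#'   [detect_peaks()] for the intact and DTT-reduced traces.
#' @param params A [classify_params()] object.
#' @param sample_id Sample identifier carried into the result.
#' @return An object of class `cdp_pair_classification`: a list with
#'   `sample_id`, `category`, `n_peaks_intact`, `n_peaks_reduced`,
#'   `shift_detected`, `flags`.
#' @export
classify_pair <- function(intact_peaks, reduced_peaks,
                          params = classify_params(), sample_id = "") {
  stopifnot(inherits(params, "cdp_classify_params"))
  n_i <- nrow(intact_peaks)
  n_r <- nrow(reduced_peaks)
  tol <- params$overlap_tol
  flags <- character(0)
  shift <- FALSE
  if (max(n_i, n_r) > params$simple_max_peaks) {
    cat_ <- "Complex"
  } else if (n_i == 1L && n_r == 1L &&
             abs(reduced_peaks$apex_rt - intact_peaks$apex_rt) > tol) {
    cat_ <- "Perfect"
    shift <- TRUE
  } else if (n_i == 1L && n_r == 2L &&
             sum(abs(reduced_peaks$apex_rt - intact_peaks$apex_rt) <= tol)
             == 1L) {
    cat_ <- "PerfectPartial"
    shift <- TRUE
  } else {
    cat_ <- "Simple"
    if (n_i == 1L && n_r == 1L &&
        abs(reduced_peaks$apex_rt - intact_peaks$apex_rt) <= tol) {
      flags <- c(flags, "no_reduction_shift")
    }
    if (n_i == 0L || n_r == 0L) flags <- c(flags, "no_peaks")
  }
  structure(list(sample_id = sample_id, category = cat_,
                 n_peaks_intact = n_i, n_peaks_reduced = n_r,
                 shift_detected = shift, flags = flags),
            class = "cdp_pair_classification")
}

#' @export
print.cdp_pair_classification <- function(x, ...) {
  cat(sprintf("<%s> %s (intact: %d peak%s, reduced: %d peak%s%s%s)\n",
              x$category, x$sample_id,
              x$n_peaks_intact, if (x$n_peaks_intact == 1L) "" else "s",
              x$n_peaks_reduced, if (x$n_peaks_reduced == 1L) "" else "s",
              if (x$shift_detected) ", shift" else "",
              if (length(x$flags)) paste0("; ", paste(x$flags,
                                                      collapse = ",")) else ""))
  invisible(x)
}

#' Classify a whole acquisition batch
#'
#' For every sample pair in the layout: subtract the assigned blank from
#' both traces, estimate the baseline noise from the peak-free flanks,
#' detect peaks and shoulders, and classify. A sample whose traces are
#' missing or unreadable yields an error record and the batch continues.
#'
#' @param layout A [build_batch_layout()] result.
#' @param traces A named list of [trace()] objects keyed by run index
#'   (`as.character(run_index)`).
#' @param peak_params A [peak_params()] object.
#' @param clf_params A [classify_params()] object.
#' @return A data frame with one row per sample: `sample_id`, `category`,
#'   `n_peaks_intact`, `n_peaks_reduced`, `shift_detected`, `flags`
#'   (`;`-separated), `error` (`NA` unless the sample failed).
#' @export
classify_batch <- function(layout, traces,
                           peak_params = cdpqc::peak_params(),
                           clf_params = classify_params()) {
  stopifnot(inherits(layout, "cdp_batch_layout"))
  pairs <- layout$pairs
  empty <- data.frame(sample_id = character(0), category = character(0),
                      n_peaks_intact = integer(0),
                      n_peaks_reduced = integer(0),
                      shift_detected = logical(0), flags = character(0),
                      error = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  window <- c(peak_params$min_rt, peak_params$max_rt)
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    p <- pairs[j, ]
    res <- tryCatch({
      get_run <- function(idx, what) {
        tr <- traces[[as.character(idx)]]
        if (is.null(tr)) {
          stop(sprintf("missing %s trace (run %d) for sample '%s'",
                       what, idx, p$sample_id), call. = FALSE)
        }
        tr
      }
      blank <- get_run(p$blank_run, "blank")
      norm_i <- subtract_blank(get_run(p$intact_run, "intact"), blank)
      norm_r <- subtract_blank(get_run(p$reduced_run, "reduced"), blank)
      pk_i <- detect_peaks(norm_i, peak_params,
                           estimate_noise(norm_i, "auto", window))
      pk_r <- detect_peaks(norm_r, peak_params,
                           estimate_noise(norm_r, "auto", window))
      cl <- classify_pair(pk_i, pk_r, clf_params, p$sample_id)
      data.frame(sample_id = cl$sample_id, category = cl$category,
                 n_peaks_intact = cl$n_peaks_intact,
                 n_peaks_reduced = cl$n_peaks_reduced,
                 shift_detected = cl$shift_detected,
                 flags = paste(cl$flags, collapse = ";"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample_id = p$sample_id, category = NA_character_,
                 n_peaks_intact = NA_integer_, n_peaks_reduced = NA_integer_,
                 shift_detected = NA, flags = "",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
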