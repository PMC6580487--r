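# Chromatogram trace container and batch layout.

.treatments <- c("blank", "intact", "reduced")

#' Construct a chromatogram trace
#'
#' A trace is a retention-time-ordered series of UV absorbance readings for
#' one injection, tagged with the sample identity and its treatment
#' (`blank`, `intact` or DTT-`reduced`).
#'
#' @param sample_id Sample identifier string.
#' @param treatment One of `"blank"`, `"intact"`, `"reduced"`.
#' @param rt Numeric vector of retention times in minutes, strictly
#'   increasing, length >= 2.
#' @param absorbance Numeric vector of UV absorbance values (mAU), same
#'   length as `rt`.
#' @return An object of class `cdp_trace`.
#' @export
#' @examples
#' trace("S1", "intact", rt = c(0, 1, 2), absorbance = c(0, 5, 0))
trace <- function(sample_id, treatment, rt, absorbance) {
  treatment <- match.arg(treatment, .treatments)
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop("`sample_id` must be a single string", call. = FALSE)
  }
  rt <- as.numeric(rt)
  absorbance <- as.numeric(absorbance)
  if (length(rt) < 2L) {
    stop("a trace needs at least 2 points", call. = FALSE)
  }
  if (length(rt) != length(absorbance)) {
    stop("`rt` and `absorbance` must have equal length", call. = FALSE)
  }
  if (!all(is.finite(rt)) || !all(is.finite(absorbance))) {
    stop("trace values must all be finite", call. = FALSE)
  }
  if (any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, treatment = treatment,
         rt = rt, absorbance = absorbance),
    class = "cdp_trace"
  )
}

#' @export
print.cdp_trace <- function(x, ...) {
  cat(sprintf("<cdp_trace> %s [%s]%s: %d points, RT %.3f..%.3f min\n",
              x$sample_id, x$treatment,
              if (!is.null(x$blank_id)) paste0(" - blank ", x$blank_id) else "",
              length(x$rt), x$rt[1L], x$rt[length(x$rt)]))
  invisible(x)
}

.dialect_sep <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "csv") "," else "\t"
}

#' Read a chromatogram trace from a two-column delimited text file
#'
#' The canonical trace format is two numeric columns (retention time in
#' minutes, absorbance) with an optional single header line, comma- or
#' tab-separated. Sample identity and treatment default to values parsed
#' from the file name via [parse_trace_filename()]; if the name does not
#' follow the convention, the file stem is used as the id with treatment
#' `"intact"`.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param sample_id,treatment Optional explicit identity; when `NULL` they
#'   are taken from the file name.
#' @return A [trace()] object.
#' @export
read_trace <- function(path, dialect = c("csv", "tsv"),
                       sample_id = NULL, treatment = NULL) {
  sep <- .dialect_sep(dialect)
  if (!file.exists(path)) {
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("trace file is empty: %s", path), call. = FALSE)
  }
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) < 2L) {
    stop(sprintf("trace file has fewer than 2 data points: %s", path),
         call. = FALSE)
  }
  fields <- strsplit(body, sep, fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2L)) {
    stop(sprintf("malformed row(s) in %s (need 2 columns): line %d",
                 path, which(n_fields < 2L)[1L] + has_header), call. = FALSE)
  }
  rt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  ab <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(rt) || anyNA(ab)) {
    bad <- which(is.na(rt) | is.na(ab))[1L]
    stop(sprintf("non-numeric value in %s at data row %d", path, bad),
         call. = FALSE)
  }
  if (is.null(sample_id) || is.null(treatment)) {
    parsed <- tryCatch(parse_trace_filename(basename(path)),
                       cdpqc_unmatched_filename = function(e) NULL)
    if (is.null(sample_id)) {
      sample_id <- if (!is.null(parsed)) parsed$sample_id else
        tools::file_path_sans_ext(basename(path))
    }
    if (is.null(treatment)) {
      treatment <- if (!is.null(parsed)) parsed$treatment else "intact"
    }
  }
  trace(sample_id, treatment, rt, ab)
}

#' Write a chromatogram trace to delimited text
#'
#' Values are serialized with 17 significant digits so that
#' `read_trace(write_trace(x))` reproduces `x` to full double precision.
#'
#' @param x A [trace()] object.
#' @param path Output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(x, "cdp_trace"))
  sep <- .dialect_sep(dialect)
  lines <- c(paste("rt", "absorbance", sep = sep),
             paste(sprintf("%.17g", x$rt), sprintf("%.17g", x$absorbance),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

.token_map <- c(intact = "intact", dtt = "reduced", blank = "blank")

#' Parse sample identity and treatment from a chromatogram file name
#'
#' The default convention is `<sampleid>_<TOKEN>.<ext>` with TOKEN one of
#' `INTACT`, `DTT`, `BLANK` (case-insensitive); `DTT` maps to treatment
#' `"reduced"`. A custom `pattern` may be supplied as a regular expression
#' with two capture groups: sample id, then treatment token.
#'
#' @param name File name (directory part ignored).
#' @param pattern Optional custom regex with two capture groups.
#' @return A list with `sample_id` and `treatment`.
#' @export
#' @examples
#' parse_trace_filename("CON0000123_DTT.csv")
parse_trace_filename <- function(name, pattern = NULL) {
  name <- basename(name)
  if (is.null(pattern)) {
    pattern <- "^(.+)_([A-Za-z]+)\\.[A-Za-z0-9]+$"
  }
  m <- regmatches(name, regexec(pattern, name))[[1L]]
  unmatched <- function(msg) {
    cond <- structure(
      class = c("cdpqc_unmatched_filename", "error", "condition"),
      list(message = msg, call = sys.call(-1L))
    )
    stop(cond)
  }
  if (length(m) < 3L) {
    unmatched(sprintf("file name '%s' does not match the naming convention",
                      name))
  }
  token <- tolower(m[[3L]])
  if (!token %in% names(.token_map)) {
    unmatched(sprintf(
      "file name '%s': treatment token '%s' is not one of INTACT/DTT/BLANK",
      name, m[[3L]]))
  }
  list(sample_id = m[[2L]], treatment = unname(.token_map[[token]]))
}

#' Build a batch layout from an ordered run list
#'
#' Runs are injections in instrument order. Every sample must appear with
#' both an `intact` and a `reduced` run, and each pair is assigned the most
#' recent blank injected before the earlier member of the pair (the
#' "blank every three pairs" acquisition scheme).
#'
#' @param runs A data frame with columns `run_index` (integer, injection
#'   order), `sample_id`, `treatment`.
#' @return An object of class `cdp_batch_layout` with elements `runs` and
#'   `pairs` (data frame: `sample_id`, `intact_run`, `reduced_run`,
#'   `blank_run`).
#' @export
build_batch_layout <- function(runs) {
  runs <- as.data.frame(runs)
  need <- c("run_index", "sample_id", "treatment")
  if (!all(need %in% names(runs))) {
    stop("`runs` needs columns run_index, sample_id, treatment",
         call. = FALSE)
  }
  runs$run_index <- as.integer(runs$run_index)
  runs$sample_id <- as.character(runs$sample_id)
  runs$treatment <- as.character(runs$treatment)
  if (anyDuplicated(runs$run_index)) {
    stop("duplicate run_index values in run list", call. = FALSE)
  }
  bad <- setdiff(unique(runs$treatment), .treatments)
  if (length(bad)) {
    stop(sprintf("unknown treatment(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  runs <- runs[order(runs$run_index), , drop = FALSE]
  rownames(runs) <- NULL

  blanks <- runs$run_index[runs$treatment == "blank"]
  samples <- runs[runs$treatment != "blank", , drop = FALSE]
  ids <- unique(samples$sample_id)
  pairs <- lapply(ids, function(id) {
    sub <- samples[samples$sample_id == id, , drop = FALSE]
    i_run <- sub$run_index[sub$treatment == "intact"]
    r_run <- sub$run_index[sub$treatment == "reduced"]
    if (length(i_run) != 1L || length(r_run) != 1L) {
      stop(sprintf(
        "sample '%s' must have exactly one intact and one reduced run (has %d/%d)",
        id, length(i_run), length(r_run)), call. = FALSE)
    }
    first <- min(i_run, r_run)
    prior <- blanks[blanks < first]
    if (length(prior) == 0L) {
      stop(sprintf("sample '%s' has no blank run preceding the pair", id),
           call. = FALSE)
    }
    data.frame(sample_id = id, intact_run = i_run, reduced_run = r_run,
               blank_run = max(prior))
  })
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(sample_id = character(), intact_run = integer(),
               reduced_run = integer(), blank_run = integer())
  pairs <- pairs[order(pmin(pairs$intact_run, pairs$reduced_run)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(runs = runs, pairs = pairs), class = "cdp_batch_layout")
}

#' @export
print.cdp_batch_layout <- function(x, ...) {
  cat(sprintf("<cdp_batch_layout> %d runs, %d sample pairs, %d blanks\n",
              nrow(x$runs), nrow(x$pairs),
              sum(x$runs$treatment == "blank")))
  invisible(x)
}
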