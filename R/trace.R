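#' Gaze trace for a single trial
#'
#' A `gaze_trace` holds one trial's uniformly sampled gaze record in
#' screen-centred degrees of visual angle: positive x is rightward gaze,
#' positive y is upward. Samples lost to blinks or pupil occlusion are kept
#' on the time axis with `valid = FALSE` so that time-based exclusion
#' windows remain computable.
#'
#' @param trial_id trial identifier (scalar).
#' @param t sample times in ms, strictly increasing with constant step
#'   `1000 / rate_hz` (up to one rounding unit).
#' @param x,y gaze position in degrees; must be finite wherever `valid`.
#' @param valid logical vector, `FALSE` during blink/pupil loss.
#' @param rate_hz nominal sampling rate (default 250).
#' @return an object of class `gaze_trace`.
#' @export
gaze_trace <- function(trial_id, t, x, y, valid = NULL, rate_hz = 250) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  valid <- as.logical(valid)
  tr <- structure(
    list(trial_id = trial_id, t = t, x = x, y = y, valid = valid,
         rate_hz = rate_hz),
    class = "gaze_trace")
  validate_gaze_trace(tr)
  tr
}

#' Validate a gaze trace's invariants
#'
#' @param tr a `gaze_trace`.
#' @return `tr`, invisibly; stops with an informative error on violation.
#' @export
validate_gaze_trace <- function(tr) {
  n <- length(tr$t)
  if (n < 2L) stop("gaze_trace must have at least 2 samples")
  if (length(tr$x) != n || length(tr$y) != n || length(tr$valid) != n) {
    stop("gaze_trace fields t, x, y, valid must have equal length")
  }
  dt <- diff(tr$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("gaze_trace time axis not strictly increasing at sample %d (t = %g)",
                 bad, tr$t[bad]))
  }
  step <- 1000 / tr$rate_hz
  if (any(abs(dt - step) > 1)) {
    bad <- which(abs(dt - step) > 1)[1L] + 1L
    stop(sprintf("gaze_trace sampling step deviates from %g ms at sample %d", step, bad))
  }
  if (any(!is.finite(tr$x[tr$valid])) || any(!is.finite(tr$y[tr$valid]))) {
    stop("gaze_trace has non-finite position at samples marked valid")
  }
  invisible(tr)
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> trial %s: %d samples @ %g Hz, %.0f-%.0f ms, %.1f%% valid\n",
              format(x$trial_id), length(x$t), x$rate_hz, x$t[1L],
              x$t[length(x$t)], 100 * mean(x$valid)))
  invisible(x)
}

#' Read a gaze trace from file
#'
#' Two dialects are supported. `"csv"` expects a header with columns
#' `t_ms, x_deg, y_deg, valid` (valid optional; blank/`NA` positions imply
#' invalid). `"asc"` is a read-only whitespace dialect resembling eye-tracker
#' sample logs: `<t> <x> <y>` per line, with `.` in the position columns
#' marking lost samples; lines starting with letters are ignored.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"asc"`.
#' @param trial_id identifier for the resulting trace (default: file name).
#' @param rate_hz nominal sampling rate.
#' @return a validated [gaze_trace()].
#' @export
read_trace <- function(path, dialect = c("csv", "asc"), trial_id = NULL,
                       rate_hz = 250) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("t_ms", "x_deg", "y_deg")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("trace file ", path, " missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    valid <- if ("valid" %in% names(df)) {
      as.logical(df$valid)
    } else is.finite(df$x_deg) & is.finite(df$y_deg)
    tr <- try(gaze_trace(trial_id, df$t_ms, df$x_deg, df$y_deg, valid,
                         rate_hz = rate_hz), silent = TRUE)
    if (inherits(tr, "try-error")) {
      stop("invalid trace in ", path, " (rows are header + data lines): ",
           attr(tr, "condition")$message)
    }
    tr
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- grepl("^\\s*[0-9]", lines)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(fields) < 3L)
    if (length(bad)) {
      stop("unparseable sample line(s) at line ",
           paste(which(keep)[bad], collapse = ", "), " in ", path)
    }
    t <- as.numeric(vapply(fields, `[[`, "", 1L))
    xs <- vapply(fields, `[[`, "", 2L)
    ys <- vapply(fields, `[[`, "", 3L)
    lost <- xs == "." | ys == "."
    x <- suppressWarnings(as.numeric(xs)); x[lost] <- NA_real_
    y <- suppressWarnings(as.numeric(ys)); y[lost] <- NA_real_
    gaze_trace(trial_id, t, x, y, valid = !lost, rate_hz = rate_hz)
  }
}

#' Write a gaze trace to CSV
#'
#' Inverse of [read_trace()] for the CSV dialect; full double precision is
#' retained so that a read/write round trip is the identity.
#'
#' @param tr a `gaze_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(tr, path) {
  validate_gaze_trace(tr)
  df <- data.frame(t_ms = tr$t,
                   x_deg = ifelse(tr$valid, tr$x, NA_real_),
                   y_deg = ifelse(tr$valid, tr$y, NA_real_),
                   valid = tr$valid)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trace span helpers
#' @keywords internal
trace_span <- function(tr) c(tr$t[1L], tr$t[length(tr$t)])
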