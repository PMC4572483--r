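# Event tables: saccades, fixations and blinks are plain data.frames with a
# fixed column order, one row per event, so they serialise losslessly to CSV.

SACCADE_COLS <- c("trial_id", "onset_ms", "offset_ms", "start_x", "start_y",
                  "end_x", "end_y", "amplitude", "peak_velocity",
                  "contains_blink", "ordinal")
FIXATION_COLS <- c("trial_id", "onset_ms", "offset_ms", "mean_x", "mean_y",
                   "duration_ms")
BLINK_COLS <- c("trial_id", "onset_ms", "offset_ms")

#' Construct an (empty or filled) saccade event table
#'
#' @param ... columns matching the saccade schema; omit all for an empty table.
#' @return data.frame with class `saccade_events`.
#' @export
saccade_events <- function(...) {
  args <- list(...)
  if (!length(args)) {
    df <- data.frame(trial_id = character(0), onset_ms = numeric(0),
                     offset_ms = numeric(0), start_x = numeric(0),
                     start_y = numeric(0), end_x = numeric(0),
                     end_y = numeric(0), amplitude = numeric(0),
                     peak_velocity = numeric(0), contains_blink = logical(0),
                     ordinal = integer(0))
  } else {
    df <- data.frame(..., stringsAsFactors = FALSE)
  }
  miss <- setdiff(SACCADE_COLS, names(df))
  if (length(miss)) stop("saccade_events missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[SACCADE_COLS]
  if (any(df$offset_ms <= df$onset_ms)) stop("saccade offset must exceed onset")
  if (any(df$amplitude < 0)) stop("saccade amplitude must be non-negative")
  class(df) <- c("saccade_events", "data.frame")
  df
}

#' Construct a fixation event table
#' @param ... columns matching the fixation schema; omit all for empty.
#' @return data.frame with class `fixation_events`.
#' @export
fixation_events <- function(...) {
  args <- list(...)
  if (!length(args)) {
    df <- data.frame(trial_id = character(0), onset_ms = numeric(0),
                     offset_ms = numeric(0), mean_x = numeric(0),
                     mean_y = numeric(0), duration_ms = numeric(0))
  } else {
    df <- data.frame(..., stringsAsFactors = FALSE)
    if (!"duration_ms" %in% names(df)) df$duration_ms <- df$offset_ms - df$onset_ms
  }
  miss <- setdiff(FIXATION_COLS, names(df))
  if (length(miss)) stop("fixation_events missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[FIXATION_COLS]
  if (any(df$duration_ms <= 0)) stop("fixation duration must be positive")
  class(df) <- c("fixation_events", "data.frame")
  df
}

#' Write event tables to CSV
#'
#' One row per event with the full schema and a stable column order.
#' Overlapping saccade intervals within a trial are rejected.
#'
#' @param events a `saccade_events` or `fixation_events` data.frame (an empty
#'   table yields a header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (inherits(events, "saccade_events") && nrow(events) > 1L) {
    for (id in unique(events$trial_id)) {
      ev <- events[events$trial_id == id, , drop = FALSE]
      ev <- ev[order(ev$onset_ms), , drop = FALSE]
      if (nrow(ev) > 1L && any(ev$onset_ms[-1L] < ev$offset_ms[-nrow(ev)])) {
        stop("overlapping saccade intervals in trial ", id)
      }
    }
  }
  df <- as.data.frame(events)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV path.
#' @param type `"saccade"` or `"fixation"` (inferred from the header when
#'   omitted).
#' @return the corresponding event table.
#' @export
read_events <- function(path, type = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(type)) {
    type <- if ("peak_velocity" %in% names(df)) "saccade" else "fixation"
  }
  if (nrow(df) == 0L) {
    return(if (type == "saccade") saccade_events() else fixation_events())
  }
  if (type == "saccade") do.call(saccade_events, df) else do.call(fixation_events, df)
}
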