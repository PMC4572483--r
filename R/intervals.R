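# Half-open-agnostic interval arithmetic on the millisecond time axis.
# Intervals are two-column matrices (onset, offset), offset >= onset.

#' Merge overlapping or touching intervals
#'
#' @param iv numeric matrix with columns onset, offset (ms); zero rows allowed.
#' @return matrix of disjoint intervals sorted by onset.
#' @keywords internal
merge_intervals <- function(iv) {
  iv <- as_interval_matrix(iv)
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  on <- iv[, 1L]; off <- iv[, 2L]
  keep_on <- on[1L]; keep_off <- off[1L]
  res <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (on[i] <= keep_off) {
      keep_off <- max(keep_off, off[i])
    } else {
      res <- rbind(res, c(keep_on, keep_off))
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  res <- rbind(res, c(keep_on, keep_off))
  colnames(res) <- c("onset", "offset")
  res
}

#' @keywords internal
as_interval_matrix <- function(iv) {
  if (is.null(iv) || length(iv) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("onset", "offset"))))
  }
  if (is.data.frame(iv)) iv <- as.matrix(iv[, 1:2])
  iv <- matrix(as.numeric(iv), ncol = 2L)
  colnames(iv) <- c("onset", "offset")
  stopifnot(all(iv[, 2L] >= iv[, 1L]))
  iv
}

#' Clip intervals to a window, dropping empties
#' @keywords internal
clip_intervals <- function(iv, lo, hi) {
  iv <- as_interval_matrix(iv)
  if (nrow(iv) == 0L) return(iv)
  iv[, 1L] <- pmax(iv[, 1L], lo)
  iv[, 2L] <- pmin(iv[, 2L], hi)
  iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
}

#' Complement of a set of intervals within [lo, hi]
#' @keywords internal
complement_intervals <- function(iv, lo, hi) {
  iv <- merge_intervals(clip_intervals(iv, lo, hi))
  if (nrow(iv) == 0L) {
    out <- matrix(c(lo, hi), ncol = 2L)
  } else {
    starts <- c(lo, iv[, 2L])
    ends <- c(iv[, 1L], hi)
    out <- cbind(starts, ends)[ends > starts, , drop = FALSE]
  }
  colnames(out) <- c("onset", "offset")
  out
}

#' Total length of the union of intervals
#' @keywords internal
interval_union_length <- function(iv) {
  iv <- merge_intervals(iv)
  if (nrow(iv) == 0L) return(0)
  sum(iv[, 2L] - iv[, 1L])
}

#' Which points fall inside any interval
#' @keywords internal
points_in_intervals <- function(t, iv) {
  iv <- as_interval_matrix(iv)
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    inside <- inside | (t >= iv[i, 1L] & t <= iv[i, 2L])
  }
  inside
}

#' Do two interval sets overlap, rowwise for the first set
#' @keywords internal
intervals_overlap_any <- function(iv, other) {
  iv <- as_interval_matrix(iv); other <- as_interval_matrix(other)
  if (nrow(iv) == 0L) return(logical(0))
  if (nrow(other) == 0L) return(rep(FALSE, nrow(iv)))
  vapply(seq_len(nrow(iv)), function(i) {
    any(iv[i, 1L] <= other[, 2L] & iv[i, 2L] >= other[, 1L])
  }, logical(1L))
}
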