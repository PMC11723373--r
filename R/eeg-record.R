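# Multichannel EEG record container and segmentation.

#' Construct an EEG record
#'
#' @param data numeric matrix `[n_channels, n_samples]`, microvolts
#' @param fs sampling rate in samples/second
#' @param channel_names character vector, one per channel
#' @param intervals data.frame with columns `start_s`, `end_s`, `label`
#'   (labels from `interictal`, `preictal`, `ictal`); bounds in seconds
#' @return object of class `eeg_record`
#' @export
eeg_record <- function(data, fs, channel_names = NULL, intervals = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (nrow(data) < 1L) stop("record needs at least one channel")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match channel count")
  dur <- ncol(data) / fs
  if (is.null(intervals))
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            label = character(0))
  if (nrow(intervals) > 0) {
    if (any(intervals$start_s < 0) || any(intervals$end_s > dur + 1e-9))
      stop("interval bounds outside the recording")
    if (any(intervals$end_s <= intervals$start_s))
      stop("intervals must have positive duration")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 intervals = intervals),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60))
  if (nrow(x$intervals) > 0) {
    tab <- tapply(x$intervals$end_s - x$intervals$start_s, x$intervals$label, sum)
    for (lb in names(tab)) cat(sprintf("  %s: %.1f min\n", lb, tab[[lb]] / 60))
  }
  invisible(x)
}

record_duration_s <- function(record, label = NULL) {
  iv <- record$intervals
  if (!is.null(label)) iv <- iv[iv$label == label, , drop = FALSE]
  sum(iv$end_s - iv$start_s)
}

#' Segment a record into non-overlapping fixed-length windows
#'
#' Cuts consecutive windows of `window_s` seconds from every interval whose
#' label matches `label_filter`; a trailing remainder shorter than a window
#' is discarded. An empty record or an over-long window yields an empty list.
#' @param record an [eeg_record()]
#' @param window_s window length in seconds
#' @param label_filter label selecting the intervals to segment
#' @return list of `[n_channels, window_samples]` matrices, each with
#'   attributes `t_start` (seconds, within the record) and `label`
#' @export
segment_record <- function(record, window_s = 2, label_filter = NULL) {
  stopifnot(inherits(record, "eeg_record"), window_s > 0)
  win <- as.integer(round(window_s * record$fs))
  iv <- record$intervals
  if (!is.null(label_filter)) iv <- iv[iv$label %in% label_filter, , drop = FALSE]
  out <- list()
  if (nrow(iv) == 0L) return(out)
  for (r in seq_len(nrow(iv))) {
    i0 <- as.integer(round(iv$start_s[r] * record$fs))
    n_avail <- as.integer(round((iv$end_s[r] - iv$start_s[r]) * record$fs))
    nseg <- n_avail %/% win
    if (nseg < 1L) next
    for (sgi in seq_len(nseg)) {
      a <- i0 + (sgi - 1L) * win
      seg <- record$data[, (a + 1L):(a + win), drop = FALSE]
      attr(seg, "t_start") <- a / record$fs
      attr(seg, "label") <- iv$label[r]
      out[[length(out) + 1L]] <- seg
    }
  }
  out
}
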