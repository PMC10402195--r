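#' Construct an iEEG recording
#'
#' A recording is a channels-by-samples numeric matrix with a sampling rate
#' and channel labels, the in-memory unit that all preprocessing and spectral
#' operations consume. Values are in microvolts; `t_start` is the clip onset
#' in seconds relative to electrode implantation.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param t_start clip start time in seconds from implant (default 0).
#' @return an object of class `ieeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels = rownames(data), t_start = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("label count (", length(channel_labels), ") must equal channel count (", nrow(data), ")")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels, t_start = t_start),
    class = "ieeg_recording"
  )
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf(
    "<ieeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `ieeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Annotation set for clip selection
#'
#' Implant and seizure timestamps, in seconds on the same clock as clip
#' window start times. Used to exclude the early post-implant period and
#' peri-ictal windows from interictal clip selection.
#'
#' @param implant_time implantation time (seconds; usually 0).
#' @param seizure_times numeric vector of seizure onset times (seconds),
#'   non-decreasing.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(implant_time = 0, seizure_times = numeric(0)) {
  seizure_times <- as.numeric(seizure_times)
  if (is.unsorted(seizure_times)) stop("`seizure_times` must be non-decreasing")
  structure(list(implant_time = implant_time, seizure_times = seizure_times),
            class = "annotation_set")
}

#' Write / read a recording as CSV
#'
#' Plain-text serialization: one row per sample, one column per channel,
#' sampling rate and start time stored on a commented header line.
#'
#' @param recording an `ieeg_recording`.
#' @param path file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `ieeg_recording`.
#' @export
write_recording_csv <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g t_start=%.10g", recording$fs, recording$t_start), con)
  utils::write.csv(
    stats::setNames(as.data.frame(t(recording$data)), recording$channel_labels),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("fs=([0-9.eE+-]+) t_start=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L) stop("not a recording CSV: missing '# fs=... t_start=...' header")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  new_recording(t(as.matrix(df)), fs = as.numeric(m[2]),
                channel_labels = colnames(df), t_start = as.numeric(m[3]))
}
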