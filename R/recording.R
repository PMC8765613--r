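# ContinuousRecording: multichannel voltage trace with a sampling clock.

#' Construct a continuous recording
#'
#' The basic container for multichannel voltage data: a channels x time matrix
#' with a sampling rate and an absolute start time. All event times elsewhere
#' in the package are absolute seconds on this clock.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels optional character vector, one per channel.
#' @param start_time time of the first sample in seconds (default 0).
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, sampling_rate, channel_labels = NULL,
                                 start_time = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_labels) == nrow(samples))
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, start_time = start_time),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.1f s from t=%g s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, x$start_time))
  invisible(x)
}

# absolute time (s) -> 1-based sample index
time_to_sample <- function(rec, t) {
  as.integer(round((t - rec$start_time) * rec$sampling_rate)) + 1L
}

sample_times <- function(rec) {
  rec$start_time + (seq_len(ncol(rec$samples)) - 1L) / rec$sampling_rate
}

#' Read / write a recording as a plain-text array container
#'
#' The container is a TSV whose first line is a comment header
#' `# odorosc_recording sampling_rate=<Hz> start_time=<s>` followed by one
#' column per channel (header row = channel labels). This is the package's
#' text-format stand-in for binary EDF.
#'
#' @param path file path.
#' @return for `read_recording`, a [continuous_recording()].
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# *odorosc_recording", hdr)) {
    stop("not an odorosc recording container: ", path)
  }
  fs <- as.numeric(sub(".*sampling_rate=([0-9.eE+-]+).*", "\\1", hdr))
  t0 <- as.numeric(sub(".*start_time=([0-9.eE+-]+).*", "\\1", hdr))
  dat <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  continuous_recording(t(as.matrix(dat)), fs, colnames(dat), t0)
}

#' @param rec a [continuous_recording()].
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# odorosc_recording sampling_rate=%.10g start_time=%.10g",
                     rec$sampling_rate, rec$start_time), con)
  dat <- as.data.frame(t(rec$samples))
  names(dat) <- rec$channel_labels
  utils::write.table(dat, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
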