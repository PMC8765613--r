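# Event-table I/O: TSV with columns trial, cue_time_s, sniff_time_s,
# condition, correct.

EVENT_COLUMNS <- c("trial", "cue_time_s", "sniff_time_s", "condition", "correct")
KNOWN_CONDITIONS <- c("odor", "no_odor", "attended_no_odor")

#' Read an event table
#'
#' Expects a TSV with header `trial, cue_time_s, sniff_time_s, condition,
#' correct`. Times are seconds on the recording clock. Condition labels are
#' normalized to lower case and must be one of `odor`, `no_odor`,
#' `attended_no_odor`. Rows with `cue_time_s > sniff_time_s` are rejected
#' (causality); duplicate trial ids and non-monotone sniff times raise
#' warnings.
#'
#' @param path TSV path.
#' @return validated event data.frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing_cols)) {
    stop("event table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ev$cue_time_s <- as.numeric(ev$cue_time_s)
  ev$sniff_time_s <- as.numeric(ev$sniff_time_s)
  ev$condition <- tolower(trimws(ev$condition))
  bad_cond <- setdiff(unique(ev$condition), KNOWN_CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  }
  acausal <- !is.na(ev$cue_time_s) & ev$cue_time_s > ev$sniff_time_s
  if (any(acausal)) {
    message(sum(acausal), " row(s) with cue_time_s > sniff_time_s rejected")
    ev <- ev[!acausal, , drop = FALSE]
  }
  if (anyDuplicated(ev$trial)) warning("duplicate trial ids in event table")
  if (is.unsorted(ev$sniff_time_s)) warning("sniff times are not monotone")
  ev$correct <- as.logical(ev$correct)
  ev
}

#' @param events event data.frame.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, intersect(EVENT_COLUMNS, names(events))], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
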