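#' Fluorescence trace matrix
#'
#' Container for extracted single-cell fluorescence traces: one row per neuron,
#' one column per frame, recorded at a fixed frame rate (miniscope recordings
#' here are 6 frames/s).
#'
#' @param values numeric matrix (or coercible), neurons x frames, raw
#'   fluorescence in arbitrary units.
#' @param neuron_ids character vector of neuron identifiers; defaults to
#'   `"n001", "n002", ...`.
#' @param frame_rate frames per second (> 0). Default 6.
#' @param t0 recording start time in seconds. Default 0.
#' @return an object of class `trace_matrix` with fields `values`,
#'   `neuron_ids`, `frame_rate`, `t0`.
#' @export
trace_matrix <- function(values, neuron_ids = NULL, frame_rate = 6, t0 = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be a finite numeric matrix (no missing frames)")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number")
  if (is.null(neuron_ids))
    neuron_ids <- sprintf("n%03d", seq_len(nrow(values)))
  if (length(neuron_ids) != nrow(values))
    stop("`neuron_ids` length must equal the number of rows of `values`")
  rownames(values) <- neuron_ids
  structure(
    list(values = values, neuron_ids = as.character(neuron_ids),
         frame_rate = frame_rate, t0 = t0),
    class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d neurons x %d frames @ %g frames/s (t0 = %g s)\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$frame_rate, x$t0))
  if (inherits(x, "normalized_trace"))
    cat("  mode:", attr(x, "mode"), "\n")
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Frame timestamps of a trace matrix
#'
#' @param x a [trace_matrix()].
#' @return numeric vector of frame times in seconds (frame i occurs at
#'   `t0 + (i - 1) / frame_rate`).
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "trace_matrix"))
  x$t0 + (seq_len(ncol(x$values)) - 1L) / x$frame_rate
}

#' Event schedule
#'
#' Typed, timestamped stimulus/behaviour intervals (CS, US, hot-plate contact,
#' freezing bouts, drug blocks) used to slice peri-event activity.
#'
#' @param label character vector of event labels.
#' @param onset_s,offset_s numeric vectors of onsets/offsets in seconds;
#'   `onset_s <= offset_s` element-wise.
#' @return a data.frame of class `event_schedule` with columns `label`,
#'   `onset_s`, `offset_s`.
#' @export
event_schedule <- function(label = character(), onset_s = numeric(),
                           offset_s = numeric()) {
  if (length(label) != length(onset_s) || length(label) != length(offset_s))
    stop("`label`, `onset_s` and `offset_s` must have equal length")
  if (any(onset_s > offset_s))
    stop("every event must satisfy onset_s <= offset_s")
  out <- data.frame(label = as.character(label), onset_s = as.numeric(onset_s),
                    offset_s = as.numeric(offset_s))
  class(out) <- c("event_schedule", "data.frame")
  out
}

as_event_schedule <- function(x) {
  if (inherits(x, "event_schedule")) return(x)
  need <- c("label", "onset_s", "offset_s")
  if (!all(need %in% names(x)))
    stop("event table must have columns label, onset_s, offset_s; missing: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  event_schedule(x$label, x$onset_s, x$offset_s)
}

# internal constructor for aligned peri-event snippets
new_peri_event_tensor <- function(values, rel_time, frame_rate, window,
                                  labels, neuron_ids) {
  structure(values,
            rel_time = rel_time, frame_rate = frame_rate, window = window,
            event_labels = labels, neuron_ids = neuron_ids,
            class = "peri_event_tensor")
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  d <- dim(x)
  w <- attr(x, "window")
  cat(sprintf(
    "<peri_event_tensor> %d neurons x %d events x %d frames (window -%g/+%g s)\n",
    d[1L], d[2L], d[3L], w[1L], w[2L]))
  invisible(x)
}

#' Relative frame times of a peri-event tensor
#'
#' @param peri a `peri_event_tensor` from [slice_peri_event()].
#' @return numeric vector of frame times relative to event onset (s);
#'   relative time 0 is the onset frame.
#' @export
peri_times <- function(peri) {
  stopifnot(inherits(peri, "peri_event_tensor"))
  attr(peri, "rel_time")
}
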