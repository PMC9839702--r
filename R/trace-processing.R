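#' Convert raw traces to deltaF/F
#'
#' Across-time normalisation: for each neuron, `(F - F_mean) / F_mean` where
#' `F_mean` is the average fluorescence across the entire recording. A constant
#' trace maps to identically zero, and the result is invariant to multiplicative
#' rescaling of the raw fluorescence.
#'
#' @param trace a [trace_matrix()] of raw fluorescence.
#' @return a `normalized_trace` (a [trace_matrix()] with attribute
#'   `mode = "dff"`), dimensionless values.
#' @export
deltaf_over_f <- function(trace) {
  stopifnot(inherits(trace, "trace_matrix"))
  f_mean <- rowMeans(trace$values)
  bad <- which(f_mean == 0)
  if (length(bad))
    stop("degenerate baseline: F_mean = 0 for neuron(s) ",
         paste(trace$neuron_ids[bad], collapse = ", "))
  out <- trace
  out$values <- sweep(sweep(trace$values, 1L, f_mean, "-"), 1L, f_mean, "/")
  class(out) <- c("normalized_trace", "trace_matrix")
  attr(out, "mode") <- "dff"
  out
}

# frames with time in [from, to): half-open so a w-second window at rate r
# always contains exactly round(w * r) frames
window_frames <- function(times, from, to) {
  which(times >= from - 1e-9 & times < to - 1e-9)
}

#' Peri-event z-score of a whole recording
#'
#' For one event, converts the raw trace to z-scores `(F - F_mean) / F_sd`
#' with moments taken over the union of a designated baseline window and the
#' event's pre-stimulus window. Sample (n - 1) standard deviation is used
#' throughout. The result is invariant to affine transforms `a * F + b`
#' (a > 0) of the raw trace.
#'
#' @param trace a [trace_matrix()] of raw fluorescence.
#' @param event a single-row event (list or data.frame with at least `onset_s`).
#' @param baseline_window numeric length-2, designated baseline period in
#'   absolute recording seconds, half-open `[start, end)`.
#' @param pre seconds of pre-stimulus window before `onset_s` to pool with the
#'   baseline (default 0: baseline window only).
#' @return a `normalized_trace` with `mode = "zscore"` and attributes
#'   `baseline_window`, `baseline_frames`.
#' @export
peri_event_zscore <- function(trace, event, baseline_window, pre = 0) {
  stopifnot(inherits(trace, "trace_matrix"), length(baseline_window) == 2L)
  if (is.data.frame(event)) event <- as.list(event[1L, ])
  times <- frame_times(trace)
  idx <- window_frames(times, baseline_window[1L], baseline_window[2L])
  if (pre > 0)
    idx <- sort(union(idx, window_frames(times, event$onset_s - pre, event$onset_s)))
  if (length(idx) < 2L)
    stop("baseline window must contain at least 2 frames")
  m <- rowMeans(trace$values[, idx, drop = FALSE])
  s <- apply(trace$values[, idx, drop = FALSE], 1L, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("degenerate baseline: zero baseline sd for neuron(s) ",
         paste(trace$neuron_ids[bad], collapse = ", "))
  out <- trace
  out$values <- sweep(sweep(trace$values, 1L, m, "-"), 1L, s, "/")
  class(out) <- c("normalized_trace", "trace_matrix")
  attr(out, "mode") <- "zscore"
  attr(out, "baseline_window") <- baseline_window
  attr(out, "baseline_frames") <- idx
  out
}

#' Slice peri-event windows into an aligned tensor
#'
#' Cuts, for every event in the schedule, a window of `pre` seconds before to
#' `post` seconds after event onset. Event onset maps to the first frame at or
#' after the onset time; the window is inclusive of the onset frame, so a
#' 10 s/10 s window at 6 frames/s yields 121 aligned frames.
#'
#' @param norm a [trace_matrix()] or `normalized_trace`.
#' @param schedule an [event_schedule()] (possibly empty).
#' @param pre,post window extent in seconds before/after onset.
#' @return a `peri_event_tensor`: array neurons x events x frames with
#'   attributes `rel_time` (s, 0 = onset frame), `window`, `event_labels`.
#' @export
slice_peri_event <- function(norm, schedule, pre, post) {
  stopifnot(inherits(norm, "trace_matrix"), pre >= 0, post >= 0)
  schedule <- as_event_schedule(schedule)
  fr <- norm$frame_rate
  n_pre <- round(pre * fr)
  n_post <- round(post * fr)
  rel_time <- (-n_pre:n_post) / fr
  n_frames <- ncol(norm$values)
  arr <- array(NA_real_,
               dim = c(nrow(norm$values), nrow(schedule), n_pre + n_post + 1L),
               dimnames = list(norm$neuron_ids, NULL, NULL))
  for (e in seq_len(nrow(schedule))) {
    i_on <- ceiling((schedule$onset_s[e] - norm$t0) * fr - 1e-9) + 1L
    lo <- i_on - n_pre
    hi <- i_on + n_post
    if (lo < 1L || hi > n_frames)
      stop(sprintf(
        "peri-event window out of range for event %d ('%s', onset %g s)",
        e, schedule$label[e], schedule$onset_s[e]))
    arr[, e, ] <- norm$values[, lo:hi]
  }
  new_peri_event_tensor(arr, rel_time, fr, c(pre, post),
                        schedule$label, norm$neuron_ids)
}

#' Z-score each peri-event snippet against its own baseline frames
#'
#' Per neuron and event instance, converts the snippet to z-scores using the
#' mean and sample sd of the frames whose relative time falls in
#' `baseline_window` (half-open). This is the form used when traces are cut
#' around each event before normalising.
#'
#' @param peri a `peri_event_tensor` of raw values.
#' @param baseline_window length-2 numeric, relative seconds (e.g. `c(-10, 0)`).
#' @return a `peri_event_tensor` of z-scores; snippets with zero baseline sd
#'   become `NA` with a warning.
#' @export
zscore_peri <- function(peri, baseline_window) {
  stopifnot(inherits(peri, "peri_event_tensor"), length(baseline_window) == 2L)
  rel <- attr(peri, "rel_time")
  idx <- window_frames(rel, baseline_window[1L], baseline_window[2L])
  if (length(idx) < 2L)
    stop("baseline window must contain at least 2 frames")
  out <- peri
  n_degenerate <- 0L
  for (i in seq_len(dim(peri)[1L])) {
    for (e in seq_len(dim(peri)[2L])) {
      b <- peri[i, e, idx]
      s <- stats::sd(b)
      if (s == 0) {
        out[i, e, ] <- NA_real_
        n_degenerate <- n_degenerate + 1L
      } else {
        out[i, e, ] <- (peri[i, e, ] - mean(b)) / s
      }
    }
  }
  if (n_degenerate > 0L)
    warning(n_degenerate,
            " snippet(s) had zero baseline sd and were set to NA")
  out
}

# average snippets across event instances -> matrix neurons x frames
average_events <- function(peri) {
  stopifnot(inherits(peri, "peri_event_tensor"))
  d <- dim(peri)
  if (d[2L] == 0L)
    return(matrix(NA_real_, d[1L], d[3L],
                  dimnames = list(attr(peri, "neuron_ids"), NULL)))
  apply(peri, c(1L, 3L), mean)
}
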