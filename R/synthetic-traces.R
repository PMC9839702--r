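#' Specification for a synthetic trace cohort
#'
#' Defines a cohort of synthetic single-cell fluorescence traces with planted,
#' event-locked response classes: `null` (baseline only), `transient`
#' (instantaneous rise, exponential decay), `linear_ramp` (activity ramping
#' linearly from event onset) and `sigmoid` (saturating response
#' `c / (1 + exp(-k (x - x0))) + y0` in time `x` from event onset).
#'
#' @param n_neurons number of neurons.
#' @param duration recording length in seconds.
#' @param frame_rate frames per second; default 6, the miniscope convention.
#' @param noise_sd sd of additive i.i.d. Gaussian fluorescence noise (a.u.).
#' @param baseline_level constant baseline fluorescence (a.u.).
#' @param responder_mix named fractions over
#'   `c("null", "transient", "linear_ramp", "sigmoid")`; must sum to 1.
#' @param ramp_slope slope of the linear ramp class (a.u./s).
#' @param sigmoid_params named numeric `c(c=, k=, x0=, y0=)`: amplitude (a.u.),
#'   rate (1/s), inflection (s from event onset), offset (a.u.).
#' @param transient_amplitude peak amplitude of the transient class (a.u.).
#' @param transient_tau exponential decay constant of the transient class (s).
#' @param event_plan an [event_schedule()] (or data.frame with `label`,
#'   `onset_s`, `offset_s`); all intervals must lie within `[0, duration]`.
#' @param seed integer RNG seed; generation is a pure function of (spec, seed).
#' @return a validated list of class `trace_cohort_spec`.
#' @export
trace_cohort_spec <- function(n_neurons, duration, frame_rate = 6,
                              noise_sd = 0.1, baseline_level = 5,
                              responder_mix = c(null = 1),
                              ramp_slope = 0.02,
                              sigmoid_params = c(c = 1, k = 0.2, x0 = 30, y0 = 0),
                              transient_amplitude = 1, transient_tau = 1,
                              event_plan = event_schedule(),
                              seed = 1L) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid spec: `duration` must be a single positive number")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("invalid spec: `frame_rate` must be a single positive number")
  if (!is.numeric(n_neurons) || n_neurons < 1)
    stop("invalid spec: `n_neurons` must be >= 1")
  if (noise_sd < 0) stop("invalid spec: `noise_sd` must be >= 0")
  classes <- c("null", "transient", "linear_ramp", "sigmoid")
  mix <- stats::setNames(numeric(4L), classes)
  if (is.null(names(responder_mix)) ||
      !all(names(responder_mix) %in% classes))
    stop("invalid spec: `responder_mix` names must be among ",
         paste(classes, collapse = ", "))
  mix[names(responder_mix)] <- responder_mix
  if (abs(sum(mix) - 1) > 1e-9)
    stop("invalid spec: `responder_mix` fractions must sum to 1")
  if (!all(c("c", "k", "x0", "y0") %in% names(sigmoid_params)))
    stop("invalid spec: `sigmoid_params` must name c, k, x0, y0")
  event_plan <- as_event_schedule(event_plan)
  if (nrow(event_plan) &&
      (any(event_plan$onset_s < 0) || any(event_plan$offset_s > duration)))
    stop("invalid spec: all event intervals must lie within [0, duration]")
  structure(
    list(n_neurons = as.integer(n_neurons), duration = duration,
         frame_rate = frame_rate, noise_sd = noise_sd,
         baseline_level = baseline_level, responder_mix = mix,
         ramp_slope = ramp_slope, sigmoid_params = sigmoid_params,
         transient_amplitude = transient_amplitude,
         transient_tau = transient_tau,
         event_plan = event_plan, seed = as.integer(seed)),
    class = "trace_cohort_spec")
}

# largest-remainder apportionment of n into integer class counts
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Sigmoid response curve
#'
#' `c / (1 + exp(-k (x - x0))) + y0`, the saturating tuning model used for
#' hot-plate-evoked activity.
#'
#' @param x time from event onset (s).
#' @param c amplitude; @param k rate (1/s); @param x0 inflection (s);
#' @param y0 offset.
#' @return numeric vector.
#' @export
sigmoid_curve <- function(x, c, k, x0, y0) c / (1 + exp(-k * (x - x0))) + y0

# noiseless analytic template of one neuron's event-locked response (a.u.
# above baseline); exported logic kept internal so tests can recompute it
response_template <- function(class, times, events, spec) {
  resp <- numeric(length(times))
  for (e in seq_len(nrow(events))) {
    x <- times - events$onset_s[e]
    in_ev <- x >= 0 & times <= events$offset_s[e]
    if (class == "transient") {
      on <- x >= 0
      resp[on] <- resp[on] +
        spec$transient_amplitude * exp(-x[on] / spec$transient_tau)
    } else if (class == "linear_ramp") {
      resp[in_ev] <- resp[in_ev] + spec$ramp_slope * x[in_ev]
    } else if (class == "sigmoid") {
      p <- spec$sigmoid_params
      resp[in_ev] <- resp[in_ev] +
        sigmoid_curve(x[in_ev], p[["c"]], p[["k"]], p[["x0"]], p[["y0"]])
    }
  }
  resp
}

#' Generate a synthetic trace cohort with planted ground truth
#'
#' Builds a neurons x frames fluorescence matrix at the spec's frame rate:
#' constant baseline plus, per planted class, an event-locked response
#' beginning at each event onset, plus additive i.i.d. Gaussian noise. Class
#' counts follow the responder mix by largest-remainder rounding; class
#' assignment is shuffled across neuron indices under the spec seed. Identical
#' spec + seed gives bit-identical output.
#'
#' @param spec a [trace_cohort_spec()].
#' @return list with `trace` (a [trace_matrix()]), `schedule` (the event plan)
#'   and `truth` (data.frame `neuron_id`, `class`).
#' @export
generate_trace_dataset <- function(spec) {
  stopifnot(inherits(spec, "trace_cohort_spec"))
  n_frames <- round(spec$duration * spec$frame_rate)
  times <- (seq_len(n_frames) - 1L) / spec$frame_rate
  counts <- largest_remainder(spec$responder_mix, spec$n_neurons)
  withr::with_seed(spec$seed, {
    cls <- sample(rep(names(counts), counts))
    templates <- vapply(
      names(counts), function(k) response_template(k, times, spec$event_plan, spec),
      numeric(n_frames))
    vals <- matrix(spec$baseline_level, spec$n_neurons, n_frames) +
      t(templates[, cls, drop = FALSE])
    if (spec$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                            nrow(vals), ncol(vals))
  })
  trace <- trace_matrix(vals, frame_rate = spec$frame_rate, t0 = 0)
  list(trace = trace,
       schedule = spec$event_plan,
       truth = data.frame(neuron_id = trace$neuron_ids, class = cls))
}
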