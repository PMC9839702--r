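# shared fixtures, built in code

# single-event noise-only cohort for calibration checks
null_cohort <- function(n_neurons, seed, noise_sd = 1, duration = 120,
                        onset = 60) {
  spec <- trace_cohort_spec(
    n_neurons = n_neurons, duration = duration, noise_sd = noise_sd,
    baseline_level = 5, responder_mix = c(null = 1),
    event_plan = event_schedule("cs", onset, onset + 20), seed = seed)
  generate_trace_dataset(spec)
}

# z-scored peri-event tensor around the cohort's single event
peri_z_of <- function(cohort, pre = 10, post = 10) {
  peri <- slice_peri_event(cohort$trace, cohort$schedule, pre, post)
  zscore_peri(peri, c(-pre, 0))
}

# tensor built directly from a neurons x frames matrix of snippets
tensor_from_matrix <- function(m, frame_rate = 6, pre = 10, post = 10) {
  tr <- trace_matrix(m, frame_rate = frame_rate, t0 = 0)
  onset <- pre + 30
  n_total <- round((onset + post + 30) * frame_rate)
  full <- matrix(0, nrow(m), n_total)
  i_on <- round(onset * frame_rate) + 1L
  idx <- (i_on - round(pre * frame_rate)):(i_on + round(post * frame_rate))
  stopifnot(length(idx) == ncol(m))
  full[, idx] <- m
  slice_peri_event(trace_matrix(full, frame_rate = frame_rate),
                   event_schedule("ev", onset, onset + post), pre, post)
}
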