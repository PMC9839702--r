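# Signed-rank wrapper following the Wilcoxon convention: zero differences
# dropped; exact distribution for small n without ties, otherwise normal
# approximation with tie/continuity correction (stats::wilcox.test).
signed_rank_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  if (length(diffs) == 0L) return(list(p = 1, shift = 0, n = 0L))
  p <- suppressWarnings(stats::wilcox.test(diffs, mu = 0,
                                           alternative = "two.sided")$p.value)
  list(p = p, shift = stats::median(diffs), n = length(diffs))
}

# per-unit-time trapezoidal AUC over selected frames
auc_rate <- function(t, y) {
  if (length(t) < 2L) return(NA_real_)
  pracma::trapz(t, y) / diff(range(t))
}

# shared frame-level excited/inhibited/none logic for one neuron
classify_frames <- function(t_base, y_base, t_resp, y_resp, alpha, auc_factor) {
  if (stats::sd(c(y_base, y_resp)) == 0) {
    return(data.frame(call = "none", criterion = "none", p_value = NA_real_,
                      shift = 0, auc_base = auc_rate(t_base, y_base),
                      auc_resp = auc_rate(t_resp, y_resp),
                      auc_ratio = NA_real_, sr_call = "none",
                      auc_call = "none", degenerate = TRUE))
  }
  diffs <- if (length(y_resp) == length(y_base)) y_resp - y_base
           else y_resp - mean(y_base)
  sr <- signed_rank_p(diffs)
  sr_call <- if (sr$p < alpha && sr$shift > 0) "excited"
             else if (sr$p < alpha && sr$shift < 0) "inhibited"
             else "none"
  a_base <- auc_rate(t_base, y_base)
  a_resp <- auc_rate(t_resp, y_resp)
  auc_call <- if (a_resp > auc_factor * abs(a_base)) "excited"
              else if (a_resp < -auc_factor * abs(a_base)) "inhibited"
              else "none"
  call <- if (sr_call == auc_call) sr_call
          else if (sr_call == "none") auc_call
          else if (auc_call == "none") sr_call
          else sr_call  # conflicting directions: signed-rank takes precedence
  criterion <- if (sr_call != "none" && auc_call == sr_call) "either"
               else if (call != "none" && sr_call == call) "signed_rank"
               else if (call != "none") "auc_ratio"
               else "none"
  data.frame(call = call, criterion = criterion, p_value = sr$p,
             shift = sr$shift, auc_base = a_base, auc_resp = a_resp,
             auc_ratio = if (a_base != 0) a_resp / abs(a_base) else NA_real_,
             sr_call = sr_call, auc_call = auc_call, degenerate = FALSE)
}

#' Classify neurons as excited / inhibited / none for one stimulus
#'
#' Per neuron, event-averaged peri-event activity in the response window is
#' compared to the baseline window by (a) a two-sided Wilcoxon signed-rank
#' test of response vs baseline frames (paired frame-by-frame when the windows
#' have equal frame counts, otherwise one-sample against the baseline mean)
#' and (b) the normalized area-under-curve criterion: per-unit-time response
#' AUC exceeding `auc_factor` times the absolute per-unit-time baseline AUC.
#' A neuron is excited if either sub-criterion fires with a positive shift;
#' inhibited symmetrically; otherwise none. Both sub-criterion outcomes are
#' recorded for auditability.
#'
#' @param peri a `peri_event_tensor` of normalized (z-score or dF/F) values.
#' @param baseline_window,response_window length-2 numeric windows in relative
#'   seconds, half-open `[start, end)`; each must contain >= 2 frames.
#' @param alpha per-neuron significance level (default 0.05).
#' @param auc_factor AUC ratio threshold (default 2, i.e. "> |2x| baseline").
#' @param stimulus label recorded in the output (defaults to the first event
#'   label of the tensor).
#' @return data.frame of class `response_labels`, one row per neuron:
#'   `neuron_id`, `stimulus`, `call`, `criterion`
#'   (`signed_rank`/`auc_ratio`/`either`/`none`), `p_value`, `shift`,
#'   `auc_base`, `auc_resp`, `auc_ratio`, `sr_call`, `auc_call`, `degenerate`.
#' @export
classify_response <- function(peri, baseline_window, response_window,
                              alpha = 0.05, auc_factor = 2,
                              stimulus = NULL) {
  stopifnot(inherits(peri, "peri_event_tensor"))
  rel <- attr(peri, "rel_time")
  ib <- window_frames(rel, baseline_window[1L], baseline_window[2L])
  ir <- window_frames(rel, response_window[1L], response_window[2L])
  if (length(ib) < 2L || length(ir) < 2L)
    stop("baseline and response windows must each contain >= 2 frames")
  if (is.null(stimulus))
    stimulus <- if (length(attr(peri, "event_labels")))
      attr(peri, "event_labels")[1L] else "stimulus"
  avg <- average_events(peri)
  rows <- lapply(seq_len(nrow(avg)), function(i)
    classify_frames(rel[ib], avg[i, ib], rel[ir], avg[i, ir],
                    alpha, auc_factor))
  out <- cbind(data.frame(neuron_id = attr(peri, "neuron_ids"),
                          stimulus = stimulus),
               do.call(rbind, rows))
  class(out) <- c("response_labels", "data.frame")
  out
}

#' Blockwise classification against a baseline recording block
#'
#' For recordings made in repeated blocks (e.g. 2-min windows at 0.5-2.5 h
#' after an injection), classifies each neuron in every block against the
#' baseline block with the same signed-rank + normalized-AUC criteria, and
#' reports whether any block was called excited.
#'
#' @param blocks named list of numeric matrices (neurons x frames) or
#'   [trace_matrix()] objects, all with the same neuron set.
#' @param baseline_block matrix or [trace_matrix()], same neurons.
#' @param alpha per-neuron significance level.
#' @param auc_factor AUC ratio threshold.
#' @param frame_rate frames per second used to build time axes when plain
#'   matrices are supplied (default 6).
#' @return list with `calls` (data.frame `neuron_id`, `block`, `call`, ...)
#'   and `any_block_excited` (named logical per neuron).
#' @export
classify_blockwise <- function(blocks, baseline_block, alpha = 0.05,
                               auc_factor = 2, frame_rate = 6) {
  get_vals <- function(b) if (inherits(b, "trace_matrix")) b$values else as.matrix(b)
  base <- get_vals(baseline_block)
  ids <- rownames(base)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(base)))
  if (is.null(names(blocks)))
    names(blocks) <- sprintf("block%d", seq_along(blocks))
  calls <- list()
  for (bn in names(blocks)) {
    v <- get_vals(blocks[[bn]])
    if (nrow(v) != nrow(base) ||
        (!is.null(rownames(v)) && !identical(rownames(v), rownames(base))))
      stop("schema error: block '", bn,
           "' does not match the baseline block's neuron set")
    t_base <- (seq_len(ncol(base)) - 1L) / frame_rate
    t_resp <- (seq_len(ncol(v)) - 1L) / frame_rate
    rows <- lapply(seq_len(nrow(v)), function(i)
      classify_frames(t_base, base[i, ], t_resp, v[i, ], alpha, auc_factor))
    calls[[bn]] <- cbind(data.frame(neuron_id = ids, block = bn),
                         do.call(rbind, rows))
  }
  calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  any_exc <- tapply(calls$call == "excited", calls$neuron_id, any)
  list(calls = calls, any_block_excited = any_exc[ids])
}

#' Detect monotonically increasing activity after an event
#'
#' Per neuron, ordinary least-squares regression of activity on time over a
#' window relative to event onset (default 0-60 s, the hot-plate convention);
#' flagged when the one-sided p-value for slope > 0 rejects at `alpha`.
#'
#' @param norm a [trace_matrix()] or `normalized_trace`.
#' @param onset event onset in recording seconds (default 0).
#' @param window length-2 relative window in seconds, default `c(0, 60)`.
#' @param alpha one-sided significance level.
#' @return data.frame `neuron_id`, `flag`, `slope` (1/s), `p` (one-sided);
#'   constant traces get `flag = FALSE`, `slope = 0`, `p = 1`.
#' @export
detect_monotonic_increase <- function(norm, onset = 0, window = c(0, 60),
                                      alpha = 0.05) {
  stopifnot(inherits(norm, "trace_matrix"))
  times <- frame_times(norm)
  idx <- window_frames(times, onset + window[1L], onset + window[2L])
  if (length(idx) < 3L) stop("window must contain >= 3 frames")
  t <- times[idx] - onset
  res <- lapply(seq_len(nrow(norm$values)), function(i) {
    fit <- fit_linear(t, norm$values[i, idx])
    p1 <- if (fit$slope > 0) fit$p / 2
          else if (fit$slope < 0) 1 - fit$p / 2
          else 1
    data.frame(flag = p1 < alpha, slope = fit$slope, p = p1)
  })
  cbind(data.frame(neuron_id = norm$neuron_ids), do.call(rbind, res))
}

#' Detect learning-related changes in trial responses
#'
#' Time-varying responses across trials are called by (a) linear regression of
#' per-trial response magnitude on trial number with significant non-zero
#' slope, and/or (b) a paired signed-rank comparison of frame-level activity
#' on the first vs last trial. Increasing if either fires positively,
#' decreasing symmetrically, else stable.
#'
#' @param per_trial numeric matrix neurons x trials of response magnitudes
#'   (e.g. mean z in the response window per trial).
#' @param alpha significance level.
#' @param first_frames,last_frames optional numeric matrices neurons x frames
#'   of first- and last-trial activity, enabling the first-vs-last criterion.
#' @return data.frame `neuron_id`, `call`
#'   (`increasing`/`decreasing`/`stable`), `method`
#'   (`slope`/`first_vs_last`/`both`/`none`), `slope`, `slope_p`, `fvl_p`.
#' @export
detect_learning_modulation <- function(per_trial, alpha = 0.05,
                                       first_frames = NULL,
                                       last_frames = NULL) {
  per_trial <- as.matrix(per_trial)
  if (ncol(per_trial) < 2L)
    stop("insufficient trials: need >= 2 trials per neuron")
  ids <- rownames(per_trial)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(per_trial)))
  trials <- seq_len(ncol(per_trial))
  out <- lapply(seq_len(nrow(per_trial)), function(i) {
    # the slope criterion needs >= 3 trials; with 2, only first-vs-last applies
    fit <- if (length(trials) >= 3L) fit_linear(trials, per_trial[i, ])
           else list(slope = NA_real_, p = NA_real_)
    s_dir <- if (!is.na(fit$p) && fit$p < alpha && fit$slope > 0) 1L
             else if (!is.na(fit$p) && fit$p < alpha && fit$slope < 0) -1L
             else 0L
    f_dir <- 0L
    fvl_p <- NA_real_
    if (!is.null(first_frames) && !is.null(last_frames)) {
      sr <- signed_rank_p(last_frames[i, ] - first_frames[i, ])
      fvl_p <- sr$p
      f_dir <- if (sr$p < alpha && sr$shift > 0) 1L
               else if (sr$p < alpha && sr$shift < 0) -1L else 0L
    }
    dir <- if (s_dir != 0L) s_dir else f_dir
    call <- c("decreasing", "stable", "increasing")[dir + 2L]
    method <- if (s_dir != 0L && f_dir == s_dir) "both"
              else if (s_dir != 0L) "slope"
              else if (f_dir != 0L) "first_vs_last" else "none"
    data.frame(call = call, method = method, slope = fit$slope,
               slope_p = fit$p, fvl_p = fvl_p)
  })
  cbind(data.frame(neuron_id = ids), do.call(rbind, out))
}

#' Zero-lag cross-correlation of two trials' peri-event snippets
#'
#' Per neuron, the Pearson correlation between the aligned snippets of two
#' event instances (zero lag).
#'
#' @param peri a `peri_event_tensor`.
#' @param trial_a,trial_b event indices.
#' @return data.frame `neuron_id`, `r`, `defined` (FALSE when either snippet
#'   has zero variance; such neurons carry `r = NA` and should be excluded
#'   from summaries).
#' @export
trial_cross_correlation <- function(peri, trial_a, trial_b) {
  stopifnot(inherits(peri, "peri_event_tensor"))
  d <- dim(peri)
  if (trial_a > d[2L] || trial_b > d[2L] || trial_a < 1L || trial_b < 1L)
    stop("trial index out of range")
  if (d[3L] < 3L) stop("need >= 3 frames per snippet")
  r <- vapply(seq_len(d[1L]), function(i) {
    a <- peri[i, trial_a, ]
    b <- peri[i, trial_b, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1L))
  data.frame(neuron_id = attr(peri, "neuron_ids"), r = r, defined = !is.na(r))
}

#' Response latency from event onset
#'
#' Latency is the time from event onset to the first frame of the first run of
#' at least `sustain` consecutive frames exceeding the baseline mean by
#' `threshold_sd` baseline standard deviations.
#'
#' @param peri a `peri_event_tensor`.
#' @param baseline_window relative-time window for baseline moments,
#'   default `c(-10, 0)`.
#' @param threshold_sd threshold in baseline sds (default 2).
#' @param sustain minimum consecutive supra-threshold frames (default 2).
#' @param event event index to measure (default 1, e.g. first foot shock).
#' @return data.frame `neuron_id`, `latency_s` (`NA` when the threshold is
#'   never exceeded), `defined`.
#' @export
response_latency <- function(peri, baseline_window = c(-10, 0),
                             threshold_sd = 2, sustain = 2, event = 1L) {
  stopifnot(inherits(peri, "peri_event_tensor"))
  rel <- attr(peri, "rel_time")
  ib <- window_frames(rel, baseline_window[1L], baseline_window[2L])
  post <- which(rel >= -1e-9)
  lat <- vapply(seq_len(dim(peri)[1L]), function(i) {
    y <- peri[i, event, ]
    b <- y[ib]
    thr <- mean(b) + threshold_sd * stats::sd(b)
    above <- y[post] >= thr
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= sustain)
    if (!length(hit)) return(NA_real_)
    first <- ends[hit[1L]] - runs$lengths[hit[1L]] + 1L
    rel[post[first]]
  }, numeric(1L))
  data.frame(neuron_id = attr(peri, "neuron_ids"), latency_s = lat,
             defined = !is.na(lat))
}

#' Population proportion of responsive neurons with bootstrap error
#'
#' Point estimate `p_hat = n_responsive / n_total` plus a neuron-level
#' bootstrap (resampling neurons with replacement) giving the bootstrapped
#' mean and standard deviation used for bars and error.
#'
#' @param labels a `response_labels` data.frame from [classify_response()].
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer RNG seed.
#' @param which which call counts as responsive: `"excited"` (default),
#'   `"inhibited"` or `"any"`.
#' @return list of class `proportion_estimate`: `n_responsive`, `n_total`,
#'   `p_hat`, `boot_mean`, `boot_sd`, `n_boot`, `seed`.
#' @export
population_proportions <- function(labels, n_boot = 10000, seed = 1L,
                                   which = c("excited", "inhibited", "any")) {
  which <- match.arg(which)
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  n_total <- nrow(labels)
  if (n_total < 1) stop("need at least one neuron")
  resp <- if (which == "any") labels$call != "none" else labels$call == which
  withr::with_seed(seed, {
    boots <- colMeans(matrix(sample(as.numeric(resp), n_total * n_boot,
                                    replace = TRUE), n_total, n_boot))
  })
  structure(list(n_responsive = sum(resp), n_total = n_total,
                 p_hat = mean(resp), boot_mean = mean(boots),
                 boot_sd = stats::sd(boots), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportion %d/%d = %.3f (bootstrap mean %.3f, sd %.3f, %d resamples)\n",
              x$n_responsive, x$n_total, x$p_hat, x$boot_mean, x$boot_sd, x$n_boot))
  invisible(x)
}

#' Paired comparison of per-neuron responses across two conditions
#'
#' Two-sided Wilcoxon signed-rank test of per-neuron response magnitudes in
#' two matched conditions (e.g. cued vs uncued freezing bouts). Zero
#' differences are dropped; if all pairs are tied the test returns p = 1.
#'
#' @param a,b numeric vectors of per-neuron magnitudes, matched by position.
#' @return list `statistic` (median paired difference), `p`, `direction`
#'   (`"a_greater"`, `"b_greater"`, `"none"`), `n_pairs`.
#' @export
compare_event_conditions <- function(a, b) {
  if (length(a) != length(b)) stop("conditions must have equal length")
  keep <- stats::complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("insufficient data: need >= 2 complete pairs")
  sr <- signed_rank_p(a - b)
  dir <- if (sr$p < 0.05 && sr$shift > 0) "a_greater"
         else if (sr$p < 0.05 && sr$shift < 0) "b_greater" else "none"
  list(statistic = stats::median(a - b), p = sr$p, direction = dir,
       n_pairs = length(a))
}
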