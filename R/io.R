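#' Write a trace bundle (matrix + events + metadata) to CSV
#'
#' Writes `<prefix>_matrix.csv` (column `neuron_id`, then one column per
#' frame), `<prefix>_events.csv` (`label`, `onset_s`, `offset_s`) and
#' `<prefix>_meta.json` (`frame_rate`, `t0`, `n_frames`).
#'
#' @param trace a [trace_matrix()]; @param schedule an [event_schedule()].
#' @param dir output directory (created if absent); @param prefix file prefix.
#' @return invisibly, the three file paths.
#' @export
write_trace_bundle <- function(trace, schedule, dir, prefix = "traces") {
  stopifnot(inherits(trace, "trace_matrix"))
  schedule <- as_event_schedule(schedule)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_matrix.csv", "_events.csv",
                                           "_meta.json")))
  mat <- data.frame(neuron_id = trace$neuron_ids, trace$values,
                    check.names = FALSE)
  colnames(mat) <- c("neuron_id", sprintf("f%d", seq_len(ncol(trace$values))))
  utils::write.csv(mat, paths[1L], row.names = FALSE)
  utils::write.csv(as.data.frame(schedule), paths[2L], row.names = FALSE)
  jsonlite::write_json(list(frame_rate = trace$frame_rate, t0 = trace$t0,
                            n_frames = ncol(trace$values)),
                       paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a trace bundle written by [write_trace_bundle()]
#'
#' @param dir directory; @param prefix file prefix.
#' @return list `trace` (a [trace_matrix()]) and `schedule`
#'   (an [event_schedule()]). Frame rate is read from the metadata sidecar,
#'   defaulting to 6 frames/s when absent.
#' @export
read_trace_bundle <- function(dir, prefix = "traces") {
  p_mat <- file.path(dir, paste0(prefix, "_matrix.csv"))
  p_ev <- file.path(dir, paste0(prefix, "_events.csv"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  for (p in c(p_mat, p_ev))
    if (!file.exists(p)) stop("missing file: ", p)
  meta <- if (file.exists(p_meta)) jsonlite::read_json(p_meta) else list()
  fr <- if (!is.null(meta$frame_rate)) meta$frame_rate else 6
  t0 <- if (!is.null(meta$t0)) meta$t0 else 0
  mat <- utils::read.csv(p_mat, check.names = FALSE)
  if (!"neuron_id" %in% names(mat))
    stop("parse error in ", p_mat, ": missing column 'neuron_id'")
  ev <- utils::read.csv(p_ev)
  for (col in c("label", "onset_s", "offset_s"))
    if (!col %in% names(ev))
      stop("parse error in ", p_ev, ": missing column '", col, "'")
  trace <- trace_matrix(as.matrix(mat[, -1L, drop = FALSE]),
                        neuron_ids = mat$neuron_id, frame_rate = fr, t0 = t0)
  list(trace = trace, schedule = event_schedule(ev$label, ev$onset_s,
                                                ev$offset_s))
}

#' Pipeline configuration
#'
#' Assembles and validates the knobs shared across stages. Peri-stimulus
#' window defaults follow the recording conventions: 10 s before/after CS and
#' US, 5 s before/after freezing bouts.
#'
#' @param stages character subset of
#'   `c("simulate", "preprocess", "classify", "fit", "topo")`.
#' @param windows named list of `c(pre, post)` seconds per event type.
#' @param alpha per-neuron significance level in (0, 1).
#' @param auc_factor normalized-AUC ratio threshold.
#' @param n_boot bootstrap resamples; @param n_shuffle permutations.
#' @param seed master integer seed (stage seeds are derived from it).
#' @param n_neurons,duration synthetic trace cohort size for the simulate
#'   stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess", "classify",
                                       "fit", "topo"),
                            windows = list(cs = c(10, 10), us = c(10, 10),
                                           freezing = c(5, 5)),
                            alpha = 0.05, auc_factor = 2,
                            n_boot = 10000, n_shuffle = 1000, seed = 1L,
                            n_neurons = 100, duration = 300) {
  known <- c("simulate", "preprocess", "classify", "fit", "topo")
  if (length(stages) && !all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("validation error: `alpha` must lie in (0, 1)")
  if (auc_factor <= 0) stop("validation error: `auc_factor` must be > 0")
  if (n_boot < 1 || n_shuffle < 1)
    stop("validation error: `n_boot` and `n_shuffle` must be >= 1")
  structure(list(stages = stages, windows = windows, alpha = alpha,
                 auc_factor = auc_factor, n_boot = as.integer(n_boot),
                 n_shuffle = as.integer(n_shuffle), seed = as.integer(seed),
                 n_neurons = as.integer(n_neurons), duration = duration),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$windows <- lapply(raw$windows, as.numeric)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the selected stages on seeded synthetic cohorts: simulate traces
#' and a tracing cohort, normalise and slice peri-event windows, classify
#' stimulus responses, fit linear/sigmoid tuning models with a bootstrap
#' population comparison, and run the topography statistics. Every stochastic
#' stage is seeded from the config, so the summary is identical across runs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory; stage CSVs, `summary.json` and
#'   `run_log.txt` are written there.
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(config$stages)) {
    warning("no stages selected; nothing to do")
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, alpha = config$alpha)
  log <- c(sprintf("ceatopo %s", as.character(utils::packageVersion("ceatopo"))),
           sprintf("master seed: %d", config$seed))

  tspec <- trace_cohort_spec(
    n_neurons = config$n_neurons, duration = config$duration,
    responder_mix = c(null = 0.4, transient = 0.2, linear_ramp = 0.2,
                      sigmoid = 0.2),
    event_plan = event_schedule("cs", config$duration * 0.4,
                                config$duration * 0.4 + 60),
    seed = config$seed)
  sim <- NULL
  if ("simulate" %in% config$stages) {
    sim <- generate_trace_dataset(tspec)
    write_trace_bundle(sim$trace, sim$schedule, out_dir, "sim")
    utils::write.csv(sim$truth, file.path(out_dir, "sim_truth.csv"),
                     row.names = FALSE)
    summary$n_neurons <- tspec$n_neurons
    log <- c(log, "simulate: trace cohort written")
  }
  peri_z <- NULL
  if ("preprocess" %in% config$stages) {
    if (is.null(sim)) sim <- generate_trace_dataset(tspec)
    w <- config$windows$cs
    peri <- slice_peri_event(sim$trace, sim$schedule, w[1L], w[2L])
    peri_z <- zscore_peri(peri, c(-w[1L], 0))
    dff <- deltaf_over_f(sim$trace)
    summary$dff_mean_abs <- mean(abs(dff$values))
    log <- c(log, "preprocess: dF/F and peri-event z-scores computed")
  }
  if ("classify" %in% config$stages) {
    if (is.null(peri_z)) {
      if (is.null(sim)) sim <- generate_trace_dataset(tspec)
      w <- config$windows$cs
      peri_z <- zscore_peri(slice_peri_event(sim$trace, sim$schedule,
                                             w[1L], w[2L]), c(-w[1L], 0))
    }
    w <- config$windows$cs
    labels <- classify_response(peri_z, c(-w[1L], 0), c(0, w[2L]),
                                alpha = config$alpha,
                                auc_factor = config$auc_factor)
    utils::write.csv(labels, file.path(out_dir, "response_labels.csv"),
                     row.names = FALSE)
    prop <- population_proportions(labels, n_boot = config$n_boot,
                                   seed = config$seed + 1L)
    summary$prop_excited <- prop$p_hat
    summary$prop_boot_sd <- prop$boot_sd
    log <- c(log, sprintf("classify: %d/%d excited", prop$n_responsive,
                          prop$n_total))
  }
  if ("fit" %in% config$stages) {
    if (is.null(sim)) sim <- generate_trace_dataset(tspec)
    on <- sim$schedule$onset_s[1L]
    times <- frame_times(sim$trace)
    idx <- window_frames(times, on, on + 60)
    t_rel <- times[idx] - on
    resp <- sim$truth$class %in% c("linear_ramp", "sigmoid")
    fits <- lapply(which(resp), function(i) {
      y <- deltaf_over_f(sim$trace)$values[i, idx]
      lin <- fit_linear(t_rel, y)
      sig <- fit_sigmoid(t_rel, y)
      cmp <- compare_models(lin, sig)
      data.frame(neuron_id = sim$trace$neuron_ids[i],
                 class = sim$truth$class[i], slope = lin$slope,
                 r2_lin = lin$r2, r2_sig = sig$r2, k = sig$k,
                 delta_se = cmp$delta_se, converged = sig$converged)
    })
    fits <- do.call(rbind, fits)
    utils::write.csv(fits, file.path(out_dir, "tuning_fits.csv"),
                     row.names = FALSE)
    boot <- bootstrap_population_stat(fits$delta_se, "delta_se",
                                      n_boot = config$n_boot,
                                      seed = config$seed + 2L)
    summary$delta_se_boot_mean <- boot$mean
    summary$delta_se_boot_sd <- boot$sd
    log <- c(log, sprintf("fit: %d tuning fits", nrow(fits)))
  }
  if ("topo" %in% config$stages) {
    cohort <- generate_tracing_cohort(topography_cohort_spec(
      cluster_plan = list(
        list(regions = sprintf("R%02d", 1:4), direction = "rostral",
             coupling = 0.9),
        list(regions = sprintf("R%02d", 5:8), direction = "caudal",
             coupling = 0.9)),
      seed = config$seed + 3L))
    kept <- filter_regions(cohort$region_counts)
    corr <- connectivity_correlation_matrix(cohort$region_counts, kept)
    cl <- hierarchical_cluster(corr, n_clusters = min(8L, nrow(corr)))
    rel <- cluster_starter_relationship(cl, cohort$region_counts,
                                        cohort$starters)
    utils::write.csv(rel, file.path(out_dir, "cluster_starter.csv"),
                     row.names = FALSE)
    ip <- inplane_correlation_test(cohort$sections,
                                   n_shuffle = config$n_shuffle,
                                   seed = config$seed + 4L)
    summary$n_regions_retained <- length(kept)
    summary$n_clusters <- cl$n_clusters
    summary$inplane_p <- ip$p
    log <- c(log, sprintf("topo: %d regions retained, %d clusters, in-plane p = %.4g",
                          length(kept), cl$n_clusters, ip$p))
  }
  jsonlite::write_json(summary[order(names(summary))],
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
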