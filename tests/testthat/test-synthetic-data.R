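test_that("degenerate no-signal spec yields the exact baseline everywhere", {
  spec <- trace_cohort_spec(10, duration = 30, noise_sd = 0,
                            baseline_level = 5, responder_mix = c(null = 1),
                            seed = 1)
  d <- generate_trace_dataset(spec)
  expect_true(all(d$trace$values == 5))
  expect_equal(dim(d$trace$values), c(10L, 180L))
  expect_true(all(d$truth$class == "null"))
})

test_that("generation is a pure function of spec and seed", {
  spec <- trace_cohort_spec(20, duration = 60, noise_sd = 0.5,
                            responder_mix = c(null = 0.5, transient = 0.5),
                            event_plan = event_schedule("cs", 20, 40),
                            seed = 42)
  a <- generate_trace_dataset(spec)
  b <- generate_trace_dataset(spec)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless sigmoid responder passes through baseline + c/2 at x0", {
  spec <- trace_cohort_spec(3, duration = 120, noise_sd = 0,
                            baseline_level = 2,
                            responder_mix = c(sigmoid = 1),
                            sigmoid_params = c(c = 1, k = 0.2, x0 = 30, y0 = 0),
                            event_plan = event_schedule("hp", 30, 100),
                            seed = 3)
  d <- generate_trace_dataset(spec)
  tt <- frame_times(d$trace)
  at_x0 <- which(abs(tt - (30 + 30)) < 1e-9)  # event onset 30 s + x0 = 30 s
  expect_length(at_x0, 1L)
  # independent evaluation of c / (1 + exp(-k (x - x0))) + y0 at x = x0
  expect_equal(unname(d$trace$values[, at_x0]), rep(2 + 1 / 2, 3))
})

test_that("responder mix counts follow largest-remainder rounding exactly", {
  spec <- trace_cohort_spec(7, duration = 10, noise_sd = 0,
                            responder_mix = c(null = 0.5, transient = 0.3,
                                              linear_ramp = 0.2),
                            seed = 5)
  d <- generate_trace_dataset(spec)
  tab <- table(d$truth$class)
  # 7 * (.5, .3, .2) = (3.5, 2.1, 1.4): floors (3, 2, 1) + one to the
  # largest remainder (null)
  expect_equal(unname(tab[c("null", "transient", "linear_ramp")]),
               c(4L, 2L, 1L), ignore_attr = TRUE)
})

test_that("invalid trace specs are rejected", {
  expect_error(trace_cohort_spec(5, duration = -1), "duration")
  expect_error(trace_cohort_spec(5, duration = 10, frame_rate = 0),
               "frame_rate")
  expect_error(trace_cohort_spec(5, duration = 10,
                                 responder_mix = c(null = 0.6)), "sum to 1")
  expect_error(trace_cohort_spec(5, duration = 10,
                                 event_plan = event_schedule("cs", 5, 20)),
               "within")
})

test_that("tracing cohort validates cluster plans and coupling", {
  expect_error(topography_cohort_spec(cluster_plan = list(
    list(regions = c("R01"), direction = "rostral", coupling = 1.5))),
    "coupling")
  expect_error(topography_cohort_spec(cluster_plan = list(
    list(regions = c("R01"), direction = "rostral", coupling = 0.5),
    list(regions = c("R01"), direction = "caudal", coupling = 0.5))),
    "disjoint")
  expect_error(topography_cohort_spec(inplane_r = -0.3), "inplane_r")
})

test_that("perfect in-plane coupling without count noise gives identical counts", {
  co <- generate_tracing_cohort(
    topography_cohort_spec(inplane_r = 1, count_noise = "none", seed = 2))
  expect_identical(co$sections$input_count, co$sections$starter_count)
  rs <- vapply(split(co$sections, co$sections$subject_id),
               function(d) stats::cor(d$input_count, d$starter_count),
               numeric(1))
  expect_equal(unname(rs), rep(1, length(rs)), tolerance = 1e-12)
})

test_that("null coupling leaves cluster penetrance unrelated to starter AP", {
  # coupling 0 everywhere: mean |r| across seeds stays near 0
  rs <- vapply(1:30, function(i) {
    co <- generate_tracing_cohort(topography_cohort_spec(
      cluster_plan = list(list(regions = sprintf("R%02d", 1:4),
                               direction = "rostral", coupling = 0)),
      seed = 100 + i))
    cl <- hierarchical_cluster(
      connectivity_correlation_matrix(co$region_counts), n_clusters = 2)
    rel <- cluster_starter_relationship(cl, co$region_counts, co$starters)
    mean(abs(rel$r), na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rs), 0.45)  # |r| of pure noise at n = 12 averages ~0.23
})

test_that("projection generator plants an exactly recoverable AP bias", {
  ap <- c(-1.8, -1.4, -1.0)
  flat <- generate_projection_dataset(4, ap, bias_slope = 0, noise_sd = 0)
  expect_equal(projection_bias(flat)$bias, rep(0, 4), tolerance = 1e-12)
  sloped <- generate_projection_dataset(4, ap, bias_slope = -1, noise_sd = 0)
  expect_equal(projection_bias(sloped)$bias, rep(-1, 4), tolerance = 1e-12)
  expect_error(generate_projection_dataset(4, -1.4, bias_slope = 0),
               "2 AP levels")
})

test_that("noisy projection bias is recovered on average across subjects", {
  pr <- generate_projection_dataset(50, seq(-1.8, -1.0, by = 0.2),
                                    bias_slope = 0.5, noise_sd = 0.1,
                                    seed = 9)
  expect_lt(abs(mean(projection_bias(pr)$bias) - 0.5), 0.1)
})
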