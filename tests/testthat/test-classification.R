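test_that("null responses are called none; reflected responses inhibited", {
  set.seed(10)
  # response distributed like baseline (noise about a common level) -> none
  m_null <- matrix(rnorm(40 * 121, mean = 1), 40)
  lab <- classify_response(tensor_from_matrix(m_null), c(-10, 0), c(0, 10))
  expect_gte(mean(lab$call == "none"), 0.85)
  # strong negative deflection -> inhibited
  base <- matrix(rnorm(5 * 60), 5)
  m_inh <- cbind(base, base - 5, base[, 1] - 5)
  lab2 <- classify_response(tensor_from_matrix(m_inh), c(-10, 0), c(0, 10))
  expect_true(all(lab2$call == "inhibited"))
})

test_that("the normalized-AUC criterion fires on constructed segment means", {
  # constant segments: baseline per-second AUC a, response 2.5a -> ratio 2.5 > 2
  a <- 0.4
  m <- matrix(c(rep(a, 60), rep(2.5 * a, 61)), 1)
  lab <- classify_response(tensor_from_matrix(m), c(-10, 0), c(0, 10))
  expect_equal(lab$auc_ratio, 2.5, tolerance = 1e-9)
  expect_equal(lab$auc_call, "excited")
  expect_equal(lab$call, "excited")
})

test_that("negating all traces swaps excited and inhibited counts exactly", {
  co <- null_cohort(150, seed = 17)
  pz <- peri_z_of(co)
  lab <- classify_response(pz, c(-10, 0), c(0, 10))
  neg <- co$trace
  neg$values <- -neg$values
  labn <- classify_response(zscore_peri(
    slice_peri_event(neg, co$schedule, 10, 10), c(-10, 0)),
    c(-10, 0), c(0, 10))
  expect_equal(sum(lab$call == "excited"), sum(labn$call == "inhibited"))
  expect_equal(sum(lab$call == "inhibited"), sum(labn$call == "excited"))
  expect_equal(lab$call == "none", labn$call == "none")
})

test_that("all-tied windows come back none with a degenerate flag", {
  m <- matrix(1, 2, 121)
  lab <- classify_response(tensor_from_matrix(m), c(-10, 0), c(0, 10))
  expect_true(all(lab$call == "none"))
  expect_true(all(lab$degenerate))
})

test_that("planted sustained responders are detected with high sensitivity", {
  # transient with slow decay (tau = 10 s) sustains >= ~2.7 noise-sd across a
  # 2 s response window; spec-level effect >= 3 noise-sd at onset
  spec <- trace_cohort_spec(500, duration = 120, noise_sd = 1,
                           baseline_level = 5,
                           responder_mix = c(transient = 1),
                           transient_amplitude = 3, transient_tau = 10,
                           event_plan = event_schedule("cs", 60, 80),
                           seed = 23)
  d <- generate_trace_dataset(spec)
  pz <- peri_z_of(d)
  lab <- classify_response(pz, c(-10, 0), c(0, 2))
  expect_gte(mean(lab$call == "excited"), 0.95)
})

test_that("blockwise classification localises the elevated block", {
  set.seed(11)
  base <- matrix(rnorm(6 * 120, 0, 1), 6)
  blocks <- list(b1 = base, b2 = base + 5, b3 = base)
  res <- classify_blockwise(blocks, base)
  expect_true(all(res$any_block_excited))
  calls <- with(res$calls, tapply(call == "excited", block, sum))
  expect_equal(unname(calls["b2"]), 6L)
  expect_equal(unname(calls["b1"] + calls["b3"]), 0L)
  # identical blocks: nothing excited
  res0 <- classify_blockwise(list(b1 = base), base)
  expect_false(any(res0$any_block_excited))
  # block order is irrelevant up to relabeling
  res_perm <- classify_blockwise(blocks[c(3, 1, 2)], base)
  expect_equal(unname(res_perm$any_block_excited),
               unname(res$any_block_excited))
  expect_error(classify_blockwise(list(b1 = base[1:3, ]), base), "schema")
})

test_that("monotonic-increase detection is one-sided in the slope", {
  t <- seq(0, 119.9, by = 1 / 6)
  ramp <- 0.01 * t
  tr <- trace_matrix(rbind(ramp, rep(2, length(t)), -ramp), frame_rate = 6)
  res <- detect_monotonic_increase(tr, onset = 0, window = c(0, 60))
  expect_equal(res$flag, c(TRUE, FALSE, FALSE))
  expect_equal(res$slope[1], 0.01, tolerance = 1e-9)
  expect_equal(res$slope[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("learning modulation combines slope and first-vs-last criteria", {
  per_trial <- rbind(0:4, rep(2, 5), 4:0)
  res <- detect_learning_modulation(per_trial)
  expect_equal(res$call, c("increasing", "stable", "decreasing"))
  # flat per-trial means but a clean first-vs-last frame-level shift
  first <- matrix(0, 1, 120)
  last <- matrix(1, 1, 120)
  res2 <- detect_learning_modulation(matrix(c(0.5, 0.4), 1), alpha = 0.05,
                                     first_frames = first, last_frames = last)
  expect_equal(res2$call, "increasing")
  expect_equal(res2$method, "first_vs_last")
  expect_error(detect_learning_modulation(matrix(1, 2, 1)), "trials")
})

test_that("trial cross-correlation is zero-lag Pearson r per neuron", {
  m <- rbind(c(0, 1, 2), c(0, 1, 2), c(1, 1, 1))
  snips <- array(NA_real_, c(3, 2, 3))
  snips[, 1, ] <- m
  snips[, 2, ] <- rbind(c(0, 1, 2), c(0, 2, 2), c(5, 5, 5))
  peri <- structure(snips, rel_time = c(0, 1, 2) / 6, frame_rate = 6,
                    window = c(0, 2 / 6), event_labels = c("a", "b"),
                    neuron_ids = c("n1", "n2", "n3"),
                    class = "peri_event_tensor")
  res <- trial_cross_correlation(peri, 1, 2)
  expect_equal(res$r[1], 1)
  # hand Pearson: cov 1, sds 1 and sqrt(4/3) -> r = sqrt(3)/2
  expect_equal(res$r[2], sqrt(3) / 2, tolerance = 1e-9)
  expect_false(res$defined[3])
  # negation flips the sign exactly
  peri2 <- peri
  peri2[, 2, ] <- -peri2[, 2, ]
  expect_equal(trial_cross_correlation(peri2, 1, 2)$r[1], -1)
})

test_that("response latency is the first sustained threshold crossing", {
  set.seed(12)
  base <- rnorm(60, 0, 1)
  step0 <- c(base, rep(5, 61))                     # crossing at onset
  step2 <- c(base, rep(0, 12), rep(5, 49))         # crossing at +2 s
  flat <- c(base, rnorm(61, 0, 1))                 # never crosses
  m <- rbind(step0, step2, flat)
  peri <- tensor_from_matrix(m)
  res <- response_latency(peri, baseline_window = c(-10, 0), threshold_sd = 2)
  expect_equal(res$latency_s[1], 0)
  expect_equal(res$latency_s[2], 2)
  expect_false(res$defined[3])
})

test_that("population proportions bootstrap matches the binomial closed form", {
  labels <- data.frame(call = rep(c("excited", "none"), each = 50))
  est <- population_proportions(labels, n_boot = 10000, seed = 7)
  expect_equal(est$p_hat, 0.5)
  # sd of a resampled mean of 100 Bernoulli(1/2): sqrt(0.25/100) = 0.05
  expect_lt(abs(est$boot_sd - 0.05) / 0.05, 0.1)
  est2 <- population_proportions(labels, n_boot = 10000, seed = 7)
  expect_identical(est$boot_mean, est2$boot_mean)
  all_exc <- data.frame(call = rep("excited", 20))
  est3 <- population_proportions(all_exc, n_boot = 500, seed = 1)
  expect_equal(est3$p_hat, 1)
  expect_equal(est3$boot_sd, 0)
})

test_that("paired condition comparison is an exact signed-rank test", {
  expect_equal(compare_event_conditions(1:10, 1:10)$p, 1)
  set.seed(13)
  b <- rnorm(30)
  res <- compare_event_conditions(b + 1, b)  # uniform +1 shift, noiseless
  expect_lt(res$p, 0.05)
  expect_equal(res$direction, "a_greater")
  expect_error(compare_event_conditions(1, 2), "insufficient")
})
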