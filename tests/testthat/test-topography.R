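toy_counts <- function() {
  # 3 subjects x 3 regions; totals 1000 each
  data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 3),
    region = rep(c("A", "B", "C"), 3),
    count = c(10, 5, 985, 10, 5, 985, 10, 5, 985))
}

test_that("region filter applies a strict 0.5% cutoff", {
  kept <- filter_regions(toy_counts(), cutoff_fraction = 0.005)
  # A at 1% retained; B at exactly 0.5% dropped (strict >); C retained
  expect_equal(kept, c("A", "C"))
  expect_equal(filter_regions(data.frame(subject_id = character(),
                                         region = character(),
                                         count = numeric())), character())
  # idempotent and order-invariant in subjects
  shuffled <- toy_counts()[sample(9), ]
  expect_equal(filter_regions(shuffled), kept)
})

test_that("zero-total subjects are excluded from the cutoff mean", {
  tab <- rbind(toy_counts(),
               data.frame(subject_id = "s4", region = c("A", "B", "C"),
                          count = c(0, 0, 0)))
  expect_warning(kept <- filter_regions(tab), "zero total")
  expect_equal(kept, c("A", "C"))
})

test_that("connectivity correlations are on fractions and catch hand cases", {
  # fractions {.1,.2,.3,.4} vs {.4,.3,.2,.1}: perfect negative
  tab <- data.frame(
    subject_id = rep(paste0("s", 1:4), each = 2),
    region = rep(c("A", "B"), 4),
    count = c(10, 40, 20, 30, 30, 20, 40, 10))
  corr <- connectivity_correlation_matrix(tab)
  expect_equal(corr["A", "B"], -1, tolerance = 1e-12)
  expect_equal(diag(corr), c(A = 1, B = 1))
  # invariant to per-subject total rescaling
  tab2 <- tab
  tab2$count <- tab$count * rep(c(1, 10, 3, 7), each = 2)
  expect_equal(connectivity_correlation_matrix(tab2), corr,
               tolerance = 1e-12)
})

test_that("hierarchical clustering recovers planted blocks exactly", {
  blocks <- matrix(-0.2, 6, 6)
  blocks[1:3, 1:3] <- 0.9
  blocks[4:6, 4:6] <- 0.9
  diag(blocks) <- 1
  rownames(blocks) <- colnames(blocks) <- paste0("R", 1:6)
  cl <- hierarchical_cluster(blocks, n_clusters = 2)
  expect_equal(length(unique(cl$assignment[1:3])), 1L)
  expect_equal(length(unique(cl$assignment[4:6])), 1L)
  expect_false(cl$assignment[1] == cl$assignment[4])
  # identity correlation, cut at n -> singletons
  idm <- diag(4)
  rownames(idm) <- colnames(idm) <- paste0("R", 1:4)
  expect_equal(hierarchical_cluster(idm, n_clusters = 4)$n_clusters, 4L)
  single <- matrix(1, 1, 1, dimnames = list("R1", "R1"))
  expect_equal(hierarchical_cluster(single)$n_clusters, 1L)
  asym <- blocks
  asym[1, 2] <- 0
  expect_error(hierarchical_cluster(asym, n_clusters = 2), "symmetric")
})

test_that("cluster penetrance proportional to starter AP reads as rostral", {
  subj <- paste0("s", 1:6)
  ap <- seq(-1.8, -0.8, length.out = 6)
  # region A fraction rises linearly with AP; B is the complement
  fa <- seq(0.2, 0.7, length.out = 6)
  tab <- data.frame(subject_id = rep(subj, each = 2),
                    region = rep(c("A", "B"), 6),
                    count = round(as.vector(rbind(fa, 1 - fa)) * 1000))
  starters <- data.frame(subject_id = subj, ap_level = ap, count = 50)
  corr <- connectivity_correlation_matrix(tab)
  cl <- hierarchical_cluster(corr, n_clusters = 2)
  rel <- cluster_starter_relationship(cl, tab, starters)
  a_cl <- cl$assignment[["A"]]
  expect_equal(abs(rel$r[rel$cluster == a_cl]), 1, tolerance = 1e-6)
  expect_equal(rel$direction[rel$cluster == a_cl], "rostral")
  expect_equal(rel$direction[rel$cluster != a_cl], "caudal")
  expect_error(cluster_starter_relationship(cl, tab[1:4, ], starters[1:2, ]),
               "insufficient")
})

test_that("in-plane permutation test rejects perfect coupling, keeps size", {
  co <- generate_tracing_cohort(
    topography_cohort_spec(inplane_r = 1, seed = 31))
  res <- inplane_correlation_test(co$sections, n_shuffle = 200, seed = 1)
  expect_true(all(res$per_subject$real_r > res$per_subject$shuffled_r))
  expect_lt(res$p, 0.05)
  # degenerate constant starter counts are excluded with a warning
  sec <- co$sections
  sec$starter_count[sec$subject_id == "s01"] <- 7
  expect_warning(res2 <- inplane_correlation_test(sec, n_shuffle = 50,
                                                  seed = 1),
                 "zero-variance")
  expect_equal(res2$excluded, "s01")
})

test_that("local-connectivity regressions recover planted slopes", {
  subj <- paste0("s", 1:6)
  starters <- data.frame(subject_id = rep(subj, 2),
                         subnucleus = rep(c("CeC", "CeL"), each = 6),
                         count = c(10, 20, 30, 40, 50, 60,
                                   35, 25, 45, 15, 55, 5))
  neigh <- data.frame(subject_id = subj, source = "SI",
                      count = 2 * starters$count[1:6])
  res <- local_connectivity_regression(neigh, starters)
  row <- res[res$source == "SI" & res$subnucleus == "CeC", ]
  expect_equal(row$slope, 2, tolerance = 1e-9)
  expect_lt(row$p, 1e-6)
  expect_true(row$ci_lo <= 2 && 2 <= row$ci_hi)
  expect_error(local_connectivity_regression(neigh[1:3, ], starters),
               "insufficient")
})

test_that("projection bias matches a hand OLS oracle", {
  prof <- data.frame(subject_id = "s1", ap_level = c(-1.8, -1.4, -1.0),
                     norm_fluor = c(0.2, 0.5, 0.6))
  # hand OLS: slope = cov/var = 0.2 / 0.16 / ... = 0.5 per 1 mm
  expect_equal(projection_bias(prof)$bias,
               stats::cov(prof$ap_level, prof$norm_fluor) /
                 stats::var(prof$ap_level), tolerance = 1e-12)
  expect_error(projection_bias(data.frame(subject_id = "s1",
                                          ap_level = -1.4,
                                          norm_fluor = 1)), "single AP")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5, tolerance = 1e-12)
  expect_equal(sidak_adjust(0.5, 10), 1 - 0.5^10)
  expect_equal(sidak_adjust(1, 3), 1)
})

test_that("projection target comparison finds only the shifted target", {
  identical_groups <- generate_projection_dataset(
    8, c(-1.6, -1.2), bias_slope = 0, noise_sd = 0,
    regions = c("SI", "LH", "BSTal"))
  res0 <- compare_projection_targets(identical_groups)
  expect_true(all(res0$per_target$p_adj == 1))
  shifted <- generate_projection_dataset(
    10, c(-1.6, -1.2), bias_slope = 0, noise_sd = 0.05,
    regions = c("SI", "LH", "BSTal"),
    group_shift = c(BSTal = 1), seed = 4)
  res1 <- compare_projection_targets(shifted)
  tgt <- res1$per_target
  expect_lt(tgt$p_adj[tgt$region == "BSTal"], 0.01)
  expect_true(all(tgt$p_adj[tgt$region != "BSTal"] > 0.05))
  expect_error(compare_projection_targets(
    identical_groups[identical_groups$subject_id %in% c("p01", "p02"), ]),
    "2 subjects")
})

test_that("incidence comparison reproduces the printed-count result", {
  res <- incidence_comparison(c(13, 20), c(1, 21))
  expect_lt(res$p_rank, 0.001)
  expect_lt(res$p_fisher, 0.001)
  same <- incidence_comparison(c(5, 10), c(10, 20))
  expect_equal(same$p_fisher, 1)
  expect_gt(same$p_rank, 0.9)
  # 20/20 vs 0/20: exact hypergeometric tail 2 / choose(40, 20)
  ext <- incidence_comparison(c(20, 20), c(0, 20))
  expect_equal(ext$p_fisher, 2 / choose(40, 20), tolerance = 1e-12)
  expect_error(incidence_comparison(c(5, 0), c(1, 2)), "group_a")
})
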