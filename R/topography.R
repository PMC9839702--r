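# per-subject fractions of total labelled cells, regions x subjects matrix
subject_fractions <- function(tables) {
  tables <- as.data.frame(tables)
  need <- c("subject_id", "region", "count")
  if (!all(need %in% names(tables)))
    stop("region count table must have columns ",
         paste(need, collapse = ", "))
  tot <- tapply(tables$count, tables$subject_id, sum)
  zero <- names(tot)[tot == 0]
  if (length(zero)) {
    warning("subject(s) with zero total labelled cells excluded: ",
            paste(zero, collapse = ", "))
    tables <- tables[!tables$subject_id %in% zero, , drop = FALSE]
  }
  cnt <- tapply(tables$count, list(tables$region, tables$subject_id), sum,
                default = 0)
  sweep(cnt, 2L, colSums(cnt), "/")
}

#' Filter regions by expression cutoff
#'
#' Retains a region iff its mean (across subjects) fraction of the subject's
#' total labelled cells strictly exceeds `cutoff_fraction` (default 0.5%, the
#' cutoff that keeps regions with more than ~5 cells on average). Subjects
#' with zero total cells are excluded from the mean with a warning.
#'
#' @param tables data.frame with columns `subject_id`, `region`, `count`
#'   (hemisphere counts, if present, are summed per region).
#' @param cutoff_fraction expression cutoff as a fraction (default 0.005).
#' @return character vector of retained region names (empty for empty input).
#' @export
filter_regions <- function(tables, cutoff_fraction = 0.005) {
  tables <- as.data.frame(tables)
  if (nrow(tables) == 0L) return(character())
  fr <- subject_fractions(tables)
  keep <- rowMeans(fr) > cutoff_fraction
  sort(rownames(fr)[keep])
}

#' Input-connectivity correlation matrix across subjects
#'
#' Converts per-subject counts to fractions of the subject's total labelled
#' cells (removing injection-efficiency scale) and returns the region x region
#' Pearson correlation matrix across subjects. Regions with zero variance
#' across subjects are excluded with a warning.
#'
#' @param tables data.frame `subject_id`, `region`, `count`.
#' @param regions regions to include (e.g. from [filter_regions()]); default
#'   all regions present.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
connectivity_correlation_matrix <- function(tables, regions = NULL) {
  fr <- subject_fractions(tables)
  if (!is.null(regions)) fr <- fr[rownames(fr) %in% regions, , drop = FALSE]
  if (ncol(fr) < 3L) stop("need >= 3 subjects to correlate regions")
  v <- apply(fr, 1L, stats::var)
  if (any(v == 0)) {
    warning("region(s) with zero variance across subjects excluded: ",
            paste(rownames(fr)[v == 0], collapse = ", "))
    fr <- fr[v > 0, , drop = FALSE]
  }
  stats::cor(t(fr))
}

#' Hierarchical clustering of a connectivity correlation matrix
#'
#' Agglomerative clustering on distance `1 - r` with average linkage;
#' deterministic given the input. Cut either into `n_clusters` groups or at
#' height `h`.
#'
#' @param corr symmetric correlation matrix (unit diagonal).
#' @param n_clusters number of clusters to cut into (optional).
#' @param h cut height on `1 - r` (optional; one of the two must be given
#'   unless the matrix has a single region).
#' @return list of class `cluster_assignment`: `assignment` (named integer),
#'   `tree` (an `hclust`), `n_clusters`.
#' @export
hierarchical_cluster <- function(corr, n_clusters = NULL, h = NULL) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || !isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("`corr` must be a symmetric correlation matrix")
  if (nrow(corr) == 1L) {
    asg <- stats::setNames(1L, rownames(corr))
    return(structure(list(assignment = asg, tree = NULL, n_clusters = 1L),
                     class = "cluster_assignment"))
  }
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  asg <- if (!is.null(n_clusters)) stats::cutree(tree, k = n_clusters)
         else if (!is.null(h)) stats::cutree(tree, h = h)
         else stop("give `n_clusters` or `h`")
  structure(list(assignment = asg, tree = tree,
                 n_clusters = length(unique(asg))),
            class = "cluster_assignment")
}

# count-weighted mean AP per subject from a starter-cell table
starter_ap_centroid <- function(starters) {
  sapply(split(starters, starters$subject_id), function(d)
    stats::weighted.mean(d$ap_level, d$count))
}

#' Relate cluster penetrance to starter-cell location
#'
#' For each cluster, the mean across member regions of the per-subject input
#' fraction is correlated with the subject's starter-cell AP centroid
#' (count-weighted mean AP). A positive correlation (penetrance rising toward
#' less-negative AP) is labelled `rostral`, negative `caudal`.
#'
#' @param clusters a `cluster_assignment` from [hierarchical_cluster()].
#' @param tables region count data.frame (`subject_id`, `region`, `count`).
#' @param starters starter-cell data.frame (`subject_id`, `ap_level`, `count`).
#' @return data.frame per cluster: `cluster`, `r`, `p`, `direction`,
#'   `n_subjects`; clusters with undefined correlation are flagged via
#'   `direction = "undefined"`.
#' @export
cluster_starter_relationship <- function(clusters, tables, starters) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  fr <- subject_fractions(tables)
  cen <- starter_ap_centroid(starters)
  common <- intersect(colnames(fr), names(cen))
  if (length(common) < 3L)
    stop("insufficient subjects: need >= 3 with both counts and starters")
  fr <- fr[, common, drop = FALSE]
  cen <- cen[common]
  if (stats::var(cen) == 0)
    stop("all subjects have the same starter AP centroid; undefined")
  out <- lapply(sort(unique(clusters$assignment)), function(cl) {
    members <- names(clusters$assignment)[clusters$assignment == cl]
    pen <- colMeans(fr[rownames(fr) %in% members, , drop = FALSE])
    if (stats::var(pen) == 0)
      return(data.frame(cluster = cl, r = NA_real_, p = NA_real_,
                        direction = "undefined", n_subjects = length(common)))
    ct <- stats::cor.test(pen, cen)
    data.frame(cluster = cl, r = unname(ct$estimate), p = ct$p.value,
               direction = if (ct$estimate > 0) "rostral" else "caudal",
               n_subjects = length(common))
  })
  do.call(rbind, out)
}

#' In-plane correlation test against an AP-shuffled null
#'
#' Per subject, the Pearson correlation between upstream input counts and
#' starter-cell counts across sections (real r), compared to the mean r under
#' permutation of the input counts across the subject's sections along the AP
#' axis (starter counts fixed). The paired statistic is a two-sided Wilcoxon
#' matched-pairs signed-rank test of real vs mean-shuffled r across subjects.
#'
#' @param sections data.frame `subject_id`, `ap`, `input_count`,
#'   `starter_count`, with >= 3 sections per subject.
#' @param n_shuffle permutations per subject (default 1000).
#' @param seed integer RNG seed.
#' @return list `per_subject` (data.frame `subject_id`, `real_r`,
#'   `shuffled_r`), `p` (paired two-sided signed-rank), `n_subjects`,
#'   `excluded` (zero-variance subjects).
#' @export
inplane_correlation_test <- function(sections, n_shuffle = 1000, seed = 1L) {
  by_subj <- split(sections, sections$subject_id)
  excluded <- character()
  rows <- list()
  withr::with_seed(seed, {
    for (sid in names(by_subj)) {
      d <- by_subj[[sid]]
      if (nrow(d) < 3L) stop("subject ", sid, " has < 3 sections")
      if (stats::var(d$input_count) == 0 || stats::var(d$starter_count) == 0) {
        excluded <- c(excluded, sid)
        next
      }
      real_r <- stats::cor(d$input_count, d$starter_count)
      shuf <- vapply(seq_len(n_shuffle), function(j)
        stats::cor(sample(d$input_count), d$starter_count), numeric(1L))
      rows[[sid]] <- data.frame(subject_id = sid, real_r = real_r,
                                shuffled_r = mean(shuf))
    }
  })
  if (length(excluded))
    warning("subject(s) with zero-variance counts excluded: ",
            paste(excluded, collapse = ", "))
  per_subject <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(per_subject) || nrow(per_subject) < 6L)
    stop("paired test needs >= 6 usable subjects")
  p <- signed_rank_p(per_subject$real_r - per_subject$shuffled_r)$p
  list(per_subject = per_subject, p = p, n_subjects = nrow(per_subject),
       excluded = excluded)
}

#' Local-connectivity regressions on starter-subnucleus composition
#'
#' For every (source structure, starter subnucleus) pair, a simple linear
#' regression across subjects of neighbouring retrogradely labelled cell
#' counts on the subject's starter-cell count in that subnucleus, with
#' two-sided slope p-value and 95% confidence interval.
#'
#' @param neighbor_counts data.frame `subject_id`, `source`, `count`.
#' @param starter_mix data.frame `subject_id`, `subnucleus`, `count`.
#' @return data.frame `source`, `subnucleus`, `slope`, `p`, `ci_lo`, `ci_hi`,
#'   `n_subjects`; zero-variance predictors are flagged with `NA` slope.
#' @export
local_connectivity_regression <- function(neighbor_counts, starter_mix) {
  subj <- intersect(unique(neighbor_counts$subject_id),
                    unique(starter_mix$subject_id))
  if (length(subj) < 4L) stop("insufficient subjects: need >= 4")
  out <- list()
  for (src in unique(neighbor_counts$source)) {
    yv <- neighbor_counts[neighbor_counts$source == src, ]
    y <- yv$count[match(subj, yv$subject_id)]
    for (sn in unique(starter_mix$subnucleus)) {
      xv <- starter_mix[starter_mix$subnucleus == sn, ]
      x <- xv$count[match(subj, xv$subject_id)]
      if (stats::var(x) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          source = src, subnucleus = sn, slope = NA_real_, p = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, n_subjects = length(subj))
        next
      }
      m <- stats::lm(y ~ x)
      sm <- summary(m)$coefficients
      ci <- stats::confint(m)["x", ]
      out[[length(out) + 1L]] <- data.frame(
        source = src, subnucleus = sn, slope = sm["x", "Estimate"],
        p = sm["x", "Pr(>|t|)"], ci_lo = ci[[1L]], ci_hi = ci[[2L]],
        n_subjects = length(subj))
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-subject projection bias across AP levels
#'
#' The bias is the OLS slope of normalized fluorescence against AP level for
#' each subject (1/mm): -1 indicates a strong rostral bias, +1 caudal.
#'
#' @param proj data.frame `subject_id`, `ap_level`, `norm_fluor` (e.g. from
#'   [generate_projection_dataset()]); each subject needs >= 2 AP levels.
#' @return data.frame `subject_id`, `bias`.
#' @export
projection_bias <- function(proj) {
  by_subj <- split(proj, proj$subject_id)
  bias <- vapply(by_subj, function(d) {
    if (length(unique(d$ap_level)) < 2L)
      stop("subject ", d$subject_id[1L],
           " has a single AP level; bias undefined")
    unname(stats::coef(stats::lm(norm_fluor ~ ap_level, data = d))[2L])
  }, numeric(1L))
  data.frame(subject_id = names(by_subj), bias = unname(bias))
}

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p raw p-value(s); @param m number of comparisons.
#' @return adjusted p-value(s), capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Compare projection targets between injection groups
#'
#' Two-way (group x target region) ANOVA on normalized fluorescence, followed
#' by per-target rostral-vs-caudal contrasts using the pooled residual mean
#' square, Sidak-adjusted across targets.
#'
#' @param proj data.frame `subject_id`, `region`, `norm_fluor`, `group`
#'   (levels `rostral` / `caudal`), >= 2 subjects per group.
#' @return list `anova` (the `aov` summary), `per_target` (data.frame
#'   `region`, `diff` (rostral - caudal), `t`, `df`, `p_raw`, `p_adj`).
#' @export
compare_projection_targets <- function(proj) {
  proj <- as.data.frame(proj)
  if (length(unique(proj$subject_id[proj$group == "rostral"])) < 2L ||
      length(unique(proj$subject_id[proj$group == "caudal"])) < 2L)
    stop("need >= 2 subjects per group")
  # average over AP levels so each (subject, region) contributes one value
  agg <- stats::aggregate(norm_fluor ~ subject_id + region + group, proj, mean)
  agg$group <- factor(agg$group, levels = c("rostral", "caudal"))
  agg$region <- factor(agg$region)
  fit <- stats::aov(norm_fluor ~ group * region, data = agg)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  m <- nlevels(agg$region)
  rows <- lapply(levels(agg$region), function(rg) {
    a <- agg$norm_fluor[agg$region == rg & agg$group == "rostral"]
    b <- agg$norm_fluor[agg$region == rg & agg$group == "caudal"]
    d <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    tstat <- if (se == 0) 0 else d / se
    df <- stats::df.residual(fit)
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    data.frame(region = rg, diff = d, t = tstat, df = df, p_raw = p,
               p_adj = sidak_adjust(p, m))
  })
  list(anova = summary(fit), per_target = do.call(rbind, rows))
}

#' Compare connectivity incidence between two groups
#'
#' On responder counts (e.g. neurons inhibited during photostimulation), a
#' two-sided Mann-Whitney test on the binary outcomes (with tie correction)
#' plus Fisher's exact test as a cross-check.
#'
#' @param group_a,group_b length-2 integer vectors `c(responders, n)`.
#' @return list `p_rank` (Mann-Whitney), `p_fisher`, `prop_a`, `prop_b`.
#' @export
incidence_comparison <- function(group_a, group_b) {
  check <- function(g, nm) {
    if (length(g) != 2L || g[2L] < 1 || g[1L] < 0 || g[1L] > g[2L])
      stop("`", nm, "` must be c(responders, n) with 0 <= responders <= n, n >= 1")
  }
  check(group_a, "group_a"); check(group_b, "group_b")
  xa <- c(rep(1, group_a[1L]), rep(0, group_a[2L] - group_a[1L]))
  xb <- c(rep(1, group_b[1L]), rep(0, group_b[2L] - group_b[1L]))
  p_rank <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided", correct = TRUE)$p.value)
  tab <- matrix(c(group_a[1L], group_a[2L] - group_a[1L],
                  group_b[1L], group_b[2L] - group_b[1L]), nrow = 2L)
  p_fisher <- stats::fisher.test(tab)$p.value
  list(p_rank = p_rank, p_fisher = p_fisher,
       prop_a = group_a[1L] / group_a[2L], prop_b = group_b[1L] / group_b[2L])
}
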