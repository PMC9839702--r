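#' Specification for a synthetic tracing cohort
#'
#' Defines a cohort of retrograde-tracing subjects with planted topography:
#' per-subject brain-region input counts in which designated region clusters
#' co-vary with the subject's starter-cell anterior-posterior (AP) centroid in
#' a planted direction, plus per-section paired (input, starter) counts with a
#' target in-plane Pearson correlation.
#'
#' Counts are Poisson around a log-linear mean in the standardized starter-AP
#' centroid; section-wise coupling uses a shared Poisson component so the
#' expected per-subject Pearson r equals `inplane_r` (supported on `[0, 1]`).
#'
#' @param n_subjects number of subjects (default 12).
#' @param n_regions number of upstream regions, named `R01 ...`.
#' @param cluster_plan list of `list(regions =, direction =, coupling =)`:
#'   disjoint region-name sets, direction `"rostral"` (counts rise toward
#'   less-negative AP) or `"caudal"`, coupling strength in `[0, 1]`.
#' @param ap_range length-2 AP range (mm from bregma, negative = posterior).
#' @param n_sections sections per subject for the in-plane series.
#' @param inplane_r target per-subject section-wise Pearson r, in `[0, 1]`.
#' @param count_scale mean regional cell count scale (cells).
#' @param section_scale mean per-section cell count (cells).
#' @param count_noise `"poisson"` (default) or `"none"` (deterministic rounded
#'   means; meaningful for `inplane_r` of 0 or 1 and noiseless recovery checks).
#' @param seed integer RNG seed.
#' @return a validated list of class `topography_cohort_spec`.
#' @export
topography_cohort_spec <- function(n_subjects = 12, n_regions = 20,
                                   cluster_plan = list(),
                                   ap_range = c(-2.0, -0.7),
                                   n_sections = 10, inplane_r = 0.6,
                                   count_scale = 100, section_scale = 20,
                                   count_noise = c("poisson", "none"),
                                   seed = 1L) {
  count_noise <- match.arg(count_noise)
  if (n_subjects < 2) stop("invalid spec: need >= 2 subjects")
  regions <- sprintf("R%02d", seq_len(n_regions))
  seen <- character()
  for (cl in cluster_plan) {
    if (!all(c("regions", "direction", "coupling") %in% names(cl)))
      stop("invalid spec: each cluster needs regions, direction, coupling")
    if (!cl$direction %in% c("rostral", "caudal"))
      stop("invalid spec: direction must be 'rostral' or 'caudal'")
    if (cl$coupling < 0 || cl$coupling > 1)
      stop("invalid spec: coupling strength must lie in [0, 1]")
    if (!all(cl$regions %in% regions))
      stop("invalid spec: cluster regions must be among ",
           paste(utils::head(regions, 3), collapse = ", "), ", ...")
    if (any(cl$regions %in% seen))
      stop("invalid spec: cluster region sets must be disjoint")
    seen <- c(seen, cl$regions)
  }
  if (inplane_r < 0 || inplane_r > 1)
    stop("invalid spec: `inplane_r` must lie in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         regions = regions, cluster_plan = cluster_plan,
         ap_range = sort(as.numeric(ap_range)),
         n_sections = as.integer(n_sections), inplane_r = inplane_r,
         count_scale = count_scale, section_scale = section_scale,
         count_noise = count_noise, seed = as.integer(seed)),
    class = "topography_cohort_spec")
}

rpois_or_round <- function(n, lambda, noise) {
  if (noise == "poisson") stats::rpois(n, lambda) else round(lambda)
}

#' Generate a synthetic retrograde-tracing cohort
#'
#' Subjects receive alternating rostral/caudal injection targets inside
#' `ap_range`; starter cells are spread over discrete AP levels and the CeC /
#' CeL / CeM subnuclei around each target. Regional input counts are Poisson
#' around `count_scale * base_r * exp(coupling * s * z)` where `z` is the
#' standardized starter-AP centroid and `s` is +1 for rostral-coupled
#' clusters, -1 for caudal. Section series pair input and starter counts with
#' expected Pearson r equal to the spec's `inplane_r` via a shared Poisson
#' component.
#'
#' @param spec a [topography_cohort_spec()].
#' @return list with `region_counts` (data.frame `subject_id`, `region`,
#'   `hemisphere`, `count`), `starters` (data.frame `subject_id`, `ap_level`,
#'   `subnucleus`, `count`), `sections` (data.frame `subject_id`, `ap`,
#'   `input_count`, `starter_count`) and `truth` (planted centroids and
#'   cluster plan).
#' @export
generate_tracing_cohort <- function(spec) {
  stopifnot(inherits(spec, "topography_cohort_spec"))
  ns <- spec$n_subjects
  subj <- sprintf("s%02d", seq_len(ns))
  # alternate rostral / caudal injection targets at ~80/20% of the AP range
  targets <- rep(stats::quantile(spec$ap_range, c(0.8, 0.2), names = FALSE),
                 length.out = ns)
  withr::with_seed(spec$seed, {
    centroids <- pmin(pmax(targets + stats::rnorm(ns, 0, 0.12),
                           spec$ap_range[1L]), spec$ap_range[2L])
    z <- as.numeric(scale(centroids))

    # starter-cell tables: 5 AP levels x 3 subnuclei around each centroid
    starters <- do.call(rbind, lapply(seq_len(ns), function(i) {
      ap_levels <- centroids[i] + seq(-0.28, 0.28, by = 0.14)
      w_ap <- stats::dnorm(ap_levels, centroids[i], 0.18)
      w <- as.vector(outer(w_ap / sum(w_ap), c(CeC = 0.3, CeL = 0.4, CeM = 0.3)))
      cnt <- as.vector(stats::rmultinom(1L, 60L, w))
      data.frame(subject_id = subj[i],
                 ap_level = rep(round(ap_levels, 2), times = 3L),
                 subnucleus = rep(c("CeC", "CeL", "CeM"), each = 5L),
                 count = cnt)
    }))

    # regional input counts, log-linear in the starter-AP centroid
    base_r <- stats::setNames(exp(stats::rnorm(spec$n_regions, 0, 0.5)),
                              spec$regions)
    dir_sign <- stats::setNames(numeric(spec$n_regions), spec$regions)
    for (cl in spec$cluster_plan)
      dir_sign[cl$regions] <-
        cl$coupling * ifelse(cl$direction == "rostral", 1, -1)
    region_counts <- do.call(rbind, lapply(seq_len(ns), function(i) {
      mu <- spec$count_scale * base_r * exp(dir_sign * z[i])
      total <- rpois_or_round(spec$n_regions, mu, spec$count_noise)
      ipsi <- if (spec$count_noise == "poisson")
        stats::rbinom(spec$n_regions, total, 0.85) else round(0.85 * total)
      data.frame(subject_id = subj[i],
                 region = rep(spec$regions, 2L),
                 hemisphere = rep(c("ipsi", "contra"), each = spec$n_regions),
                 count = c(ipsi, total - ipsi))
    }))

    # per-section paired counts: shared-component Poisson coupling
    r <- spec$inplane_r
    sections <- do.call(rbind, lapply(seq_len(ns), function(i) {
      ap <- round(centroids[i] + seq(-0.3, 0.3, length.out = spec$n_sections), 3)
      if (spec$count_noise == "none") {
        lam <- spec$section_scale * (0.5 + seq_len(spec$n_sections) / spec$n_sections)
        starter <- round(lam)
        input <- if (r == 1) starter else round(r * (lam - mean(lam)) + mean(lam))
      } else {
        lam <- spec$section_scale
        common <- stats::rpois(spec$n_sections, r * lam)
        starter <- common + stats::rpois(spec$n_sections, (1 - r) * lam)
        input <- common + stats::rpois(spec$n_sections, (1 - r) * lam)
      }
      data.frame(subject_id = subj[i], ap = ap,
                 input_count = input, starter_count = starter)
    }))
  })
  list(region_counts = region_counts, starters = starters, sections = sections,
       truth = list(subject_id = subj, ap_centroid = centroids,
                    cluster_plan = spec$cluster_plan))
}

#' Generate a synthetic anterograde projection dataset
#'
#' Per subject and region, normalized fluorescence across AP levels with a
#' planted linear AP trend of slope `bias_slope` (1/mm) about a unit baseline,
#' plus optional Gaussian noise. Subjects alternate between `rostral` and
#' `caudal` injection groups; `group_shift` adds a per-region offset for the
#' caudal group (for planted between-group target differences).
#'
#' @param n_subjects number of subjects.
#' @param ap_levels numeric vector of at least two AP levels (mm).
#' @param bias_slope planted slope of fluorescence vs AP (1/mm).
#' @param noise_sd sd of additive Gaussian noise (default 0, exact recovery).
#' @param regions character vector of target regions.
#' @param group_shift named numeric, added to caudal-group values per region.
#' @param seed integer RNG seed.
#' @return data.frame `subject_id`, `region`, `ap_level`, `norm_fluor`,
#'   `group`, of class `projection_table`.
#' @export
generate_projection_dataset <- function(n_subjects, ap_levels, bias_slope,
                                        noise_sd = 0, regions = "injection_site",
                                        group_shift = NULL, seed = 1L) {
  if (length(ap_levels) < 2L)
    stop("need >= 2 AP levels: projection bias is undefined for a single level")
  subj <- sprintf("p%02d", seq_len(n_subjects))
  group <- rep(c("rostral", "caudal"), length.out = n_subjects)
  grid <- expand.grid(subject_id = subj, region = regions,
                      ap_level = as.numeric(ap_levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- group[match(grid$subject_id, subj)]
  base <- 1 + bias_slope * (grid$ap_level - mean(ap_levels))
  if (!is.null(group_shift)) {
    sh <- group_shift[grid$region]
    sh[is.na(sh)] <- 0
    base <- base + ifelse(grid$group == "caudal", sh, 0)
  }
  withr::with_seed(seed, {
    noise <- if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  })
  grid$norm_fluor <- pmax(0, base + noise)
  class(grid) <- c("projection_table", "data.frame")
  grid
}
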