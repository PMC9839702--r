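#' Ordinary least-squares linear tuning fit
#'
#' Fits `y = intercept + slope * t` with a two-sided p-value for slope != 0.
#' Residual standard error is `sqrt(SSE / (n - 2))`. A constant `y` is treated
#' as the degenerate fit: slope 0, `r2` defined as 0, p = 1, se = 0.
#'
#' @param t time points (s); must not be constant.
#' @param y response values (dimensionless, e.g. dF/F).
#' @return object of class `linear_fit`: `slope`, `intercept`, `r2`, `p`,
#'   `se`, `n`, `sse`.
#' @export
fit_linear <- function(t, y) {
  if (length(t) != length(y)) stop("`t` and `y` must have equal length")
  n <- length(y)
  if (n < 3L) stop("need >= 3 points")
  if (stats::var(t) == 0) stop("singular design: `t` is constant")
  if (stats::var(y) == 0) {
    fit <- list(slope = 0, intercept = mean(y), r2 = 0, p = 1, se = 0,
                n = n, sse = 0)
    class(fit) <- "linear_fit"
    return(fit)
  }
  slope <- stats::cov(t, y) / stats::var(t)
  intercept <- mean(y) - slope * mean(t)
  res <- y - intercept - slope * t
  sse <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  se_slope <- sqrt(sse / (n - 2)) / sqrt(stats::var(t) * (n - 1))
  tstat <- slope / se_slope
  structure(
    list(slope = slope, intercept = intercept, r2 = 1 - sse / tss,
         p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
         se = sqrt(sse / (n - 2)), n = n, sse = sse),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: slope %.4g, intercept %.4g, R2 %.3f, p %.3g, se %.4g\n",
              x$slope, x$intercept, x$r2, x$p, x$se))
  invisible(x)
}

#' Sigmoid tuning fit
#'
#' Least-squares fit of the saturating model
#' `y(x) = c / (1 + exp(-k (x - x0))) + y0` by Levenberg-Marquardt
#' (minpack.lm), with a multi-start grid over `k` and `x0` plus a
#' linear-tangent start (small `k`, `c` scaled so the curve's central slope
#' matches the OLS line) so a pure line is fit at least as well as by the
#' linear model. Bounds: `k > 0`, `x0` within the time window +/- 30 s,
#' `c` and `y0` free. The degenerate constant fit (c = 0, y0 = mean) is always
#' a candidate, so `r2` lies in [0, 1].
#'
#' @param t time points (s), >= 5 of them.
#' @param y response values.
#' @param k_grid multi-start grid for the rate parameter (1/s).
#' @return object of class `sigmoid_fit`: `c`, `k`, `x0`, `y0`, `r2`, `se`
#'   (`sqrt(SSE / (n - 4))`), `converged`, `n`, `sse`.
#' @export
fit_sigmoid <- function(t, y, k_grid = c(0.02, 0.1, 0.5)) {
  if (length(t) != length(y)) stop("`t` and `y` must have equal length")
  n <- length(y)
  if (n < 5L) stop("need >= 5 points")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    fit <- list(c = 0, k = min(k_grid), x0 = mean(range(t)), y0 = mean(y),
                r2 = 0, se = 0, converged = TRUE, n = n, sse = 0)
    class(fit) <- "sigmoid_fit"
    return(fit)
  }
  rng <- range(t)
  span <- diff(rng)
  lower <- c(c = -Inf, k = 1e-6, x0 = rng[1L] - 30, y0 = -Inf)
  upper <- c(c = Inf, k = Inf, x0 = rng[2L] + 30, y0 = Inf)
  sse_at <- function(p) {
    r <- y - sigmoid_curve(t, p[["c"]], p[["k"]], p[["x0"]], p[["y0"]])
    sum(r * r)
  }
  # candidate starts: grid over (k, x0) at data-driven amplitude, plus the
  # linear-tangent start matching the OLS slope at the window midpoint
  x0_cands <- unique(c(stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE),
                       mean(rng)))
  amp <- max(y) - min(y)
  starts <- list()
  for (k in unique(c(k_grid, 4 / span)))
    for (x0 in x0_cands)
      starts[[length(starts) + 1L]] <-
        c(c = amp, k = k, x0 = x0, y0 = min(y))
  ols <- fit_linear(t, y)
  for (k_lin in c(2 / span, 0.1 / span))  # the second is the near-linear limit
    starts[[length(starts) + 1L]] <-
      c(c = 4 * ols$slope / k_lin, k = k_lin, x0 = mean(rng),
        y0 = ols$intercept + ols$slope * mean(rng) - 2 * ols$slope / k_lin)
  # screen starts by SSE; refine the best few plus the linear-tangent start
  resid_fn <- function(p)
    y - sigmoid_curve(t, p[1L], p[2L], p[3L], p[4L])
  sse0 <- vapply(starts, sse_at, numeric(1L))
  refine <- unique(c(utils::head(order(sse0), 3L),
                     length(starts) - 1L, length(starts)))
  best <- NULL
  for (i in refine) {
    st <- unname(starts[[i]])
    st[3L] <- min(max(st[3L], lower[["x0"]]), upper[["x0"]])
    st[2L] <- max(st[2L], lower[["k"]])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = unname(lower), upper = unname(upper),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$sse)
      best <- list(p = c(cc = fit$par[1L], k = fit$par[2L],
                         x0 = fit$par[3L], y0 = fit$par[4L]),
                   sse = fit$deviance, converged = fit$info %in% 1:3)
  }
  # analytic linear-limit candidate: at the k lower bound the sigmoid equals
  # the OLS line to machine precision, so the sigmoid never fits worse than
  # the linear model (LM can stall on the flat large-c / small-k ridge)
  k0 <- lower[["k"]]
  lin_limit <- c(cc = 4 * ols$slope / k0, k = k0, x0 = mean(rng),
                 y0 = ols$intercept + ols$slope * mean(rng) -
                   2 * ols$slope / k0)
  lin_sse <- sse_at(c(c = lin_limit[["cc"]], k = lin_limit[["k"]],
                      x0 = lin_limit[["x0"]], y0 = lin_limit[["y0"]]))
  if (is.null(best) || lin_sse < best$sse)
    best <- list(p = lin_limit, sse = lin_sse, converged = TRUE)
  const_sse <- tss  # degenerate constant model, always available
  if (is.null(best) || best$sse > const_sse) {
    structure(list(c = 0, k = min(k_grid), x0 = mean(rng), y0 = mean(y),
                   r2 = 0, se = sqrt(const_sse / (n - 4)),
                   converged = FALSE, n = n, sse = const_sse),
              class = "sigmoid_fit")
  } else {
    structure(list(c = unname(best$p[["cc"]]), k = unname(best$p[["k"]]),
                   x0 = unname(best$p[["x0"]]), y0 = unname(best$p[["y0"]]),
                   r2 = 1 - best$sse / tss, se = sqrt(best$sse / (n - 4)),
                   converged = isTRUE(best$converged), n = n, sse = best$sse),
              class = "sigmoid_fit")
  }
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid fit: c %.4g, k %.4g 1/s, x0 %.4g s, y0 %.4g; R2 %.3f, se %.4g%s\n",
    x$c, x$k, x$x0, x$y0, x$r2, x$se,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Compare linear and sigmoid fits of the same data
#'
#' `delta_r2 = r2_sigmoid - r2_linear`; `delta_se = se_linear - se_sigmoid`,
#' the change in residual standard error when switching from the linear to
#' the nonlinear fit (positive favours the sigmoid).
#'
#' @param lin a `linear_fit`; @param sig a `sigmoid_fit`, both on the same data.
#' @return list `delta_r2`, `delta_se`.
#' @export
compare_models <- function(lin, sig) {
  stopifnot(inherits(lin, "linear_fit"), inherits(sig, "sigmoid_fit"))
  if (lin$n != sig$n)
    stop("fits were made on different numbers of points")
  list(delta_r2 = sig$r2 - lin$r2, delta_se = lin$se - sig$se)
}

#' Bootstrap distribution of a population fit statistic
#'
#' Resamples neurons with replacement and records the population mean of the
#' per-neuron statistic per resample (10000 resamples by default), for the
#' best-fit slope, R-squared, sigmoid k, or change in standard error.
#'
#' @param per_neuron_values numeric vector, one value per neuron.
#' @param statistic one of `"slope"`, `"r2"`, `"k"`, `"delta_se"`.
#' @param n_boot number of resamples (default 10000).
#' @param seed integer RNG seed.
#' @return object of class `bootstrap_distribution`: `statistic`, `samples`,
#'   `mean`, `sd`, `n_boot`, `n_neurons`, `seed`.
#' @export
bootstrap_population_stat <- function(per_neuron_values,
                                      statistic = c("slope", "r2", "k",
                                                    "delta_se"),
                                      n_boot = 10000, seed = 1L) {
  statistic <- match.arg(statistic)
  v <- per_neuron_values[is.finite(per_neuron_values)]
  if (length(v) < 2L) stop("need >= 2 neurons with finite values")
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  withr::with_seed(seed, {
    samples <- colMeans(matrix(sample(v, length(v) * n_boot, replace = TRUE),
                               length(v), n_boot))
  })
  structure(list(statistic = statistic, samples = samples,
                 mean = mean(samples), sd = stats::sd(samples),
                 n_boot = as.integer(n_boot), n_neurons = length(v),
                 seed = as.integer(seed)),
            class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("bootstrap of %s: mean %.4g, sd %.4g (%d neurons, %d resamples)\n",
              x$statistic, x$mean, x$sd, x$n_neurons, x$n_boot))
  invisible(x)
}

#' Compare two bootstrap distributions of a population statistic
#'
#' Student's two-sided unpaired t-test on the two bootstrap sample sets (the
#' procedure used to compare population goodness-of-fit distributions). Note
#' this inherits non-standard calibration from the bootstrap sample size; a
#' percentile CI on the index-paired difference of the two sample sets is
#' reported alongside as a labelled extension.
#'
#' @param a,b `bootstrap_distribution` objects with the same statistic and
#'   `n_boot`.
#' @return list `t`, `p`, `diff_ci95` (percentile interval of `a - b`,
#'   extension).
#' @export
compare_population_fits <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_distribution"),
            inherits(b, "bootstrap_distribution"))
  if (a$statistic != b$statistic)
    stop("distributions summarise different statistics")
  if (a$n_boot != b$n_boot)
    stop("distributions have different n_boot")
  if (stats::sd(a$samples) == 0 && stats::sd(b$samples) == 0) {
    tt <- list(statistic = c(t = 0),
               p.value = if (a$mean == b$mean) 1 else 0)
  } else {
    tt <- stats::t.test(a$samples, b$samples, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       diff_ci95 = unname(stats::quantile(a$samples - b$samples,
                                          c(0.025, 0.975))))
}
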