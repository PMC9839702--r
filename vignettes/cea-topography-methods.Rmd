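---
title: "Methods: peri-event calcium statistics and circuit topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event calcium statistics and circuit topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatopo)
```

## What the package models

Neuron populations in the central amygdala (CeA) are organised along the
rostro-caudal (anterior-posterior, AP) axis: rostral and caudal
subpopulations receive different upstream inputs, send different projections,
and respond differently to noxious and learned stimuli. `ceatopo` implements
the quantitative machinery needed to characterise such topography from two
kinds of data:

* **single-cell calcium traces** (neurons x frames, 6 frames/s by
  convention) with event schedules (stimulus onsets/offsets, freezing
  bouts), and
* **tracing tables**: per-subject retrogradely labelled cell counts by
  brain region, starter-cell AP/subnucleus distributions, per-section
  paired counts, and anterograde fluorescence by AP level.

Because raw recordings of this kind are rarely deposited, the package ships
seeded synthetic-data generators with planted ground truth; every analysis
stage is validated end-to-end against what was planted.

## Trace normalisation

Two normalisations are exposed, and callers choose per analysis:

* **dF/F** for across-time comparisons: $(F - \bar F)/\bar F$ with $\bar F$
  the mean over the *entire* recording. It is exactly zero for a constant
  trace and invariant to multiplicative rescaling.
* **Peri-event z-score** for event-locked comparisons:
  $(F - \mu)/\sigma$ with moments taken over the union of a designated
  baseline period and the event's pre-stimulus window. We use the sample
  (n−1) standard deviation; this choice is documented so that hand oracles
  match exactly. The result is invariant to positive affine transforms of
  the raw fluorescence.

Windows are half-open `[start, end)` so a w-second window at rate r always
contains exactly `round(w * r)` frames. When slicing peri-event tensors,
event onset maps to the first frame at or after the onset time and the
window includes the onset frame: a 10 s / 10 s window at 6 frames/s yields
121 aligned frames. Peri-stimulus window defaults are 10 s before/after CS
and US and 5 s before/after freezing bouts.

## Response classification

A neuron is called excited or inhibited for a stimulus when **either** of
two sub-criteria fires (both outcomes are stored for audit):

1. **Signed-rank**: a two-sided Wilcoxon signed-rank test of response-window
   frames against baseline-window frames of the event-averaged snippet, at
   α = 0.05, with the direction given by the median shift. When the windows
   have equal frame counts the test is paired frame-by-frame; otherwise it
   is a one-sample test against the baseline mean. Zero differences are
   dropped (the Wilcoxon convention); the implementation delegates to
   `stats::wilcox.test`, which is exact for small samples without ties and
   uses the tie/continuity-corrected normal approximation otherwise.
2. **Normalized AUC**: trapezoidal area under the curve per unit time in
   each window; the response fires when its per-second AUC exceeds twice
   the *absolute* baseline per-second AUC (the `|2x|` rule), with the
   symmetric rule for inhibition.

Two properties of this scheme are worth knowing. First, the signed-rank
sub-criterion alone is calibrated: on null data its one-direction rate is
α/2. Second, the AUC sub-criterion is *not* calibrated on z-scored input,
because z-scoring makes the baseline AUC nearly zero, so the `|2x|`
threshold is easy to exceed; the combined OR-criterion therefore has a high
false-positive rate on pure noise (reported by the acceptance script as
`null_excited_rate_combined`). This is a property of the criterion as
defined, not of the implementation; analyses that need calibrated error
rates should use the signed-rank sub-call (`sr_call`), which is also what
the calibration test constrains. Negating every trace swaps
excited/inhibited labels exactly.

Further classifiers follow the same conventions: blockwise classification
compares each recording block to a baseline block and ORs excitation over
blocks; monotonic-increase detection is a one-sided OLS slope test on a
0-60 s post-contact window; learning modulation across trials combines a
per-trial slope regression with a first-vs-last signed-rank comparison;
trial cross-correlation is the zero-lag Pearson r between aligned snippets
(the conservative reading of "cross-correlated activity"); latency is the
first run of at least two consecutive frames exceeding the baseline mean by
2 baseline sds (the paper-style latency sort leaves the definition open, so
it is fixed here and parameterised). Population proportions carry a
neuron-level bootstrap (resampling neurons with replacement) for bars and
error.

## Tuning fits and model comparison

Stimulus-period activity (dF/F on t = 0-60 s from first contact) is fit by

* an OLS line (slope, intercept, $R^2$, two-sided slope p), and
* a sigmoid $y(x) = c/(1+e^{-k(x-x_0)}) + y_0$, fit by Levenberg-Marquardt
  least squares.

Sigmoid fitting uses a multi-start strategy: a data-driven primary start
(`c = range(y)`, `y0 = min(y)`, `x0` = window midpoint, `k = 4/span`), a
grid over `k` in {0.02, 0.1, 0.5} 1/s and `x0` at the time quartiles, and a
linear-tangent start whose central slope matches the OLS line. Starts are
screened by their initial SSE and the best few refined. Bounds keep
`k > 0` and `x0` within the window ± 30 s, which removes the
mirror-symmetric duplicate optimum at (−c, −k). Two deterministic fallback
candidates are always evaluated analytically: the constant fit
(`c = 0, y0 = mean`), which guarantees $R^2 \in [0, 1]$, and the
linear-limit sigmoid at the `k` lower bound, which equals the OLS line to
machine precision and guarantees the sigmoid never fits worse than the
line (the optimizer can stall on the flat large-`c`/small-`k` ridge).

Residual standard error is $\sqrt{SSE/(n-p)}$ with $p$ = 2 (line) or 4
(sigmoid). Model comparison reports `delta_r2 = r2_sig - r2_lin` and
`delta_se = se_lin - se_sig` (positive favours the sigmoid). Population
statistics (slope, $R^2$, `k`, `delta_se`) are bootstrapped by resampling
*neurons* with replacement, 10000 resamples by default, and two populations
are compared with Student's two-sided unpaired t-test on the bootstrap
sample sets. That t-test inherits its degrees of freedom from the number of
bootstrap resamples and is therefore anticonservative by construction; the
comparison additionally reports a percentile interval of the index-paired
difference of the two bootstrap sample sets, clearly an extension, for a
more honest uncertainty statement.

**Known limitation.** Deciding "sigmoid-like vs linear" per neuron by the
sign of `delta_se` is intrinsically ambiguous for near-linear responses:
on an exactly linear response the sigmoid's two extra parameters absorb
roughly $2\sigma^2$ of residual noise in expectation, which is the same
size as the $n-p$ penalty in `delta_se`, so the sign on true-line neurons
is close to a coin flip biased only mildly toward the line (about 3:1 in
our synthetic checks, independent of the noise level and of the optimizer
start strategy). Saturating responses are classified essentially perfectly,
so the per-neuron discrimination accuracy on an equal mixture plateaus
around the high 80s of percent. The population-level bootstrap comparison
separates the same two populations at vanishing p-values; per-neuron sign
calls on weakly curved responses should be treated with caution.

## Tracing topography statistics

* **Expression cutoff**: a region is retained iff its mean across-subject
  fraction of the subject's total labelled cells strictly exceeds 0.5%
  (strict `>`, so a region at exactly 0.5% in every subject is dropped);
  zero-total subjects are excluded from the mean with a warning.
* **Connectivity correlations** are computed on per-subject *fractions*
  (removing injection-efficiency scale, which the raw counts confound),
  then clustered agglomeratively on distance `1 - r` with average linkage.
  The cut (cluster count or height) is a parameter: no principled universal
  choice exists, and published cluster counts depend on it.
* **Starter-location relationships**: each subject's starter distribution
  is summarised by its count-weighted mean AP (centroid); per cluster the
  mean member-region fraction is correlated with the centroid across
  subjects. AP is in mm relative to bregma with negative = posterior, so a
  positive correlation means penetrance rises rostrally and the cluster is
  labelled `rostral`.
* **In-plane permutation test**: per subject, Pearson r between input
  counts and starter counts across sections; the null permutes the input
  counts across that subject's sections along the AP axis (starter counts
  fixed), 1000 shuffles by default, and the paired statistic is a
  two-sided Wilcoxon matched-pairs signed-rank test of real vs
  mean-shuffled r across subjects (per-subject pairing; per-section
  variants can be built from the same pieces). At least 6 subjects are
  required for the paired test to have any rejection region.
* **Local-connectivity regressions** are simple per-pair OLS fits of
  neighbouring labelled-cell counts on starter-subnucleus counts with 95%
  CIs; **projection bias** is the per-subject OLS slope of
  injection-normalized fluorescence across AP levels (−1 = strong rostral
  bias); target-region group differences use a two-way (group x region)
  ANOVA with per-region contrasts on the pooled residual mean square,
  Sidak-adjusted (`1 - (1-p)^m`); **incidence comparisons** of responder
  counts use a tie-corrected Mann-Whitney test on the 0/1 outcomes plus
  Fisher's exact test as a cross-check.

## The synthetic-data generators

The generators define the study conditions the tests exercise.

* **Traces**: constant baseline plus event-locked class templates -
  `null`, `transient` (instantaneous rise, exponential decay, τ = 1 s
  default), `linear_ramp` (default 0.02 a.u./s), and `sigmoid` (default
  c = 1, k = 0.2 1/s, x0 = 30 s, y0 = 0) - with additive i.i.d. Gaussian
  noise. Noise is the simplest model sufficient for type-I-error and
  recovery testing; no amplitude statistics for real traces are published
  to fit against, so the defaults are stated, not fitted. Class counts
  follow the responder mix by largest-remainder rounding (deterministic,
  sums exactly); assignment order is shuffled under the seed.
* **Tracing cohorts** (12 subjects by default, alternating rostral/caudal
  injection targets): regional counts are Poisson around a log-linear mean
  in the standardized starter-AP centroid, `scale * base_r *
  exp(coupling * s * z)`, giving non-negative integers with controllable
  coupling; per-section pairs use a shared-Poisson-component construction
  (`X = C + E1`, `Y = C + E2`) whose expected Pearson r equals the target,
  exactly 1 when the shared component is everything. Negative target
  in-plane correlations are not supported by this construction and are
  rejected; the motivating use case is positive. A `count_noise = "none"`
  mode replaces Poisson draws with rounded means for noiseless
  exact-recovery checks (meaningful at in-plane r of 0 or 1).
* **Projections**: per subject and AP level, normalized fluorescence about
  a unit baseline with a planted linear AP slope; with zero noise the
  planted bias is recovered exactly.

What the generators do **not** emulate: slow drift and photobleaching,
correlated (shared-source) noise across neurons, spike-to-fluorescence
kinetics, atlas geometry, hemispheric asymmetries beyond a fixed ipsilateral
fraction, and overdispersion beyond Poisson. Passing tests therefore show
correctness of the statistical machinery under clean planted structure, not
robustness to every artifact of real recordings.

## Problem sizes and numerical choices

Validation suites run at deliberately modest sizes chosen to make
Monte-Carlo error small relative to the margins being checked: 1000 null
neurons for calibration, 500 planted responders for sensitivity, 200
neurons for sigmoid recovery (10% noise), 100 + 100 for model
discrimination, 200 null cohorts / 100 alternative cohorts (12 subjects x
10 sections, 200 shuffles) for permutation-test size and power, and 100
seeded cohorts for direction recovery. Bootstraps default to 10000
resamples. All randomness flows through explicit integer seeds via
`withr::with_seed`, so results are bit-reproducible and the caller's RNG
state is never touched. Degenerate inputs (zero baseline sd, constant
predictors, all-tied windows, zero-variance snippets) are either errors
naming the offending unit or flagged exclusions, never silent NAs.
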