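---
title: "Permutation spline tests: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation spline tests: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `splinetests`: the
smoothing primitive, the three permutation tests built on it, the
synthetic-data generators used to exercise them, and the design decisions
taken where more than one reasonable choice existed. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Input model

All functions consume a long-format table: one row per observation, with
a subject identifier, a numeric independent axis `x` (time, age, or any
continuous axis), a numeric response `y`, and categorical metadata
columns. `as_long_table()` / `read_long_table()` validate this contract:
rows with missing subject or non-finite `x`/`y` are dropped and counted,
at least two distinct subjects and two distinct `x` values must remain,
and strings are compared after trimming surrounding whitespace (no case
folding). Ties in `x` within a subject are allowed and kept.

Two filters act before any test:

* `cut_low` (default 0) drops subjects with **at most** `cut_low`
  observations — i.e. a subject is kept iff it has *strictly more* than
  `cut_low` rows, so `cut_low = 1` removes subjects seen only once. The
  strict reading is deliberate and documented in the CLI help; an
  inclusive reading would differ by one observation per subject.
* `cut_sparse` (two-group test only; default 4) is the minimum number of
  pooled observations a group must have for its spline to be fit. The
  floor of 4 is structural: a local quadratic fit is underdetermined
  below degree + 2 = 4 points.

## The smoothing primitive

Every test summarizes data with the same loess smoother, implemented
pointwise: for a query point *q* inside the training range, the
`ceil(span * n)` nearest training points by |x − q| are selected (clamped
to at least degree + 2 so the local system is always solvable; ties at
the cutoff distance are all included), weighted by the tricube kernel
w = (1 − (d/d_max)³)³ with d_max the largest selected distance, and a
weighted least-squares polynomial of the requested degree, centered at
*q*, is solved; its intercept is the prediction. Queries outside the
training range return `NA` — curves are **never extrapolated** beyond the
first and last observation of the subject or group that produced them.
This no-extrapolation rule is what makes the sliding test's data-density
bookkeeping meaningful.

Numerical choices:

* Degenerate neighborhoods degrade deterministically: if all selected
  points sit exactly at *q* the prediction is their mean; if every
  neighbor ties at the cutoff (all tricube weights zero) uniform weights
  are used; a singular local system falls back to degree − 1, then to the
  weighted mean.
* Defaults `span = 0.75`, `degree = 2` are the conventional loess
  defaults; both are user arguments everywhere. Larger spans smooth more.
* Gaussian (least-squares) fitting only, no robustness iterations:
  outliers therefore influence the splines, which is an acknowledged
  limitation of the approach as a whole; the sparsity filters are the
  mitigation offered.
* Duplicate x values are retained and weighted individually.
* Evaluation is direct at every query point (no interpolation surface):
  grids are at most a few thousand points, and direct evaluation is
  verifiable against a brute-force weighted-least-squares oracle, which
  the test suite does to 1e-8. The kernel is compiled (RcppArmadillo)
  because the two-group test refits ~2000 group splines per run at
  default settings.

The suite also cross-checks the smoother statistically against
`stats::loess` (direct surface) on dense smooth data; exact numeric
agreement with other loess implementations is *not* a goal — their
neighborhood internals differ — and the tests' conclusions are designed
to be robust to that: observed and permuted statistics always use the
same smoother, so any smoother bias cancels in the comparison.

## permuspliner: overall two-group difference

The statistic is the absolute area between the two group splines,
computed as the **sum** of |ĝ₁ − ĝ₂| over `ints` (default 1000) evenly
spaced grid points spanning the *intersection* of the two groups'
observed x ranges (applying the no-extrapolation rule to group curves
too). On an even grid the sum is proportional to the Riemann integral;
users comparing statistics across different `ints` values should note
the statistic scales with `ints` while the p-value does not.

The null shuffles subject-level group labels without replacement,
preserving group sizes and each subject's intact trajectory — permuting
labels rather than observations preserves the within-subject correlation
structure, which is exactly what makes the permutation null honest for
longitudinal data. For each of `perms` (default 999) draws both group
splines are refit and the distance recomputed **over the permuted
groups' own overlapping range** (recomputed per permutation, since the
shuffled groups' ranges can differ from the observed ones — the
alternative of freezing the original grid was rejected because each
permuted dataset must be processed exactly like the observed one).
Permutations in which a shuffled group falls below `cut_sparse` or whose
spline cannot be fit are discarded and redrawn so the permutation count
stays constant; the redraw count is reported.

The empirical p-value uses add-one smoothing, p = (b + 1)/(m + 1) with b
the number of permuted distances ≥ the observed one (`test_direction =
"more"`; `"less"` flips the inequality, testing for groups *more similar*
than chance). Ties count toward the null — conservative — and the
attainable floor is 1/(m + 1). One seeded generator drives the whole
invocation, so a seed reproduces the permutation stream bit-for-bit;
subjects are processed in sorted order so the result is invariant to
which group is labelled "group 1".

## sliding_spliner: localizing the difference

Each subject is summarized by its own spline over its own observation
window, which fills sampling gaps without binning. Subjects without
enough distinct x values for the requested degree degrade gracefully —
degree 2 → degree 1 → straight-line interpolation between the subject's
own points — rather than being dropped (only subjects with < 2 distinct
x values are dropped, with a warning); fallbacks are reported in the
result. All subject curves are evaluated on `ints` (default 100) grid
points spanning the **union** of subject ranges, `NA` outside each
subject's own window. At each grid point the two groups' available
values are compared with a two-sample test, but a p-value is emitted
only where both groups have at least `test_density` (default 3)
contributing subjects; subject counts are recorded at every grid point
regardless, and the companion plot scales point size by them.

The per-interval test is Mann–Whitney by default — chosen because the
package exists for data whose longitudinal variation is not normal — with
Welch's t as an option (`interval_test = "welch_t"`). The Mann–Whitney
implementation is `stats::wilcox.test`: exact when both groups have ≤ 8
values without ties, otherwise the tie-corrected normal approximation
with continuity correction. With ≥ 9 subjects per group a complete
separation saturates at the normal-approximation minimum (≈ 1.8e-4 for
10 vs 10), so adjacent fully separated intervals tie at that value;
consumers localizing a signal should treat the set of minimal-p
intervals, not just the first, as the candidate region. No multiplicity
adjustment is applied — the raw per-interval p-values are returned so
callers can apply `p.adjust` as appropriate — and the reference line
drawn by `plot_sliding_pvals` is the nominal 0.05.

## trendyspliner: non-zero trend in one group

The group spline is fit to the pooled observations and evaluated on
`ints` grid points across the observed range; the statistic is the
*signed* sum of (curve − baseline), where the baseline is the flat
(zero-slope) line through the spline's first grid value. A flat baseline
encodes the null "the response does not meaningfully increase or
decrease": a sloped baseline would need a second anchor that nothing in
the model supplies, so the single-anchor flat line is the design choice.
The sign of the area is the trend direction.

The null permutes each subject's responses across that subject's own
time points, independently per subject, leaving x values and subject
membership untouched. Each permuted replicate is treated exactly like
the observed data — spline refit, area measured against the *permuted*
spline's own start value — so the null is exchangeable by construction.
The p-value is two-sided on absolute areas, ties toward the null.

`mean_center = TRUE` first shifts every subject's mean to the grand mean
of all observations (the grand mean of observations, not of subject
means — with unbalanced designs these differ; the observation-level
definition was chosen so the centered table's overall mean is unchanged).
Centering removes between-subject baseline heterogeneity (body weight,
starting diversity) without altering any subject's internal trajectory,
improving sensitivity to a shared trend. It is off by default.

A note on symmetry: mirroring a *curve* about its start value negates the
area exactly, and negating all responses negates it exactly too (the
suite checks both, the latter including p-value invariance under the
same seed). Reversing the *time axis* negates the area only when the
fitted curve is symmetric about its midpoint (e.g. exactly linear data):
the baseline is anchored at the start, so asymmetric curves yield
different magnitudes in the two directions. The suite therefore checks
time-reversal antisymmetry on noiseless linear data only.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and seed (R's
default Mersenne-Twister stream via an isolated seed context), and
every generated table passes the input validation above.

* `simulate_perturbation_study()` — the power-sweep design: two groups of
  `n_per_group = 10` subjects, `n_timepoints = 30` observations each at
  jittered positions on [0, 1] (even spacing plus uniform jitter of half
  a step), control group pure Gaussian noise (`noise_sd = 1`) around a
  flat baseline, perturbed group plus one or two Gaussian bumps of
  amplitude `magnitude × noise_sd`. The single-region default sits late
  in the series (center 0.7, width 0.1); the two-region scenario (centers
  0.3 and 0.7) gives the second bump the opposite sign, so the two
  perturbations partially cancel in any whole-series summary and the
  scenario is qualitatively harder at low magnitude. `magnitude = 0`
  degenerates to an exchangeable null.
* `simulate_null()` — both groups from the identical process, for
  type-I-error calibration; `staggered_entry` shifts each subject's entry
  and exit inward by uniform fractions of the axis, thinning boundary
  density so the sliding test's gate provably activates.
* `simulate_trend()` — per-subject random intercepts
  (`subject_offset_sd`) plus a shared linear slope and noise; `slope = 0`
  with large offsets is the heterogeneous-baseline null that
  `mean_center` exists to fix.

These generators emulate the *structure* of a perturbation study, not any
particular dataset: no per-subject random intercepts in the perturbation
scenario (the groups differ only by the bump), no compositionality, zero
inflation, or heteroscedasticity of real microbiome relative abundances,
and no dropout unless `staggered_entry` asks for it. Consequently the
absolute p-values at low magnitudes depend on details no published figure
pins down, and the suite asserts only what survives that freedom: the 4x
scenarios reach (or nearly reach) the permutation floor, median p is
non-increasing in magnitude over seeded replicates, nulls reject at the
nominal rate within exact binomial bounds, and the sliding minimum-p sits
inside the perturbed region. Passing these says the machinery is correct
and calibrated; it does not certify power on real microbiome data.

## Problem sizes in the shipped checks

The test suite runs the headline 4x scenarios at full defaults (999
permutations, 1000 grid points) and scales the sweeps down where the
property being checked is size-invariant: the magnitude-monotonicity
sweep uses 99 permutations and 200 grid points over 20 replicates per
magnitude (the p-value does not depend on grid resolution, and median
ordering needs no 0.001 floor), and the calibration runs use 200
replicates of 8 subjects × 12 timepoints with 199 permutations (a
permutation test is exactly calibrated at any size, so nominal-rate
rejection is size-independent). `scripts/acceptance.R` recomputes the
two 4x p-values at full defaults from scratch.

## Known limitations

* Loess without robustness iterations is outlier-sensitive, most acutely
  in sparse regions; `cut_low`/`cut_sparse` and the span are the levers.
* The two-group statistic weights all grid points equally; a difference
  confined to a short window dilutes over a long series (the sliding
  test is the remedy).
* The sliding test's per-interval values are correlated across intervals
  (neighboring grid points share subjects and smoothing windows), so
  familywise error over intervals is not controlled and clusters of
  small p-values should be read as one region, not many discoveries.
* Group-label permutation assumes subjects are exchangeable between
  groups under the null; confounding between group and covariates is not
  adjusted for.
* `test_direction = "less"` tests for groups more similar than chance —
  useful, but its power is limited when between-subject variability is
  small, since permuted groups then resemble the observed ones anyway.
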