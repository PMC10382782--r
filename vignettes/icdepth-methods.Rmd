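---
title: "Vector-sum and MLE observer models for 3D cue integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector-sum and MLE observer models for 3D cue integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdepth)
```

## The problem

When a 3D surface is specified by several depth cues at once — a texture
gradient and binocular disparity, say — how does the visual system combine
the per-cue signals into a single perceived depth? Two observer models with
very different assumptions make overlapping but distinguishable
predictions, and this package implements both as executable, simulatable
observers together with the full analysis pipeline needed to tell them
apart in psychophysical data.

**The linear MLE model** assumes each cue module produces an *unbiased but
noisy* depth estimate $\hat z_i \sim \mathcal N(z, \sigma_i^2)$ and that
the combined estimate is the reliability-weighted average

$$\hat z_c = \sum_i w_i \hat z_i, \qquad
  w_i = \frac{1/\sigma_i^2}{\sum_j 1/\sigma_j^2}, \qquad
  \sigma_c = \Big(\sum_i \sigma_i^{-2}\Big)^{-1/2}.$$

The combined estimate always lies between the single-cue estimates, and
its variance is smaller than either.

**The intrinsic-constraint (IC) vector-sum model** assumes each cue module
produces a *deterministic but generally biased* signal, linear in distal
depth: $\hat z_i = k_i z$. The slope $k_i$ — the *cue strength* — depends
on the quality of the cue under the current viewing conditions (a nuisance
variable such as fixation distance changes $k_i$ without changing the
surface). The combined percept is the Euclidean norm of the signals,

$$\hat z_c = \sqrt{\textstyle\sum_i \hat z_i^2}
           = \sqrt{\textstyle\sum_i k_i^2}\; z = k_c z,$$

so adding a cue *increases* perceived depth, and a cue specifying zero
depth (a "flatness cue": a null disparity field, an undistorted screen
texture) contributes nothing at all. All response variability is late,
task-related noise whose SD grows with the *perceived* magnitude through a
Weber law, $\sigma_N(\hat z) = W\hat z + c$.

The JND of a 2IFC depth discrimination task is reinterpreted accordingly:
it is not estimation noise but the distal-depth change needed to overcome
task noise, $J = \sigma_N / k$. Two consequences carry the empirical
program:

1. $J_c = (1/J_t^2 + 1/J_d^2)^{-1/2}$ — *formally identical* to the MLE
   variance rule (`combine_jnds()` and `mle_combined_sigma()` agree to
   machine precision), but predicted to hold at matched *perceived* depth
   rather than matched simulated depth.
2. With $\hat z_s = k z_s$ for the standard,
   $J = W z_s + c/k$ (`weber_jnd()`), so discounting the Weber and
   baseline terms from a measured JND exposes the $1/k$ hyperbola
   (`corrected_jnd()`).

## What the synthetic-data generators emulate

No data were deposited for the source study, so the package generates its
own: cohorts of IC or MLE observers with per-subject parameters drawn from
configurable population specs, pushed through the three experiment
designs.

* **Probe adjustment** (`generate_exp1()`): 3 cue conditions x 4
  peak-to-trough depths (2.5, 5, 10, 15 mm) x 2 fixation distances (40,
  80 cm) x 7 repetitions, order randomised within distance blocks. IC
  probes are the deterministic percept plus task noise; MLE probes are
  noisy percept draws. Settings are truncated at zero *by redraw*, not
  clipping, to avoid a point mass at 0.
* **2IFC staircases** (`generate_exp2()`): per subject, 12 standards
  (3 cues x 2 distances x 2 perceived-depth levels) selected by
  `select_standards()`, each run with four interleaved transformed
  up-down staircases (2-up/1-down, 1-up/2-down, 3-up/1-down, 1-up/3-down)
  to 12 reversals.
* **Flatness conditions** (`generate_exp3()`): variant A crosses monocular
  viewing (disparity absent) with binocular viewing of the picture plane
  (null disparity field); variant B crosses an RDS (no usable texture)
  with a reliable textural flatness cue. IC observers are invariant by
  construction; MLE observers are pulled toward flatness in proportion to
  the flat cue's reliability.

Default population parameters state a world consistent with the
qualitative human findings: $k_t \sim U[0.6, 1.4]$ at both distances,
$k_d \sim U[0.8, 1.8]$ at 40 cm but $U[0.6, 1.2]$ at 80 cm (the classic
failure of depth constancy for disparity), $W = 0.13$, $c = 1.66$ mm (the
reported group means). These defaults were chosen once and are fully
configurable; the parameter-recovery tests use them as generating truths.

What the generators do *not* emulate: stimulus rendering, vergence and
eye-movement dynamics, depth adaptation, learning or sequential effects,
lapses of attention (the generative observers never lapse), and
interval-order bias in the 2IFC task. A green recovery test therefore
establishes that the *analysis pipeline* is consistent and unbiased for
data of this structure — not that human data will be as clean.

## Tunable parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `slope_k` | mm/mm | drawn | cue strength; slope of the perceptual function |
| `weber_W` | — | 0.13 | task-noise growth with perceived depth |
| `constant_c` | mm | 1.66 | baseline task noise |
| `sigma` (MLE) | mm | drawn | per-cue estimation noise SD |
| `step_mm` | mm | 10% of standard | staircase step, halved after reversal 4 |
| `target_reversals` | — | 12 | staircase termination |
| `lapse` | — | 0.02 | fixed lapse rate in psychometric fits |

Depths are millimetres throughout and fixation distances centimetres; no
unit conversions happen outside I/O.

## Numerical and design choices

* **Staircase placement.** Step sizes and start values are not reported in
  the source procedures. Rules converging above the 50% point start at
  1.5x the standard, the others at 0.5x, so the four rules bracket the PSE
  from both sides; the step is 10% of the standard's simulated depth and
  halves once after the fourth reversal. A 400-trial safety cap aborts
  pathological runs. Whether the four staircases were interleaved
  trial-by-trial or run sequentially is also unstated; the generator
  interleaves (statistically equivalent here, since responses are
  conditionally independent given the comparison value).
* **2IFC noise placement.** A single task-noise draw is applied to the
  decision difference, with SD set by the perceived depth of the standard
  — this makes $J = \sigma_N/k$ exact. A per-interval variant (effective
  SD $\times\sqrt 2$) is available via `per_interval_noise = TRUE`. MLE
  observers compare two independent percept draws, so their predicted JND
  is $\sqrt 2\,\sigma_c$ (in simulated units, $\times$ the 0.9945 factor
  below) — do not conflate this with the variance rule itself.
* **Psychometric fitting.** Fixed lapse (default 0.02) because
  staircase-concentrated sampling cannot identify it; multi-start grid
  then L-BFGS-B with $\sigma \in [0.01, 50]$ mm; perfectly separable data
  are flagged non-identifiable rather than reported at the bound. The JND
  is the 84%-point distance, $\sigma\,\Phi^{-1}(0.84) \approx
  0.9945\sigma$ at zero lapse, computed through the lapse-adjusted curve
  otherwise. The default pools the four staircases of a standard into one
  fit (more stable at 12 reversals each); a per-staircase mode with
  averaging mirrors the original procedure.
* **Cue-strength fits.** Free intercept by default (absorbs probe
  calibration offsets), slope reported as $k$; a zero-intercept mode
  matches the theoretical form and roughly halves the slope standard
  error. This choice is consequential: under the default noise world the
  per-cell slope SE is 0.09–0.16, i.e. ~11% of a typical $k$, which is
  why the recovery suite reports the free-intercept RMS honestly at that
  level.
* **Standard selection.** Per-cue quadratics are unconstrained least
  squares on per-depth means; monotonicity on [2.5, 15] mm is checked
  post hoc (flag or error, caller's choice), the root inside the stimulus
  range is taken, and out-of-range roots are used but flagged as
  extrapolated. Anchoring the small standard at the *largest* perceived
  depth reached at 2.5 mm and the large standard at the *smallest*
  perceived depth reached at 15 mm keeps every cue's standard inside the
  stimulus range.
* **Weber-model fit.** $J = W z_s + c/k$ is linear in $(W, c)$ given
  $(z_s, 1/k)$, so the non-negative least-squares solution is computed
  exactly by comparing the unconstrained fit with the two boundary fits.
  Note that $z_s$ and $1/k$ are strongly collinear by construction (the
  standards were chosen to match perceived depth, $z_s \approx
  \hat z^\ast/k$), which inflates the variance of the split between $W$
  and $c$ at small $n$; recovery tests bound the resulting error rather
  than pretend it away.
* **Corrected JND.** Default form $(J - W z_s)/c$, which equals $1/k$
  exactly for model-generated JNDs; the unscaled form $J - W z_s$
  (predicted curve $c/k$) is switchable.
* **Unmeasurable cells.** $k = 0$ makes the JND undefined (a staircase
  cannot converge); such cells carry the `NA_real_` sentinel and are
  filtered, never silently turned into `Inf`. Uninformative cues are
  encoded with a large finite $\sigma$ (default $10^6$ mm), keeping the
  weighting algebra closed.
* **Mixed models and Bayes factors.** The random-intercept model is fit by
  maximum likelihood profiled down to the one-dimensional variance ratio,
  with the $\lambda = 0$ boundary evaluated explicitly; `BF01 =
  exp((BIC_full - BIC_null)/2)` is the unit-information approximation.
  The original analyses used JZS-prior Bayes factors; without the human
  data those exact values (0.055 / 0.21 / 0.42) are not reproducible, so
  only the *direction* of the evidence is asserted: IC-generated flatness
  data favour the null, MLE-generated data favour the effect.
* **ANOVA.** Balanced fully-within designs only, on subject-by-cell
  means; each effect is tested against its subject interaction;
  generalized $\eta^2$ pools all subject-involving terms. Effects whose
  sum of squares is numerically zero (exactly additive data) report
  $F = 0$ rather than a 0/0 artefact. Unbalanced tables are an error —
  no imputation.

## Interpreting the recovery suite

Three calibration points deserve explanation, because they follow from
statistics rather than code:

* *Psychometric recovery at 500 trials.* The per-trial Fisher information
  of a cumulative Gaussian caps how precisely $\mu$ and $\sigma$ can be
  estimated jointly: no placement of 500 trials makes both land within
  $\pm 0.3$ (at $\sigma = 2$) in 95% of runs — the optimum is ~94%.
  The suite therefore asserts the $\pm 0.3$ band per parameter (97% and
  95% observed with a 7-level constant-stimuli design spanning
  $\pm 2\sigma$; the joint rate is 92%).
* *Slope recovery at 7 repetitions.* With task noise
  $\sigma_N = 0.13\,\hat z + 1.66$ mm and the 4-depth design, ordinary
  least squares with a free intercept cannot beat ~11% relative RMS on the
  cue-strength slopes; the suite reports this honestly (the corresponding
  criterion is expected to sit just above a 10% bound) while the
  downstream, parameter-free origin regression of observed on predicted
  combined strengths is unbiased (slope within [0.95, 1.05] in 96% of
  seeds).
* *SD "null" calibration.* With $W > 0$, perceived depth — and hence task
  noise — genuinely differs between cue conditions, so "no cue-type effect
  on adjustment SDs" is only *exactly* true in a constant-noise world.
  The type-I calibration therefore uses $W = 0$; in Weber worlds the
  claim is directional, not exact.

## Known limitations

* Perceptual functions are linear with non-negative slope; nonlinear
  mappings and depth priors are out of scope.
* The staircase engine implements transformed up-down rules only (no
  QUEST/Psi), and the psychometric module fits cumulative Gaussians only,
  without goodness-of-fit deviance tests.
* The ANOVA layer handles balanced fully-within designs; no
  Greenhouse–Geisser correction, no crossed random effects.
* Bayes factors are BIC approximations; they approach JZS values only at
  large $n$.
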