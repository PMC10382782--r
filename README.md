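# icdepth

Observer models and analysis tools for 3D depth-cue integration
experiments.

When a surface's depth is specified by several cues at once (a texture
gradient, binocular disparity), two observer models compete to explain how
the percepts combine:

* the **linear MLE model** — each cue yields an unbiased noisy estimate
  $\hat z_i \sim \mathcal N(z, \sigma_i^2)$ and the combined estimate is
  the reliability-weighted average, with variance
  $\sigma_c^2 = (\sum_i \sigma_i^{-2})^{-1}$;
* the **intrinsic-constraint (IC) vector-sum model** — each cue yields a
  deterministic linear signal $\hat z_i = k_i z$ (the slope $k_i$ is the
  *cue strength*) and the combined percept is the vector norm
  $\hat z_c = \sqrt{\sum_i \hat z_i^2} = \sqrt{\sum_i k_i^2}\,z$, with all
  response variability coming from late task noise
  $\sigma_N = W \hat z + c$ (a Weber law on perceived depth).

The IC reading of a 2IFC discrimination threshold is $J = \sigma_N/k$,
which yields a combined-cue prediction
$J_c = (1/J_t^2 + 1/J_d^2)^{-1/2}$ — formally identical to the MLE
variance rule, but holding at matched *perceived* rather than *simulated*
depth. The package implements both models as generative simulators,
together with everything needed to run the discriminating analyses on
synthetic cohorts:

* transformed up-down staircases (2-up/1-down, 1-up/2-down, 3-up/1-down,
  1-up/3-down) driving simulated 2IFC trials;
* cumulative-Gaussian psychometric fits with PSE (50%) and JND (84%)
  extraction;
* cue-strength estimation from probe-adjustment data and the
  parameter-free vector-sum prediction of combined-cue strength;
* perceived-depth-matched standard selection, vector-sum and MLE JND
  predictions, Weber task-noise model fits ($J = W z_s + c/k$),
  noise-corrected JNDs, and type-10 Grubbs outlier screening;
* a simplified inferential layer: balanced repeated-measures ANOVA with
  generalized $\eta^2$, Bonferroni paired t tests, profiled
  random-intercept mixed models, and BIC-approximate Bayes factors.

Everything is driven by one master seed, so each analysis stage can be
validated by parameter recovery on observers with known ground truth.

## Worked example

```r
library(icdepth)

combined_strength(c(0.6, 0.8))           # vector-sum cue strength
#> [1] 1
weber_jnd(10, 1, task_noise_model(0.13, 1.66))
#> [1] 2.96                               # J = W*z_s + c/k

cfg <- pipeline_config(observer_class = "ic", n_subjects = 6, seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)
str(res$summary)
#> List of 6
#>  $ n_subjects      : int 6
#>  $ seed            : int 42
#>  $ observer_class  : chr "ic"
#>  $ slope_regression:List of 4
#>   ..$ slope   : num 0.976
#>   ..$ se_slope: num 0.0301
#>   ..$ r       : num 0.736
#>   ..$ n       : int 12
#>  $ weber           :List of 4
#>   ..$ weber_W_mean   : num 0.137
#>   ..$ weber_W_se     : num 0.0105
#>   ..$ constant_c_mean: num 1.52
#>   ..$ constant_c_se  : num 0.116
#>  $ flatness_bf01   :List of 2
#>   ..$ A: num 4.28
#>   ..$ B: num 3.82
```

Reading the numbers: the cohort was generated by IC observers, and the
analysis recovers that world. The regression of observed on predicted
combined-cue strengths — a prediction with *zero* free parameters — has
slope 0.976 (unity means the vector-sum rule holds exactly). The Weber
task-noise fit over all staircase-derived JNDs recovers the generating
parameters ($W = 0.13$, $c = 1.66$ mm) as 0.137 and 1.52. The
BIC-approximate Bayes factors for a flatness-cue effect are 4.3 and 3.8 in
favour of the *null* in the two flatness experiments — flatness cues are
inert for IC observers, whereas an MLE cohort (`observer_class = "mle"`
with a reliable `sigma_flat_texture`) drives them far below 1.

`res` also carries every intermediate table (trial tables, cue strengths,
per-cell SDs, standards, JND records and predictions); passing
`out_dir = "somewhere"` writes them all as CSV plus a `summary.json`.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/icdepth.R", package="icdepth"))')" \
  simulate --observer ic --n 6 --seed 42 --out run1
```

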