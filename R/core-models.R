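#' @keywords internal
"_PACKAGE"

## Closed label set for depth cues. "combined" is an output label only and is
## rejected as an input to any combination rule.
CUE_LABELS <- c("disparity", "texture", "combined", "flat_texture", "none")

#' Validate a cue label
#'
#' @param cue character scalar, one of `"disparity"`, `"texture"`,
#'   `"combined"`, `"flat_texture"`, `"none"`.
#' @param allow_combined should `"combined"` be accepted? Combination rules
#'   never take `"combined"` as an input cue.
#' @return the validated label, invisibly usable.
#' @export
cue_label <- function(cue, allow_combined = TRUE) {
  if (!is.character(cue) || length(cue) != 1L || !(cue %in% CUE_LABELS)) {
    stop("unknown cue label: ", paste(cue, collapse = ", "),
         " (must be one of ", paste(CUE_LABELS, collapse = ", "), ")")
  }
  if (!allow_combined && cue == "combined") {
    stop("'combined' is not a valid input cue for a combination rule")
  }
  cue
}

#' Viewing condition
#'
#' A viewing condition is characterised by its fixation distance; depth is in
#' millimetres throughout, fixation distance in centimetres.
#'
#' @param fixation_distance_cm positive fixation distance in cm.
#' @param label optional free-text label.
#' @return an object of class `viewing_condition`.
#' @export
viewing_condition <- function(fixation_distance_cm, label = NULL) {
  stopifnot(is.numeric(fixation_distance_cm), length(fixation_distance_cm) == 1L)
  if (!is.finite(fixation_distance_cm) || fixation_distance_cm <= 0) {
    stop("fixation_distance_cm must be a positive finite number")
  }
  structure(
    list(fixation_distance_cm = fixation_distance_cm,
         label = label %||% paste0(fixation_distance_cm, "cm")),
    class = "viewing_condition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear perceptual function
#'
#' The mapping from simulated (distal) depth to perceived depth for one cue
#' under one viewing condition: `z_hat = k * z + intercept`. The slope `k` is
#' the cue strength. The theoretical model has zero intercept; empirical fits
#' may carry a free intercept that absorbs probe-calibration offsets.
#'
#' @param slope_k non-negative slope (mm perceived per mm simulated).
#' @param cue cue label.
#' @param condition optional `viewing_condition`.
#' @param intercept finite intercept in mm (default 0).
#' @return an object of class `perceptual_function`.
#' @export
perceptual_function <- function(slope_k, cue = "none", condition = NULL,
                                intercept = 0) {
  cue_label(cue)
  stopifnot(is.numeric(slope_k), length(slope_k) == 1L, is.finite(slope_k))
  if (slope_k < 0) stop("slope_k must be >= 0")
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(
    list(cue = cue, condition = condition, slope_k = slope_k,
         intercept = intercept),
    class = "perceptual_function"
  )
}

#' Perceived depth under a linear perceptual function
#'
#' @param pf a `perceptual_function`.
#' @param z simulated depth(s) in mm, all `>= 0`.
#' @return perceived depth(s) in mm, clipped at 0.
#' @export
perceived_depth <- function(pf, z) {
  stopifnot(inherits(pf, "perceptual_function"), is.numeric(z))
  if (any(!is.finite(z)) || any(z < 0)) stop("z must be finite and >= 0")
  pmax(pf$slope_k * z + pf$intercept, 0)
}

#' Vector-sum (intrinsic constraint) combination of depth estimates
#'
#' The combined percept is the Euclidean norm of the single-cue depth
#' signals. A zero-valued estimate contributes nothing, so specifying zero
#' depth with a cue is equivalent to removing the cue (flatness invariance).
#'
#' @param estimates numeric vector of non-negative single-cue depth
#'   estimates (mm).
#' @return combined depth estimate (mm).
#' @export
vector_sum <- function(estimates) {
  if (length(estimates) == 0L) stop("need at least one depth estimate")
  stopifnot(is.numeric(estimates))
  if (any(!is.finite(estimates)) || any(estimates < 0)) {
    stop("estimates must be finite and >= 0")
  }
  sqrt(sum(estimates^2))
}

#' Combined cue strength under the vector-sum rule
#'
#' When every cue renders the same simulated depth (no cue conflict) the
#' combined percept is itself linear in depth, with slope
#' `k_c = sqrt(sum(k_i^2))`.
#'
#' @param k_list numeric vector of non-negative single-cue strengths.
#' @return combined cue strength; always `>= max(k_list)`.
#' @export
combined_strength <- function(k_list) {
  if (length(k_list) == 0L) stop("need at least one cue strength")
  stopifnot(is.numeric(k_list))
  if (any(!is.finite(k_list)) || any(k_list < 0)) {
    stop("cue strengths must be finite and >= 0")
  }
  sqrt(sum(k_list^2))
}

#' MLE reliability weights
#'
#' Weights proportional to reliabilities `1/sigma^2`, normalised to sum to 1.
#' Uninformative cues are encoded with a large finite sigma (e.g. `1e6` mm),
#' never `Inf` or 0, so the algebra stays closed.
#'
#' @param sigmas numeric vector of positive cue noise SDs (mm).
#' @return numeric vector of weights in (0, 1) summing to 1.
#' @export
mle_weights <- function(sigmas) {
  if (length(sigmas) == 0L) stop("need at least one sigma")
  stopifnot(is.numeric(sigmas))
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("all sigmas must be finite and > 0")
  }
  r <- 1 / sigmas^2
  r / sum(r)
}

#' MLE (reliability-weighted) combination of depth estimates
#'
#' @param estimates numeric vector of single-cue depth estimates (mm).
#' @param sigmas numeric vector of matching cue noise SDs (mm).
#' @return the weighted-average combined estimate; always between
#'   `min(estimates)` and `max(estimates)`.
#' @export
mle_combine <- function(estimates, sigmas) {
  if (length(estimates) != length(sigmas)) {
    stop("estimates and sigmas must be cue-aligned (same length)")
  }
  stopifnot(is.numeric(estimates))
  if (any(!is.finite(estimates))) stop("estimates must be finite")
  sum(mle_weights(sigmas) * estimates)
}

#' SD of the MLE combined estimate
#'
#' `sigma_c = sqrt(1 / sum(1/sigma_i^2))`; strictly smaller than the
#' smallest single-cue sigma when two or more informative cues combine.
#'
#' @param sigmas numeric vector of positive cue noise SDs (mm).
#' @return combined-estimate SD (mm).
#' @export
mle_combined_sigma <- function(sigmas) {
  if (length(sigmas) == 0L) stop("need at least one sigma")
  stopifnot(is.numeric(sigmas))
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("all sigmas must be finite and > 0")
  }
  sqrt(1 / sum(1 / sigmas^2))
}

#' Task-noise model
#'
#' Late-stage (task-related) response noise, independent of which cues are in
#' the display. Its SD grows with the *perceived* magnitude through a Weber
#' fraction: `sigma_N(z_hat) = weber_W * z_hat + constant_c`.
#'
#' @param weber_W non-negative Weber fraction (dimensionless).
#' @param constant_c non-negative baseline noise (mm). Must be positive when
#'   `weber_W == 0` so that `sigma_N > 0` everywhere.
#' @return an object of class `task_noise_model`.
#' @export
task_noise_model <- function(weber_W = 0.13, constant_c = 1.66) {
  stopifnot(is.numeric(weber_W), length(weber_W) == 1L, is.finite(weber_W),
            is.numeric(constant_c), length(constant_c) == 1L,
            is.finite(constant_c))
  if (weber_W < 0 || constant_c < 0) stop("weber_W and constant_c must be >= 0")
  if (weber_W == 0 && constant_c == 0) {
    stop("constant_c must be > 0 when weber_W is 0 (sigma_N would vanish)")
  }
  structure(list(weber_W = weber_W, constant_c = constant_c),
            class = "task_noise_model")
}

#' Task-noise SD at a given perceived depth
#'
#' @param noise a `task_noise_model`.
#' @param z_hat perceived depth(s) in mm.
#' @return `weber_W * z_hat + constant_c`.
#' @export
task_noise_sd <- function(noise, z_hat) {
  stopifnot(inherits(noise, "task_noise_model"), is.numeric(z_hat))
  noise$weber_W * z_hat + noise$constant_c
}

#' JND from task noise and cue strength
#'
#' Under the intrinsic-constraint reading, the JND is the simulated-depth
#' change needed to overcome the task noise: `J = sigma_N / k`. A
#' zero-strength cue is unmeasurable (a staircase cannot converge): the
#' function returns `NA_real_` as a tagged sentinel rather than `Inf`, so
#' downstream tables can filter such cells.
#'
#' @param sigma_N positive task-noise SD (mm).
#' @param k non-negative cue strength.
#' @return JND in mm, or `NA_real_` when `k == 0`.
#' @export
jnd_from_strength <- function(sigma_N, k) {
  stopifnot(is.numeric(sigma_N), is.numeric(k))
  if (any(!is.finite(sigma_N)) || any(sigma_N <= 0)) {
    stop("sigma_N must be finite and > 0")
  }
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  out <- sigma_N / k
  out[k == 0] <- NA_real_  # unmeasurable sentinel
  out
}

#' Combine single-cue JNDs
#'
#' `J_c = 1 / sqrt(sum(1/J_i^2))`. Formally identical to
#' [mle_combined_sigma()] applied to the same values, even though the two
#' theories interpret the inputs differently (task-noise-limited thresholds
#' vs. estimation-noise SDs).
#'
#' @param j_list numeric vector of positive single-cue JNDs (mm).
#' @return combined JND (mm).
#' @export
combine_jnds <- function(j_list) {
  if (length(j_list) == 0L) stop("need at least one JND")
  stopifnot(is.numeric(j_list))
  if (any(!is.finite(j_list)) || any(j_list <= 0)) {
    stop("all JNDs must be finite and > 0")
  }
  1 / sqrt(sum(1 / j_list^2))
}

#' Weber task-noise model of the JND
#'
#' With `sigma_N = W * k * z_s + c` (task noise growing with the perceived
#' depth of the standard), the JND relative to the distal depth of the
#' standard is `J = W * z_s + c / k`.
#'
#' @param z_s non-negative simulated (distal) depth of the standard (mm).
#' @param k positive cue strength (`k == 0` yields the `NA_real_`
#'   unmeasurable sentinel).
#' @param noise a `task_noise_model`.
#' @return predicted JND in mm.
#' @export
weber_jnd <- function(z_s, k, noise) {
  stopifnot(inherits(noise, "task_noise_model"), is.numeric(z_s), is.numeric(k))
  if (any(!is.finite(z_s)) || any(z_s < 0)) stop("z_s must be finite and >= 0")
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  out <- noise$weber_W * z_s + noise$constant_c / k
  out[k == 0] <- NA_real_
  out
}

#' Noise-corrected JND
#'
#' Removes the Weber-law and baseline-noise contributions from a measured
#' JND. The default `"scaled"` form is `(J - W * z_s) / c`, which equals
#' `1/k` exactly when `J` was generated by [weber_jnd()]; the `"unscaled"`
#' form `J - W * z_s` (predicted curve `c/k`) is also hyperbolic in `k` and
#' is provided as an alternative.
#'
#' @param j measured JND(s) in mm.
#' @param z_s simulated depth(s) of the standard (mm).
#' @param noise a `task_noise_model`; `constant_c > 0` required for the
#'   scaled form.
#' @param form `"scaled"` (default) or `"unscaled"`.
#' @return corrected JND (dimensionless for `"scaled"`, mm for
#'   `"unscaled"`).
#' @export
corrected_jnd <- function(j, z_s, noise, form = c("scaled", "unscaled")) {
  form <- match.arg(form)
  stopifnot(inherits(noise, "task_noise_model"), is.numeric(j), is.numeric(z_s))
  resid <- j - noise$weber_W * z_s
  if (form == "unscaled") return(resid)
  if (noise$constant_c <= 0) {
    stop("constant_c must be > 0 for the scaled corrected JND")
  }
  resid / noise$constant_c
}
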