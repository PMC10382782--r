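#' Stimulus specification
#'
#' A simulated corrugated surface described by the depth each cue renders.
#' `NA` means the cue is absent/uninformative (e.g. the random-dot texture of
#' an RDS); `0` means the cue actively specifies a flat surface (e.g. a null
#' disparity field under binocular viewing of a picture). The vector-sum
#' model treats the two identically; the MLE model does not.
#'
#' @param cue_condition label for the experimental cue condition
#'   (`"disparity"`, `"texture"`, `"combined"`, ...).
#' @param z_texture_mm depth rendered by the texture gradient (mm) or `NA`.
#' @param z_disparity_mm depth rendered by binocular disparity (mm) or `NA`.
#' @param distance_cm fixation distance (cm).
#' @param texture_label `"texture"` or `"flat_texture"`; the latter marks a
#'   reliable textural flatness cue (back-projected polka dots) so that an
#'   MLE observer can assign it its own noise SD.
#' @return an object of class `ic_stimulus`.
#' @export
stimulus <- function(cue_condition, z_texture_mm = NA_real_,
                     z_disparity_mm = NA_real_, distance_cm = 40,
                     texture_label = "texture") {
  cue_label(cue_condition)
  stopifnot(texture_label %in% c("texture", "flat_texture"))
  for (z in list(z_texture_mm, z_disparity_mm)) {
    if (!is.na(z) && (!is.finite(z) || z < 0)) {
      stop("cue depths must be NA or finite and >= 0")
    }
  }
  structure(
    list(cue_condition = cue_condition, z_texture_mm = z_texture_mm,
         z_disparity_mm = z_disparity_mm, distance_cm = distance_cm,
         texture_label = texture_label),
    class = "ic_stimulus"
  )
}

#' Intrinsic-constraint (vector-sum) observer
#'
#' A deterministic observer: each cue maps distal depth to an internal
#' signal through a linear perceptual function, and the percept is the
#' vector norm of the signals. All stochasticity in its responses comes from
#' late, task-related noise.
#'
#' @param id subject label.
#' @param strengths data.frame with columns `cue` (`"texture"`,
#'   `"disparity"`), `distance_cm`, `k` (and optionally `intercept`), one row
#'   per cue x viewing condition.
#' @param task_noise a [task_noise_model()].
#' @return an object of class `ic_observer`.
#' @export
ic_observer <- function(id, strengths, task_noise = task_noise_model()) {
  stopifnot(is.data.frame(strengths),
            all(c("cue", "distance_cm", "k") %in% names(strengths)),
            inherits(task_noise, "task_noise_model"))
  if (any(strengths$k < 0)) stop("cue strengths must be >= 0")
  if (anyDuplicated(strengths[, c("cue", "distance_cm")])) {
    stop("duplicate (cue, distance_cm) entries in strengths")
  }
  structure(list(id = id, strengths = strengths, task_noise = task_noise),
            class = c("ic_observer", "observer"))
}

#' Maximum-likelihood observer
#'
#' A stochastic observer: each available cue yields an unbiased noisy depth
#' estimate which are combined by reliability weighting. Flatness cues
#' (signals specifying zero depth) enter the average like any other cue and
#' pull the percept toward zero.
#'
#' @param id subject label.
#' @param noises data.frame with columns `cue` (`"texture"`, `"disparity"`,
#'   `"flat_texture"`), `distance_cm`, `sigma` (mm, > 0).
#' @param task_noise optional [task_noise_model()] added at the response
#'   stage; `NULL` (default) means all response variability is estimation
#'   noise.
#' @return an object of class `mle_observer`.
#' @export
mle_observer <- function(id, noises, task_noise = NULL) {
  stopifnot(is.data.frame(noises),
            all(c("cue", "distance_cm", "sigma") %in% names(noises)))
  if (any(noises$sigma <= 0)) {
    stop("all cue noise sigmas must be > 0 (use a large finite sigma for an ",
         "uninformative cue)")
  }
  if (!is.null(task_noise)) stopifnot(inherits(task_noise, "task_noise_model"))
  structure(list(id = id, noises = noises, task_noise = task_noise),
            class = c("mle_observer", "observer"))
}

lookup_param <- function(tab, value_col, cue, distance_cm) {
  hit <- tab$cue == cue & tab$distance_cm == distance_cm
  if (sum(hit) != 1L) {
    stop("no (", cue, ", ", distance_cm, " cm) entry configured for observer")
  }
  tab[[value_col]][hit]
}

## Cues carried by a stimulus, as (label-for-lookup, depth) pairs.
stimulus_cues <- function(s) {
  out <- list()
  if (!is.na(s$z_texture_mm)) {
    out[[length(out) + 1L]] <- list(cue = s$texture_label, z = s$z_texture_mm)
  }
  if (!is.na(s$z_disparity_mm)) {
    out[[length(out) + 1L]] <- list(cue = "disparity", z = s$z_disparity_mm)
  }
  if (length(out) == 0L) stop("stimulus carries no cues")
  out
}

#' Deterministic percept of an IC observer
#'
#' `vector_sum` over the available cues of `k_i * z_i`. Cues with zero
#' rendered depth or zero strength contribute nothing, so a null disparity
#' field and an absent disparity cue give bit-identical percepts.
#'
#' @param obs an `ic_observer`.
#' @param s an `ic_stimulus`.
#' @return perceived depth (mm).
#' @export
ic_percept <- function(obs, s) {
  stopifnot(inherits(obs, "ic_observer"), inherits(s, "ic_stimulus"))
  cues <- stimulus_cues(s)
  signals <- vapply(cues, function(cc) {
    ## the IC observer has one texture module: a flat texture is just the
    ## texture cue rendering zero depth
    cue <- if (cc$cue == "flat_texture") "texture" else cc$cue
    k <- lookup_param(obs$strengths, "k", cue, s$distance_cm)
    k * cc$z
  }, numeric(1))
  vector_sum(signals)
}

#' One noisy percept of an MLE observer
#'
#' Draws `z_hat_i ~ Normal(z_i, sigma_i)` for every cue the stimulus
#' carries (including flatness cues at `z = 0`), combines them by
#' reliability weighting, and clips at 0.
#'
#' @param obs an `mle_observer`.
#' @param s an `ic_stimulus`.
#' @param n number of independent draws (default 1).
#' @return perceived depth draw(s) (mm).
#' @export
mle_percept_sample <- function(obs, s, n = 1L) {
  stopifnot(inherits(obs, "mle_observer"), inherits(s, "ic_stimulus"))
  cues <- stimulus_cues(s)
  sig <- vapply(cues, function(cc) {
    lookup_param(obs$noises, "sigma", cc$cue, s$distance_cm)
  }, numeric(1))
  z <- vapply(cues, `[[`, numeric(1), "z")
  w <- mle_weights(sig)
  ## weighted average of independent normal draws
  draws <- colSums(w * z + w * sig * matrix(stats::rnorm(length(z) * n),
                                            nrow = length(z)))
  pmax(draws, 0)
}

## Truncated-at-zero normal draws by redraw (no point mass at 0).
rnorm_trunc0 <- function(mean, sd) {
  n <- length(mean)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- 0; break }  # pathological mean << 0
  }
  out
}

#' Simulate one probe-adjustment trial
#'
#' The observer matches the amplitude of a 2D probe to the perceived depth
#' of the stimulus. For an IC observer the probe setting is the
#' deterministic percept plus task noise whose SD depends only on the
#' perceived magnitude; for an MLE observer it is a noisy percept draw plus
#' any configured task noise. Settings are truncated at 0 by redraw.
#'
#' @param obs an observer.
#' @param s an `ic_stimulus`.
#' @return probe setting (mm).
#' @export
simulate_adjustment <- function(obs, s) {
  UseMethod("simulate_adjustment")
}

#' @export
simulate_adjustment.ic_observer <- function(obs, s) {
  z_hat <- ic_percept(obs, s)
  rnorm_trunc0(z_hat, task_noise_sd(obs$task_noise, z_hat))
}

#' @export
simulate_adjustment.mle_observer <- function(obs, s) {
  p <- mle_percept_sample(obs, s)
  if (!is.null(obs$task_noise)) {
    p <- rnorm_trunc0(p, task_noise_sd(obs$task_noise, p))
  }
  p
}

#' Simulate one 2IFC depth-discrimination response
#'
#' For an IC observer, both percepts are deterministic and the decision is
#' corrupted by a single task-noise draw whose SD is set by the perceived
#' depth of the standard (`sigma_N = W * z_hat_std + c`), so
#' `P(choose comparison) = Phi(k * dz / sigma_N)` and the 84%-point JND is
#' `sigma_N / k`. With `per_interval_noise = TRUE` each interval receives an
#' independent draw (effective SD x sqrt(2)). For an MLE observer, two
#' independent noisy percepts are compared.
#'
#' @param obs an observer.
#' @param standard,comparison `ic_stimulus` objects.
#' @param per_interval_noise logical; IC observers only.
#' @return logical: comparison judged deeper.
#' @export
simulate_2ifc <- function(obs, standard, comparison,
                          per_interval_noise = FALSE) {
  UseMethod("simulate_2ifc")
}

#' @export
simulate_2ifc.ic_observer <- function(obs, standard, comparison,
                                      per_interval_noise = FALSE) {
  z_std <- ic_percept(obs, standard)
  z_cmp <- ic_percept(obs, comparison)
  sd_n <- task_noise_sd(obs$task_noise, z_std)
  if (per_interval_noise) sd_n <- sd_n * sqrt(2)
  (z_cmp - z_std + stats::rnorm(1L, 0, sd_n)) > 0
}

#' @export
simulate_2ifc.mle_observer <- function(obs, standard, comparison,
                                       per_interval_noise = FALSE) {
  z_std <- mle_percept_sample(obs, standard)
  z_cmp <- mle_percept_sample(obs, comparison)
  if (!is.null(obs$task_noise)) {
    z_std <- z_std + stats::rnorm(1L, 0, task_noise_sd(obs$task_noise, z_std))
    z_cmp <- z_cmp + stats::rnorm(1L, 0, task_noise_sd(obs$task_noise, z_cmp))
  }
  (z_cmp - z_std) > 0
}
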