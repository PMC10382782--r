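## Deterministic child seeds: one master seed spawns a stable stream per
## subject (and per stage via `salt`), so cohorts are reproducible and
## unchanged by adding subjects. Kept below 2^31 - 1.
child_seed <- function(seed, index, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) %% 100000) * 20011 + index * 7919 + salt * 104729) %%
    2147483647L
}

## A population parameter is a point mass (scalar), a uniform range
## c(lo, hi), or a named list keyed by fixation distance of either.
draw_param <- function(p, distance_cm = NULL) {
  if (is.list(p)) {
    if (is.null(distance_cm)) stop("distance-keyed parameter needs a distance")
    p <- p[[as.character(distance_cm)]]
    if (is.null(p)) stop("no parameter entry for distance ", distance_cm)
  }
  if (length(p) == 1L) return(p)
  if (length(p) == 2L) {
    if (p[2] < p[1]) stop("invalid range: upper bound below lower bound")
    return(stats::runif(1L, p[1], p[2]))
  }
  stop("parameter must be a scalar, a c(lo, hi) range, or a distance-keyed list")
}

#' Population specification for an IC-observer cohort
#'
#' Defaults follow the qualitative pattern of human data at 40/80 cm:
#' disparity is the stronger cue at near fixation and loses strength with
#' distance (the classic failure of depth constancy), texture strengths are
#' similar at both distances, and task noise has Weber fraction ~0.13 with a
#' ~1.66 mm baseline.
#'
#' @param k_texture texture cue strength: scalar, `c(lo, hi)` uniform range,
#'   or a list keyed by distance.
#' @param k_disparity disparity cue strength, same forms.
#' @param weber_W,constant_c task-noise parameters, same forms.
#' @param distances_cm fixation distances the cohort is configured for.
#' @return a population spec of class `ic_population`.
#' @export
ic_population <- function(k_texture = c(0.6, 1.4),
                          k_disparity = list(`40` = c(0.8, 1.8),
                                             `80` = c(0.6, 1.2)),
                          weber_W = 0.13, constant_c = 1.66,
                          distances_cm = c(40, 80)) {
  structure(list(k_texture = k_texture, k_disparity = k_disparity,
                 weber_W = weber_W, constant_c = constant_c,
                 distances_cm = distances_cm),
            class = c("ic_population", "population_spec"))
}

#' Population specification for an MLE-observer cohort
#'
#' @param sigma_texture,sigma_disparity estimation-noise SD (mm) per cue:
#'   scalar, range, or distance-keyed list.
#' @param sigma_flat_texture SD of the textural flatness cue (back-projected
#'   polka dots); small values make flatness reliable and attractive.
#' @param task_noise optional `task_noise_model` added at the response
#'   stage (`NULL`: responses reflect estimation noise only, the configuration
#'   under which the combined-cue SD follows the reliability-combination rule
#'   exactly).
#' @param distances_cm fixation distances.
#' @return a population spec of class `mle_population`.
#' @export
mle_population <- function(sigma_texture = c(1.5, 3),
                           sigma_disparity = list(`40` = c(1, 2),
                                                  `80` = c(1.5, 3)),
                           sigma_flat_texture = 1e6,
                           task_noise = NULL,
                           distances_cm = c(40, 80)) {
  structure(list(sigma_texture = sigma_texture,
                 sigma_disparity = sigma_disparity,
                 sigma_flat_texture = sigma_flat_texture,
                 task_noise = task_noise,
                 distances_cm = distances_cm),
            class = c("mle_population", "population_spec"))
}

#' Draw a cohort of synthetic observers
#'
#' Observer parameters are drawn independently per subject from the
#' population spec, reproducibly under the master seed.
#'
#' @param pop an [ic_population()] or [mle_population()] spec.
#' @param n number of observers.
#' @param seed master seed.
#' @return a list of observers.
#' @export
make_cohort <- function(pop, n, seed) {
  stopifnot(inherits(pop, "population_spec"), n >= 1L)
  lapply(seq_len(n), function(i) {
    set.seed(child_seed(seed, i, salt = 0L))
    draw_observer(pop, sprintf("S%02d", i))
  })
}

draw_observer <- function(pop, id) UseMethod("draw_observer")

#' @export
draw_observer.ic_population <- function(pop, id) {
  strengths <- do.call(rbind, lapply(pop$distances_cm, function(d) {
    data.frame(cue = c("texture", "disparity"), distance_cm = d,
               k = c(draw_param(pop$k_texture, d),
                     draw_param(pop$k_disparity, d)))
  }))
  ic_observer(id, strengths,
              task_noise_model(draw_param(pop$weber_W),
                               draw_param(pop$constant_c)))
}

#' @export
draw_observer.mle_population <- function(pop, id) {
  noises <- do.call(rbind, lapply(pop$distances_cm, function(d) {
    data.frame(cue = c("texture", "disparity", "flat_texture"),
               distance_cm = d,
               sigma = c(draw_param(pop$sigma_texture, d),
                         draw_param(pop$sigma_disparity, d),
                         draw_param(pop$sigma_flat_texture, d)))
  }))
  mle_observer(id, noises, task_noise = pop$task_noise)
}
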