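#' Experiment-1 design (probe adjustment)
#'
#' Defaults mirror the stated factorial: three cue conditions, four
#' peak-to-trough depths, two fixation distances, seven repetitions.
#'
#' @param cues cue conditions.
#' @param depths_mm simulated peak-to-trough depths (mm).
#' @param distances_cm fixation distances (cm).
#' @param reps repetitions per cell.
#' @param texture_null_disparity if `TRUE`, texture-only trials carry a null
#'   disparity field (binocular viewing of the picture plane) instead of no
#'   disparity cue at all; irrelevant for IC observers, consequential for
#'   MLE observers.
#' @return a design list.
#' @export
exp1_design <- function(cues = c("disparity", "texture", "combined"),
                        depths_mm = c(2.5, 5, 10, 15),
                        distances_cm = c(40, 80), reps = 7L,
                        texture_null_disparity = FALSE) {
  stopifnot(length(cues) > 0, length(depths_mm) > 0, length(distances_cm) > 0,
            reps >= 1L, all(depths_mm > 0))
  lapply(cues, cue_label, allow_combined = TRUE)
  list(cues = cues, depths_mm = depths_mm, distances_cm = distances_cm,
       reps = as.integer(reps),
       texture_null_disparity = isTRUE(texture_null_disparity))
}

## Map (cue condition, depth) to the per-cue rendered depths.
cue_depths <- function(cue, z, texture_null_disparity = FALSE) {
  switch(cue,
    disparity = list(z_t = NA_real_, z_d = z, tl = "texture"),
    texture = list(z_t = z,
                   z_d = if (texture_null_disparity) 0 else NA_real_,
                   tl = "texture"),
    combined = list(z_t = z, z_d = z, tl = "texture"),
    stop("unsupported cue condition: ", cue)
  )
}

## Vectorized strength / noise lookups over rows of a trial table.
table_param <- function(tab, value_col, cues, dists) {
  idx <- match(paste(cues, dists), paste(tab$cue, tab$distance_cm))
  if (anyNA(idx)) {
    miss <- unique(paste0(cues, "@", dists)[is.na(idx)])
    stop("observer lacks parameters for: ", paste(miss, collapse = ", "))
  }
  tab[[value_col]][idx]
}

## Vectorized deterministic IC percepts for a trial table with columns
## z_texture_mm, z_disparity_mm, distance_cm.
ic_percept_rows <- function(obs, df) {
  k_t <- table_param(obs$strengths, "k", "texture", df$distance_cm)
  k_d <- table_param(obs$strengths, "k", "disparity", df$distance_cm)
  s_t <- ifelse(is.na(df$z_texture_mm), 0, k_t * df$z_texture_mm)
  s_d <- ifelse(is.na(df$z_disparity_mm), 0, k_d * df$z_disparity_mm)
  sqrt(s_t^2 + s_d^2)
}

## Vectorized probe settings for a trial table; one draw per row.
probe_rows <- function(obs, df) UseMethod("probe_rows")

#' @export
probe_rows.ic_observer <- function(obs, df) {
  z_hat <- ic_percept_rows(obs, df)
  rnorm_trunc0(z_hat, task_noise_sd(obs$task_noise, z_hat))
}

#' @export
probe_rows.mle_observer <- function(obs, df) {
  tl <- if ("texture_label" %in% names(df)) df$texture_label else "texture"
  tl <- rep_len(tl, nrow(df))
  sig_t <- table_param(obs$noises, "sigma", tl, df$distance_cm)
  sig_d <- table_param(obs$noises, "sigma", "disparity", df$distance_cm)
  has_t <- !is.na(df$z_texture_mm)
  has_d <- !is.na(df$z_disparity_mm)
  if (any(!has_t & !has_d)) stop("trial rows without any cue")
  n <- nrow(df)
  draw_t <- stats::rnorm(n, ifelse(has_t, df$z_texture_mm, 0), sig_t)
  draw_d <- stats::rnorm(n, ifelse(has_d, df$z_disparity_mm, 0), sig_d)
  r_t <- ifelse(has_t, 1 / sig_t^2, 0)
  r_d <- ifelse(has_d, 1 / sig_d^2, 0)
  p <- pmax((r_t * draw_t + r_d * draw_d) / (r_t + r_d), 0)
  if (!is.null(obs$task_noise)) {
    p <- rnorm_trunc0(p, task_noise_sd(obs$task_noise, p))
  }
  p
}

#' Simulate an Experiment-1 adjustment dataset
#'
#' Runs the full factorial for each observer in the cohort, with trial order
#' randomised within each fixation-distance block, and returns one row per
#' probe-adjustment trial.
#'
#' @param cohort list of observers (see [make_cohort()]).
#' @param design an [exp1_design()].
#' @param seed master seed; each subject gets a derived child seed.
#' @return a data.frame with columns `subject_id`, `distance_cm`, `cue`,
#'   `z_texture_mm`, `z_disparity_mm`, `z_mm`, `rep`, `probe_mm`.
#' @export
generate_exp1 <- function(cohort, design = exp1_design(), seed = 1L) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  out <- lapply(seq_along(cohort), function(i) {
    obs <- cohort[[i]]
    set.seed(child_seed(seed, i, salt = 1L))
    tab <- expand.grid(cue = design$cues, z_mm = design$depths_mm,
                       rep = seq_len(design$reps),
                       distance_cm = design$distances_cm,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ## randomise presentation order within each distance block
    tab <- do.call(rbind, lapply(split(tab, tab$distance_cm),
                                 function(b) b[sample(nrow(b)), ]))
    zz <- Map(cue_depths, tab$cue, tab$z_mm,
              MoreArgs = list(texture_null_disparity =
                                design$texture_null_disparity))
    tab$z_texture_mm <- vapply(zz, `[[`, numeric(1), "z_t")
    tab$z_disparity_mm <- vapply(zz, `[[`, numeric(1), "z_d")
    tab$probe_mm <- probe_rows(obs, tab)
    tab$subject_id <- obs$id
    rownames(tab) <- NULL
    tab[, c("subject_id", "distance_cm", "cue", "z_texture_mm",
            "z_disparity_mm", "z_mm", "rep", "probe_mm")]
  })
  do.call(rbind, out)
}

#' Simulate an Experiment-3 flatness-cue dataset
#'
#' Variant `"A"` compares monocular viewing of a textured surface (no
#' disparity signal) with binocular viewing of the same picture (null
#' disparity field). Variant `"B"` compares an RDS (no usable texture) with
#' a disparity surface carrying a reliable textural flatness cue
#' (back-projected polka dots). IC observers are constructed to be invariant
#' across each pair; MLE observers are pulled toward flatness when the
#' flat cue is reliable.
#'
#' @param cohort list of observers.
#' @param experiment `"A"` (monocular vs binocular) or `"B"` (RDS vs flat
#'   texture).
#' @param depths_mm,distances_cm,reps design factors.
#' @param seed master seed.
#' @return a data.frame like [generate_exp1()] with an extra
#'   `flatness_condition` column.
#' @export
generate_exp3 <- function(cohort, experiment = c("A", "B"),
                          depths_mm = c(2.5, 5, 10, 15),
                          distances_cm = c(40, 80), reps = 7L, seed = 1L) {
  experiment <- match.arg(experiment)
  conds <- if (experiment == "A") c("monocular", "binocular")
           else c("rds", "flat_texture")
  out <- lapply(seq_along(cohort), function(i) {
    obs <- cohort[[i]]
    set.seed(child_seed(seed, i, salt = 3L))
    tab <- expand.grid(flatness_condition = conds, z_mm = depths_mm,
                       rep = seq_len(reps), distance_cm = distances_cm,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- do.call(rbind, lapply(split(tab, tab$distance_cm),
                                 function(b) b[sample(nrow(b)), ]))
    if (experiment == "A") {
      tab$cue <- "texture"
      tab$z_texture_mm <- tab$z_mm
      tab$z_disparity_mm <- ifelse(tab$flatness_condition == "binocular",
                                   0, NA_real_)
      tab$texture_label <- "texture"
    } else {
      tab$cue <- "disparity"
      tab$z_disparity_mm <- tab$z_mm
      tab$z_texture_mm <- ifelse(tab$flatness_condition == "flat_texture",
                                 0, NA_real_)
      tab$texture_label <- ifelse(tab$flatness_condition == "flat_texture",
                                  "flat_texture", "texture")
    }
    tab$probe_mm <- probe_rows(obs, tab)
    tab$subject_id <- obs$id
    rownames(tab) <- NULL
    tab[, c("subject_id", "distance_cm", "cue", "flatness_condition",
            "z_texture_mm", "z_disparity_mm", "z_mm", "rep", "probe_mm")]
  })
  do.call(rbind, out)
}

## Build a standard/comparison stimulus for a cue condition at depth z.
standard_stimulus <- function(cue, z, distance_cm) {
  zz <- cue_depths(cue, z)
  stimulus(cue, z_texture_mm = zz$z_t, z_disparity_mm = zz$z_d,
           distance_cm = distance_cm, texture_label = zz$tl)
}

#' Simulate an Experiment-2 2IFC staircase dataset
#'
#' For every standard in `standards`, four transformed up-down staircases
#' (2-up/1-down, 1-up/2-down, 3-up/1-down, 1-up/3-down) are interleaved
#' trial by trial until each reaches its reversal target. Staircase
#' placement defaults: rules converging above the 50% point start at 1.5x
#' the standard, the others at 0.5x; the step is 10% of the standard's
#' simulated depth and is halved after the fourth reversal.
#'
#' @param cohort list of observers, whose `id`s must match
#'   `standards$subject_id`.
#' @param standards data.frame with columns `subject_id`, `cue`,
#'   `distance_cm`, `size`, `z_standard_mm` (as produced by
#'   [select_standards()]). Rows with `NA` depth (unmeasurable cells) are
#'   skipped with a warning.
#' @param target_reversals reversals per staircase (default 12).
#' @param step_fraction initial step as a fraction of the standard depth.
#' @param seed master seed.
#' @param max_trials per-staircase safety cap.
#' @return a data.frame with one row per 2IFC trial: `subject_id`,
#'   `distance_cm`, `cue`, `size`, `standard_mm`, `comparison_mm`,
#'   `staircase_rule`, `trial_idx`, `chose_comparison`, `is_reversal`.
#' @export
generate_exp2 <- function(cohort, standards, target_reversals = 12L,
                          step_fraction = 0.1, seed = 1L, max_trials = 400L) {
  stopifnot(is.data.frame(standards),
            all(c("subject_id", "cue", "distance_cm", "size",
                  "z_standard_mm") %in% names(standards)))
  ids <- vapply(cohort, `[[`, character(1), "id")
  n_skipped <- sum(is.na(standards$z_standard_mm))
  if (n_skipped > 0) {
    warning(n_skipped, " unmeasurable standard cell(s) skipped")
  }
  rules <- default_staircase_rules()
  out <- list()
  for (i in seq_along(cohort)) {
    obs <- cohort[[i]]
    set.seed(child_seed(seed, i, salt = 2L))
    std_i <- standards[standards$subject_id == obs$id &
                         !is.na(standards$z_standard_mm), , drop = FALSE]
    for (r in seq_len(nrow(std_i))) {
      row <- std_i[r, ]
      z_std <- row$z_standard_mm
      std_stim <- standard_stimulus(row$cue, z_std, row$distance_cm)
      states <- lapply(rules, function(rl) {
        start <- if (rl$n_down > 1L) 1.5 * z_std else 0.5 * z_std
        cfg <- staircase_config(rl, start_mm = start,
                                step_mm = step_fraction * z_std,
                                target_reversals = target_reversals)
        list(cfg = cfg, st = staircase_init(cfg), trials = 0L)
      })
      trial_idx <- 0L
      recs <- list()
      repeat {
        open <- which(!vapply(states, function(s) s$st$finished, logical(1)))
        if (length(open) == 0L) break
        j <- if (length(open) == 1L) open else sample(open, 1L)
        sc <- states[[j]]
        if (sc$trials >= max_trials) {
          stop("staircase exceeded the safety cap of ", max_trials,
               " trials (subject ", obs$id, ", ", row$cue, ")")
        }
        comp_z <- sc$st$value
        resp <- simulate_2ifc(obs, std_stim,
                              standard_stimulus(row$cue, comp_z,
                                                row$distance_cm))
        sc$st <- staircase_update(sc$st, sc$cfg, resp)
        sc$trials <- sc$trials + 1L
        states[[j]] <- sc
        trial_idx <- trial_idx + 1L
        recs[[trial_idx]] <- data.frame(
          subject_id = obs$id, distance_cm = row$distance_cm,
          cue = row$cue, size = row$size, standard_mm = z_std,
          comparison_mm = comp_z,
          staircase_rule = format_rule(sc$cfg$rule),
          trial_idx = trial_idx, chose_comparison = resp,
          is_reversal = sc$st$last_was_reversal)
      }
      out[[length(out) + 1L]] <- do.call(rbind, recs)
    }
  }
  if (length(out) == 0L) stop("no measurable standards to run")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
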