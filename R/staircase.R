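#' Transformed up-down staircase rule
#'
#' The four rules used for 2IFC depth discrimination are 1-up/2-down,
#' 2-up/1-down, 1-up/3-down and 3-up/1-down. Exactly one of the two counts
#' must equal 1.
#'
#' @param n_up number of consecutive "not deeper" responses required to move
#'   the comparison up.
#' @param n_down number of consecutive "deeper" responses required to move
#'   the comparison down.
#' @return an object of class `staircase_rule`.
#' @export
staircase_rule <- function(n_up, n_down) {
  stopifnot(length(n_up) == 1L, length(n_down) == 1L,
            n_up == as.integer(n_up), n_down == as.integer(n_down))
  n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up < 1L || n_down < 1L) stop("n_up and n_down must be >= 1")
  if (sum(c(n_up, n_down) == 1L) != 1L) {
    stop("exactly one of n_up, n_down must equal 1 (transformed up-down rule)")
  }
  structure(list(n_up = n_up, n_down = n_down),
            class = "staircase_rule")
}

#' @rdname staircase_rule
#' @param rule a `staircase_rule`.
#' @return `format_rule()`: a label such as `"1up2down"`.
#' @export
format_rule <- function(rule) {
  stopifnot(inherits(rule, "staircase_rule"))
  paste0(rule$n_up, "up", rule$n_down, "down")
}

#' Convergence point of a transformed up-down rule
#'
#' The proportion of "deeper" responses at which the expected movement of the
#' staircase is zero: `0.5^(1/m)` for 1-up/m-down, `1 - 0.5^(1/m)` for
#' m-up/1-down.
#'
#' @param rule a `staircase_rule`.
#' @return the target response probability.
#' @export
convergence_point <- function(rule) {
  stopifnot(inherits(rule, "staircase_rule"))
  if (rule$n_up == 1L) 0.5^(1 / rule$n_down) else 1 - 0.5^(1 / rule$n_up)
}

#' Staircase configuration
#'
#' @param rule a `staircase_rule`.
#' @param start_mm starting comparison value (mm).
#' @param step_mm initial step size (mm).
#' @param target_reversals reversals at which the staircase terminates
#'   (default 12).
#' @param floor_mm lowest allowed comparison value (default 0.05 mm).
#' @param halve_after_reversal halve the step once this many reversals have
#'   occurred (`Inf` disables the schedule).
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(rule, start_mm, step_mm,
                             target_reversals = 12L, floor_mm = 0.05,
                             halve_after_reversal = 4L) {
  stopifnot(inherits(rule, "staircase_rule"),
            is.numeric(start_mm), is.numeric(step_mm),
            is.numeric(floor_mm), target_reversals >= 1L)
  if (step_mm <= 0) stop("step_mm must be > 0")
  if (floor_mm < 0 || start_mm <= floor_mm) {
    stop("need start_mm > floor_mm >= 0")
  }
  structure(
    list(rule = rule, start_mm = start_mm, step_mm = step_mm,
         target_reversals = as.integer(target_reversals),
         floor_mm = floor_mm, halve_after_reversal = halve_after_reversal),
    class = "staircase_config"
  )
}

#' Initialise staircase bookkeeping
#'
#' @param config a `staircase_config`.
#' @return an object of class `staircase_state`.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(value = config$start_mm, step = config$step_mm,
         up_count = 0L, down_count = 0L,
         last_move = 0L,              # -1 down, +1 up, 0 none yet
         reversal_count = 0L, trial = 0L,
         halved = FALSE, finished = FALSE,
         last_was_reversal = FALSE),
    class = "staircase_state"
  )
}

#' Advance a staircase by one response
#'
#' Updates the consecutive-response counters, moves the comparison value when
#' the rule's count is reached, flags direction changes as reversals, halves
#' the step once the configured reversal is passed, and floors the value.
#'
#' @param state a `staircase_state`.
#' @param config the `staircase_config` the state was initialised from.
#' @param comparison_judged_deeper logical response for the trial just run at
#'   `state$value`.
#' @return the updated `staircase_state`; `$last_was_reversal` flags whether
#'   this response produced a reversal, `$finished` whether the target
#'   reversal count has been reached.
#' @export
staircase_update <- function(state, config, comparison_judged_deeper) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(config, "staircase_config"),
            is.logical(comparison_judged_deeper),
            length(comparison_judged_deeper) == 1L,
            !is.na(comparison_judged_deeper))
  if (state$finished) stop("staircase already finished; no further updates")
  rule <- config$rule
  state$trial <- state$trial + 1L
  state$last_was_reversal <- FALSE
  move <- 0L
  if (comparison_judged_deeper) {
    state$down_count <- state$down_count + 1L
    state$up_count <- 0L
    if (state$down_count >= rule$n_down) {
      move <- -1L
      state$down_count <- 0L
    }
  } else {
    state$up_count <- state$up_count + 1L
    state$down_count <- 0L
    if (state$up_count >= rule$n_up) {
      move <- 1L
      state$up_count <- 0L
    }
  }
  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversal_count <- state$reversal_count + 1L
      state$last_was_reversal <- TRUE
      if (!state$halved &&
          state$reversal_count >= config$halve_after_reversal) {
        state$step <- state$step / 2
        state$halved <- TRUE
      }
      if (state$reversal_count >= config$target_reversals) {
        state$finished <- TRUE
      }
    }
    state$last_move <- move
    state$value <- max(config$floor_mm, state$value + move * state$step)
  }
  state
}

#' Run a staircase against a responder
#'
#' @param responder a function taking a comparison value (mm) and returning a
#'   logical "comparison judged deeper" response.
#' @param config a `staircase_config`.
#' @param max_trials safety cap; exceeding it aborts with a diagnostic
#'   (default 400).
#' @return a data.frame with one row per trial: `trial_idx`,
#'   `comparison_mm` (value presented), `chose_comparison`, `is_reversal`.
#' @export
run_staircase <- function(responder, config, max_trials = 400L) {
  stopifnot(is.function(responder), inherits(config, "staircase_config"))
  state <- staircase_init(config)
  values <- numeric(0); resps <- logical(0); revs <- logical(0)
  while (!state$finished) {
    if (state$trial >= max_trials) {
      stop("staircase exceeded the safety cap of ", max_trials,
           " trials with only ", state$reversal_count, "/",
           config$target_reversals, " reversals")
    }
    presented <- state$value
    resp <- isTRUE(responder(presented))
    state <- staircase_update(state, config, resp)
    values <- c(values, presented)
    resps <- c(resps, resp)
    revs <- c(revs, state$last_was_reversal)
  }
  data.frame(trial_idx = seq_along(values),
             comparison_mm = values,
             chose_comparison = resps,
             is_reversal = revs)
}

## The four rules of the 2IFC design, bracketing the PSE from both sides.
default_staircase_rules <- function() {
  list(staircase_rule(2, 1), staircase_rule(1, 2),
       staircase_rule(3, 1), staircase_rule(1, 3))
}
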