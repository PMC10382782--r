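#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `P(choose comparison) = lapse/2 + (1 - lapse) * Phi((x - mu)/sigma)`
#' to binary 2IFC data. The lapse rate is fixed (default 0.02) because
#' staircase sampling concentrates trials near threshold and cannot identify
#' it. A multi-start grid over (mu, sigma) precedes box-constrained
#' optimisation to avoid local optima.
#'
#' @param x comparison values (mm).
#' @param response logical (or 0/1): comparison chosen as deeper.
#' @param lapse fixed lapse rate in `[0, 0.06]`.
#' @param min_trials minimum number of trials required (default 20).
#' @param sigma_bounds bounds for sigma (mm).
#' @return an object of class `psychometric_fit` with elements `pse`,
#'   `sigma`, `lapse`, `loglik`, `n_trials`, `converged`, `boundary`.
#' @export
fit_cumulative_gaussian <- function(x, response, lapse = 0.02,
                                    min_trials = 20L,
                                    sigma_bounds = c(0.01, 50)) {
  response <- as.logical(response)
  stopifnot(is.numeric(x), length(x) == length(response), !anyNA(x),
            !anyNA(response))
  if (length(x) < min_trials) {
    stop("need at least ", min_trials, " trials (got ", length(x), ")")
  }
  if (length(unique(response)) < 2L) {
    stop("non-identifiable: all responses in one category")
  }
  if (lapse < 0 || lapse > 0.06) stop("lapse must be in [0, 0.06]")

  ## reject label-flipped data: a reliably decreasing response function
  ## cannot be a cumulative Gaussian in this parameterisation
  b <- suppressWarnings(stats::glm(response ~ x, family = stats::binomial()))
  bz <- summary(b)$coefficients
  if (nrow(bz) >= 2L && bz[2L, 1L] < 0 && bz[2L, 3L] < -2) {
    stop("psychometric function appears to be decreasing in x; ",
         "check response coding")
  }

  nll <- function(par) {
    mu <- par[1L]; sigma <- exp(par[2L])
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((x - mu) / sigma)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(log(ifelse(response, p, 1 - p)))
  }

  sdx <- max(stats::sd(x), 1e-3)
  mu_grid <- unique(stats::quantile(x, seq(0.15, 0.85, length.out = 7),
                                    names = FALSE))
  sg_grid <- pmin(pmax(sdx * c(0.1, 0.25, 0.5, 1, 2), sigma_bounds[1L]),
                  sigma_bounds[2L])
  starts <- expand.grid(mu = mu_grid, ls = log(unique(sg_grid)))
  vals <- apply(starts, 1L, nll)
  best <- as.numeric(starts[which.min(vals), ])

  lb <- c(min(x) - 2 * sdx, log(sigma_bounds[1L]))
  ub <- c(max(x) + 2 * sdx, log(sigma_bounds[2L]))
  opt <- stats::optim(best, nll, method = "L-BFGS-B", lower = lb, upper = ub)

  sigma <- exp(opt$par[2L])
  ## perfectly separable data: sigma is only bounded above by the data and
  ## the ML estimate degenerates toward 0 -- flag rather than report
  separable <- max(x[!response]) < min(x[response])
  boundary <- separable || sigma <= sigma_bounds[1L] * 1.0001 ||
    sigma >= sigma_bounds[2L] * 0.9999
  structure(
    list(pse = opt$par[1L], sigma = sigma, lapse = lapse,
         loglik = -opt$value, n_trials = length(x),
         converged = opt$convergence == 0L && !boundary,
         boundary = boundary),
    class = "psychometric_fit"
  )
}

#' Extract PSE and JND from a psychometric fit
#'
#' The PSE is the 50% point (`mu` for this parameterisation) and the JND
#' the distance from the PSE to the 84% point, computed through the
#' lapse-adjusted curve: `JND = sigma * qnorm((p - lapse/2)/(1 - lapse))`
#' with `p = 0.84`, which reduces to `0.9945 * sigma` at zero lapse.
#'
#' @param fit a converged `psychometric_fit`.
#' @param criterion response probability defining the JND (default 0.84).
#' @return a list with `pse` and `jnd` (mm).
#' @export
extract_pse_jnd <- function(fit, criterion = 0.84) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge (or hit the sigma bound); no PSE/JND")
  }
  q <- (criterion - fit$lapse / 2) / (1 - fit$lapse)
  if (q <= 0.5 || q >= 1) stop("criterion not reachable under this lapse rate")
  list(pse = fit$pse, jnd = fit$sigma * stats::qnorm(q))
}

#' Fit psychometric functions to an Experiment-2 trial table
#'
#' Fits one cumulative Gaussian per (subject, cue, distance, standard size).
#' The default pools the four staircases' trials into one fit (more stable
#' at 12 reversals each); `mode = "per_staircase"` instead fits each
#' staircase separately and averages the resulting PSEs and JNDs.
#'
#' @param trials a trial table from [generate_exp2()].
#' @param mode `"pooled"` or `"per_staircase"`.
#' @param lapse fixed lapse rate.
#' @return a data.frame of JND records: `subject_id`, `cue`, `distance_cm`,
#'   `size`, `standard_mm`, `pse_mm`, `jnd_mm`, `n_trials`, `converged`.
#' @export
analyze_exp2 <- function(trials, mode = c("pooled", "per_staircase"),
                         lapse = 0.02) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trials),
            all(c("subject_id", "cue", "distance_cm", "size", "standard_mm",
                  "comparison_mm", "staircase_rule",
                  "chose_comparison") %in% names(trials)))
  key <- interaction(trials$subject_id, trials$cue, trials$distance_cm,
                     trials$size, drop = TRUE)
  out <- lapply(split(trials, key), function(g) {
    fit1 <- function(d) {
      f <- tryCatch(
        fit_cumulative_gaussian(d$comparison_mm, d$chose_comparison,
                                lapse = lapse),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) return(c(NA_real_, NA_real_, 0))
      pj <- extract_pse_jnd(f)
      c(pj$pse, pj$jnd, 1)
    }
    if (mode == "pooled") {
      v <- fit1(g)
    } else {
      per <- vapply(split(g, g$staircase_rule), fit1, numeric(3))
      ok <- per[3, ] == 1
      v <- if (any(ok)) c(rowMeans(per[1:2, ok, drop = FALSE]), 1)
           else c(NA_real_, NA_real_, 0)
    }
    data.frame(subject_id = g$subject_id[1L], cue = g$cue[1L],
               distance_cm = g$distance_cm[1L], size = g$size[1L],
               standard_mm = g$standard_mm[1L],
               pse_mm = v[1L], jnd_mm = v[2L],
               n_trials = nrow(g), converged = v[3L] == 1)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
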