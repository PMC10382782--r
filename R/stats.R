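## All subsets of a character vector, ordered by size (excluding empty set).
subsets_of <- function(x) {
  out <- list()
  for (k in seq_along(x)) {
    cmb <- utils::combn(x, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

term_name <- function(s) paste(sort(s), collapse = ":")

#' Repeated-measures ANOVA for a balanced fully-within design
#'
#' Classical sum-of-squares decomposition for a balanced, fully crossed
#' within-subject design with one (pre-aggregated) value per subject x
#' cell. Each within effect is tested against its interaction with
#' subjects; generalized eta squared uses all subject-involving terms as the
#' error pool (the standard form for fully within designs).
#'
#' @param data data.frame with one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject column.
#' @param within character vector of within-subject factor columns.
#' @return data.frame with `effect`, `df_num`, `df_den`, `F`, `p`, `ges`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data), all(within %in% names(data)),
            length(within) >= 1L)
  facs <- c(subject, within)
  fd <- data[facs]
  fd[] <- lapply(fd, function(v) factor(v))
  if (any(table(fd) != 1L)) {
    stop("design is not balanced with one value per subject x cell; ",
         "pre-aggregate to cell means first (no imputation is done)")
  }
  y <- data[[dv]]
  if (anyNA(y)) stop("missing values in the dependent variable")
  grand <- mean(y)

  ## observation-level effect components by inclusion-exclusion over terms
  comps <- list()
  for (s in subsets_of(facs)) {
    nm <- term_name(s)
    cellmean <- stats::ave(y, fd[s], FUN = mean)
    eff <- cellmean - grand
    for (k in seq_len(length(s) - 1L)) {
      for (sub in utils::combn(s, k, simplify = FALSE)) {
        eff <- eff - comps[[term_name(sub)]]
      }
    }
    comps[[nm]] <- eff
  }
  ss <- vapply(comps, function(e) sum(e^2), numeric(1))
  nlev <- vapply(fd, nlevels, integer(1))
  df_of <- function(s) prod(nlev[s] - 1L)
  subj_terms <- names(ss)[vapply(names(ss), function(nm) {
    subject %in% strsplit(nm, ":", fixed = TRUE)[[1L]]
  }, logical(1))]
  ss_subj_pool <- sum(ss[subj_terms])

  ss_tol <- 1e-12 * max(sum(ss), 1)   # numerical zero for exact effects
  out <- lapply(subsets_of(within), function(a) {
    nm <- term_name(a)
    err <- term_name(c(a, subject))
    dfn <- df_of(a); dfe <- df_of(c(a, subject))
    fval <- if (ss[[nm]] <= ss_tol) 0
            else (ss[[nm]] / dfn) / (ss[[err]] / dfe)
    data.frame(effect = nm, df_num = dfn, df_den = dfe, F = fval,
               p = stats::pf(fval, dfn, dfe, lower.tail = FALSE),
               ges = ss[[nm]] / (ss[[nm]] + ss_subj_pool))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni-corrected paired t tests
#'
#' @param pairs a named list of `list(x =, y =)` paired samples.
#' @param m number of comparisons the correction is for (default
#'   `length(pairs)`).
#' @return data.frame with `comparison`, `t`, `df`, `p`, `p_adjusted`,
#'   `mean_diff`.
#' @export
paired_t_bonferroni <- function(pairs, m = length(pairs)) {
  stopifnot(is.list(pairs), length(pairs) >= 1L, m >= 1L)
  nms <- names(pairs) %||% paste0("pair", seq_along(pairs))
  out <- Map(function(p, nm) {
    stopifnot(length(p$x) == length(p$y))
    d <- p$x - p$y
    if (length(d) < 2L) stop("paired t test needs n >= 2")
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(data.frame(comparison = nm, t = 0, df = length(d) - 1L,
                          p = 1, p_adjusted = 1, mean_diff = 0))
      }
      stop("zero variance of non-zero differences in '", nm,
           "'; t statistic undefined")
    }
    tt <- stats::t.test(p$x, p$y, paired = TRUE)
    data.frame(comparison = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_adjusted = min(1, tt$p.value * m),
               mean_diff = unname(tt$estimate))
  }, pairs, nms)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits `y = X beta + b_subject + e` with `b ~ N(0, tau2)`,
#' `e ~ N(0, sigma2)` by maximising the likelihood profiled down to the
#' one-dimensional variance ratio `lambda = tau2/sigma2`; `lambda = 0`
#' (ordinary regression) is included as a candidate so the boundary is
#' handled exactly.
#'
#' @param data data.frame.
#' @param fixed one-sided or two-sided formula for the fixed effects, e.g.
#'   `probe_mm ~ z_mm + cue`.
#' @param subject name of the grouping column.
#' @return an object of class `ri_lmm_fit`: `loglik`, `bic`, `aic`, `beta`,
#'   `sigma2`, `tau2`, `lambda`, `n`, `n_par`, `converged`.
#' @export
fit_random_intercept_lmm <- function(data, fixed, subject) {
  stopifnot(is.data.frame(data), inherits(fixed, "formula"),
            subject %in% names(data))
  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fixed, mf)
  g <- factor(data[[subject]])
  stopifnot(length(y) == length(g))
  n <- length(y)
  idx <- split(seq_len(n), g)
  ng <- lengths(idx)

  ## per-group sufficient statistics
  XtX_g <- lapply(idx, function(ii) crossprod(X[ii, , drop = FALSE]))
  Xs_g <- lapply(idx, function(ii) colSums(X[ii, , drop = FALSE]))
  Xty_g <- lapply(idx, function(ii) crossprod(X[ii, , drop = FALSE], y[ii]))
  ys_g <- vapply(idx, function(ii) sum(y[ii]), numeric(1))
  yty_g <- vapply(idx, function(ii) sum(y[ii]^2), numeric(1))

  profile_ll <- function(lambda) {
    a <- lambda / (1 + ng * lambda)
    XtVX <- Reduce(`+`, Map(function(M, s, ai) M - ai * tcrossprod(s),
                            XtX_g, Xs_g, as.list(a)))
    XtVy <- Reduce(`+`, Map(function(v, s, ai, yi) v - ai * s * yi,
                            Xty_g, Xs_g, as.list(a), as.list(ys_g)))
    ytVy <- sum(yty_g - a * ys_g^2)
    beta <- solve(XtVX, XtVy)
    rss <- ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(1 + ng * lambda)) + n)
    list(ll = ll, beta = beta, sigma2 = sigma2)
  }

  opt <- stats::optimize(function(loglam) -profile_ll(exp(loglam))$ll,
                         interval = c(-15, 10))
  lambda <- exp(opt$minimum)
  cand <- list(`0` = profile_ll(0), fit = profile_ll(lambda))
  best <- which.max(vapply(cand, `[[`, numeric(1), "ll"))
  fit <- cand[[best]]
  if (best == 1L) lambda <- 0
  n_par <- ncol(X) + 2L
  structure(
    list(loglik = fit$ll, bic = -2 * fit$ll + n_par * log(n),
         aic = -2 * fit$ll + 2 * n_par,
         beta = drop(fit$beta), sigma2 = fit$sigma2,
         tau2 = lambda * fit$sigma2, lambda = lambda, n = n, n_par = n_par,
         converged = is.finite(fit$ll), fixed = fixed),
    class = "ri_lmm_fit"
  )
}

#' BIC-approximate Bayes factor for nested mixed models
#'
#' `BF01 = exp((BIC_full - BIC_null)/2)`: values above 1 favour the null
#' (reduced) model. This is the standard unit-information-prior
#' approximation; it is not a JZS Bayes factor.
#'
#' @param fit_null,fit_full `ri_lmm_fit` objects on the same data, with
#'   nested fixed effects.
#' @return a list with `loglik0`, `loglik1`, `bic0`, `bic1`, `bf01`.
#' @export
bic_bayes_factor <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "ri_lmm_fit"), inherits(fit_full, "ri_lmm_fit"))
  if (fit_null$n != fit_full$n) {
    stop("models were fit to different numbers of observations")
  }
  list(loglik0 = fit_null$loglik, loglik1 = fit_full$loglik,
       bic0 = fit_null$bic, bic1 = fit_full$bic,
       bf01 = exp((fit_full$bic - fit_null$bic) / 2))
}
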