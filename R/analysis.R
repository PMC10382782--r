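#' Estimate cue strengths from adjustment data
#'
#' Ordinary least-squares line per (subject, cue condition, distance) cell
#' mapping simulated to perceived depth; the slope is reported as the cue
#' strength `k`. A free intercept (default) absorbs probe-calibration
#' offsets; `intercept = FALSE` forces the theoretical zero-intercept form.
#'
#' @param exp1 adjustment trial table (see [generate_exp1()]).
#' @param intercept fit a free intercept?
#' @return data.frame with `subject_id`, `cue`, `distance_cm`, `k`,
#'   `intercept`, `r_squared`, `n`, `degenerate` (constant responses).
#' @export
estimate_cue_strengths <- function(exp1, intercept = TRUE) {
  stopifnot(is.data.frame(exp1),
            all(c("subject_id", "cue", "distance_cm", "z_mm",
                  "probe_mm") %in% names(exp1)))
  key <- interaction(exp1$subject_id, exp1$cue, exp1$distance_cm, drop = TRUE)
  out <- lapply(split(exp1, key), function(g) {
    if (length(unique(g$z_mm)) < 2L) {
      stop("need >= 2 distinct simulated depths per cell to fit a slope")
    }
    degenerate <- stats::sd(g$probe_mm) == 0
    fml <- if (intercept) probe_mm ~ z_mm else probe_mm ~ 0 + z_mm
    fit <- stats::lm(fml, data = g)
    co <- stats::coef(fit)
    k <- unname(co[["z_mm"]])
    b0 <- if (intercept) unname(co[["(Intercept)"]]) else 0
    ## suppressWarnings: summary.lm warns on (legitimate) noiseless fits
    r2 <- if (degenerate) NA_real_
          else suppressWarnings(summary(fit)$r.squared)
    data.frame(subject_id = g$subject_id[1L], cue = g$cue[1L],
               distance_cm = g$distance_cm[1L], k = k, intercept = b0,
               r_squared = r2, n = nrow(g), degenerate = degenerate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameter-free combined-cue prediction and origin regression
#'
#' For each subject and fixation distance with both single-cue slopes and a
#' combined-cue slope, predicts `k_c = sqrt(k_t^2 + k_d^2)` with no free
#' parameters and regresses observed on predicted combined strengths through
#' the origin.
#'
#' @param strengths output of [estimate_cue_strengths()].
#' @return a list with `records` (subject, distance, observed, predicted,
#'   model) and `regression` (`slope`, `se_slope`, `r`, `n`).
#' @export
predict_and_compare_combined <- function(strengths) {
  stopifnot(is.data.frame(strengths),
            all(c("subject_id", "cue", "distance_cm", "k") %in%
                  names(strengths)))
  key <- interaction(strengths$subject_id, strengths$distance_cm, drop = TRUE)
  recs <- lapply(split(strengths, key), function(g) {
    kt <- g$k[g$cue == "texture"]; kd <- g$k[g$cue == "disparity"]
    kc <- g$k[g$cue == "combined"]
    if (length(kt) != 1L || length(kd) != 1L || length(kc) != 1L) {
      message("skipping cell with missing slopes: ", g$subject_id[1L], " @ ",
              g$distance_cm[1L], " cm")
      return(NULL)
    }
    data.frame(subject_id = g$subject_id[1L], distance_cm = g$distance_cm[1L],
               observed = kc,
               predicted = combined_strength(c(max(kt, 0), max(kd, 0))),
               model = "vector_sum")
  })
  records <- do.call(rbind, recs)
  if (is.null(records) || nrow(records) < 2L) {
    stop("not enough complete cells for the origin regression")
  }
  rownames(records) <- NULL
  fit <- stats::lm(observed ~ 0 + predicted, data = records)
  ## suppressWarnings: summary.lm warns when the prediction is exact
  sm <- suppressWarnings(summary(fit))$coefficients
  list(records = records,
       regression = list(slope = unname(sm[1L, 1L]),
                         se_slope = unname(sm[1L, 2L]),
                         r = stats::cor(records$observed, records$predicted),
                         n = nrow(records)))
}

#' Adjustment-SD analysis with MLE-predicted combined SD
#'
#' Computes the per-cell sample SD of probe settings and, wherever both
#' single-cue SDs exist for a (subject, distance, depth) triple, the
#' reliability-combination prediction for the combined-cue SD.
#'
#' @param exp1 adjustment trial table.
#' @param min_reps minimum repetitions for a cell to be kept (default 3).
#' @return a list with `sd_table` (per-cell SDs) and `mle_prediction`
#'   (observed vs predicted combined SD per subject/distance/depth).
#' @export
adjustment_sd_analysis <- function(exp1, min_reps = 3L) {
  stopifnot(is.data.frame(exp1))
  key <- interaction(exp1$subject_id, exp1$cue, exp1$distance_cm, exp1$z_mm,
                     drop = TRUE)
  cells <- lapply(split(exp1, key), function(g) {
    if (nrow(g) < min_reps) return(NULL)
    data.frame(subject_id = g$subject_id[1L], cue = g$cue[1L],
               distance_cm = g$distance_cm[1L], z_mm = g$z_mm[1L],
               sd_mm = stats::sd(g$probe_mm), n = nrow(g))
  })
  sd_table <- do.call(rbind, cells)
  if (is.null(sd_table)) stop("no cell has >= ", min_reps, " repetitions")
  rownames(sd_table) <- NULL
  key2 <- interaction(sd_table$subject_id, sd_table$distance_cm,
                      sd_table$z_mm, drop = TRUE)
  preds <- lapply(split(sd_table, key2), function(g) {
    st <- g$sd_mm[g$cue == "texture"]; sd_ <- g$sd_mm[g$cue == "disparity"]
    sc <- g$sd_mm[g$cue == "combined"]
    if (length(st) != 1L || length(sd_) != 1L || length(sc) != 1L ||
        any(c(st, sd_) <= 0)) return(NULL)
    data.frame(subject_id = g$subject_id[1L], distance_cm = g$distance_cm[1L],
               z_mm = g$z_mm[1L], sd_combined_obs = sc,
               sd_combined_pred = mle_combined_sigma(c(st, sd_)))
  })
  list(sd_table = sd_table, mle_prediction = do.call(rbind, preds))
}

## Fit perceived = a + b z + c z^2 to per-depth means; return coefficients.
quad_fit <- function(z, y) {
  m <- tapply(y, z, mean)
  zz <- as.numeric(names(m))
  if (length(zz) < 3L) stop("need >= 3 distinct depths for a quadratic fit")
  stats::coef(stats::lm(m ~ zz + I(zz^2)))
}

quad_eval <- function(co, z) co[[1L]] + co[[2L]] * z + co[[3L]] * z^2

## Root of a + b z + c z^2 = target, preferring the root inside `range`.
quad_invert <- function(co, target, range) {
  a <- co[[1L]] - target; b <- co[[2L]]; cc <- co[[3L]]
  if (abs(cc) < 1e-12) {            # effectively linear
    if (abs(b) < 1e-12) return(list(z = NA_real_, extrapolated = FALSE))
    roots <- -a / b
  } else {
    disc <- b^2 - 4 * cc * a
    if (disc < 0) return(list(z = NA_real_, extrapolated = FALSE))
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * cc)
  }
  tol <- 1e-8
  inside <- roots[roots >= range[1L] - tol & roots <= range[2L] + tol]
  if (length(inside) > 0L) {
    return(list(z = min(inside), extrapolated = FALSE))
  }
  pos <- roots[roots > 0]
  if (length(pos) == 0L) return(list(z = NA_real_, extrapolated = FALSE))
  dist <- pmin(abs(pos - range[1L]), abs(pos - range[2L]))
  list(z = pos[which.min(dist)], extrapolated = TRUE)
}

#' Select perceived-depth-matched standards for 2IFC testing
#'
#' Per subject and fixation distance, fits a second-order curve of perceived
#' versus simulated depth for each cue condition, anchors two target
#' perceived depths (the small standard at the greatest perceived depth
#' reached at the lowest simulated depth, the large standard at the smallest
#' perceived depth reached at the highest), and inverts each cue's curve to
#' find the simulated depth eliciting each target. All three cues' standards
#' for a given size are thereby matched in perceived depth.
#'
#' @param exp1 adjustment trial table.
#' @param depth_range stimulus range used for anchoring and root selection
#'   (default `c(2.5, 15)` mm).
#' @param nonmonotone `"flag"` (default; cell marked unmeasurable with a
#'   warning) or `"error"` when a fitted curve is not increasing on the
#'   range.
#' @return data.frame with `subject_id`, `cue`, `distance_cm`, `size`
#'   (`"small"`/`"large"`), `z_standard_mm`, `target_perceived_mm`,
#'   `extrapolated`.
#' @export
select_standards <- function(exp1, depth_range = c(2.5, 15),
                             nonmonotone = c("flag", "error")) {
  nonmonotone <- match.arg(nonmonotone)
  stopifnot(is.data.frame(exp1))
  key <- interaction(exp1$subject_id, exp1$distance_cm, drop = TRUE)
  out <- lapply(split(exp1, key), function(g) {
    cues <- unique(g$cue)
    fits <- lapply(split(g, g$cue), function(gg) {
      quad_fit(gg$z_mm, gg$probe_mm)
    })
    monotone <- vapply(fits, function(co) {
      ## derivative b + 2 c z is linear: check both endpoints
      all(co[[2L]] + 2 * co[[3L]] * depth_range > 0)
    }, logical(1))
    if (any(!monotone)) {
      msg <- paste0("non-monotone perceived-depth fit for ",
                    g$subject_id[1L], " @ ", g$distance_cm[1L], " cm (",
                    paste(names(fits)[!monotone], collapse = ", "), ")")
      if (nonmonotone == "error") stop(msg)
      warning(msg, call. = FALSE)
    }
    usable <- names(fits)[monotone]
    if (length(usable) == 0L) return(NULL)
    target_small <- max(vapply(fits[usable], quad_eval, numeric(1),
                               z = depth_range[1L]))
    target_large <- min(vapply(fits[usable], quad_eval, numeric(1),
                               z = depth_range[2L]))
    do.call(rbind, lapply(cues, function(cu) {
      do.call(rbind, Map(function(size, target) {
        if (!(cu %in% usable)) {
          z <- NA_real_; ex <- FALSE
        } else {
          inv <- quad_invert(fits[[cu]], target, depth_range)
          z <- inv$z; ex <- inv$extrapolated
        }
        data.frame(subject_id = g$subject_id[1L], cue = cu,
                   distance_cm = g$distance_cm[1L], size = size,
                   z_standard_mm = z, target_perceived_mm = target,
                   extrapolated = ex)
      }, c("small", "large"), c(target_small, target_large)))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Vector-sum prediction of the combined-cue JND
#'
#' Because the standards are matched in perceived depth, the task noise is
#' matched across cue conditions and the combined JND is predicted directly
#' from the single-cue JNDs measured at the same perceived depth:
#' `J_c = 1/sqrt(1/J_t^2 + 1/J_d^2)`. A missing single-cue JND
#' (unmeasurable cell) degrades gracefully to the remaining cue's JND.
#'
#' @param jnd_records output of [analyze_exp2()].
#' @return data.frame of prediction records: `subject_id`, `distance_cm`,
#'   `size`, `observed`, `predicted`, `model`.
#' @export
predict_jnd_vector_sum <- function(jnd_records) {
  stopifnot(is.data.frame(jnd_records))
  j <- jnd_records[!is.na(jnd_records$jnd_mm), , drop = FALSE]
  key <- interaction(j$subject_id, j$distance_cm, j$size, drop = TRUE)
  out <- lapply(split(j, key), function(g) {
    singles <- g$jnd_mm[g$cue %in% c("texture", "disparity")]
    obs <- g$jnd_mm[g$cue == "combined"]
    if (length(singles) == 0L || length(obs) != 1L) return(NULL)
    data.frame(subject_id = g$subject_id[1L], distance_cm = g$distance_cm[1L],
               size = g$size[1L], observed = obs,
               predicted = combine_jnds(singles), model = "vector_sum")
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no complete cells with a combined-cue JND")
  rownames(res) <- NULL
  res
}

#' MLE prediction of the combined-cue JND
#'
#' The reliability-combination rule is applied at matched *simulated* depth:
#' per single cue, the JND-versus-pedestal relationship is taken as the line
#' through the measured (pedestal, JND) points, evaluated at the combined
#' standard's simulated depth, and the interpolated JNDs are combined. With
#' two pedestals per cue the line passes through them exactly. Negative
#' extrapolations are floored at a small positive value and flagged.
#'
#' @param jnd_records output of [analyze_exp2()].
#' @param floor_mm floor for extrapolated JNDs (default 0.01).
#' @return data.frame of prediction records with columns as in
#'   [predict_jnd_vector_sum()] plus `floored`.
#' @export
predict_jnd_mle <- function(jnd_records, floor_mm = 0.01) {
  stopifnot(is.data.frame(jnd_records))
  j <- jnd_records[!is.na(jnd_records$jnd_mm), , drop = FALSE]
  key <- interaction(j$subject_id, j$distance_cm, drop = TRUE)
  out <- lapply(split(j, key), function(g) {
    comb <- g[g$cue == "combined", , drop = FALSE]
    if (nrow(comb) == 0L) return(NULL)
    lines <- lapply(split(g[g$cue %in% c("texture", "disparity"), ],
                          g$cue[g$cue %in% c("texture", "disparity")],
                          drop = TRUE),
                    function(gg) {
      if (nrow(gg) < 2L || length(unique(gg$standard_mm)) < 2L) return(NULL)
      stats::coef(stats::lm(jnd_mm ~ standard_mm, data = gg))
    })
    lines <- Filter(Negate(is.null), lines)
    if (length(lines) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(comb)), function(r) {
      z0 <- comb$standard_mm[r]
      js <- vapply(lines, function(co) unname(co[1L] + co[2L] * z0),
                   numeric(1))
      floored <- any(js < floor_mm)
      js <- pmax(js, floor_mm)
      data.frame(subject_id = comb$subject_id[r],
                 distance_cm = comb$distance_cm[r], size = comb$size[r],
                 observed = comb$jnd_mm[r], predicted = combine_jnds(js),
                 model = "mle", floored = floored)
    }))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no cells with both single-cue lines and a ",
                         "combined-cue JND")
  rownames(res) <- NULL
  res
}

#' Fit the Weber task-noise model to JND records
#'
#' Least-squares fit of `J = W * z_s + c / k` per subject over that
#' subject's (cue, condition, pedestal) JND records, with `W, c >= 0`
#' enforced. The model is linear in `(W, c)` given the predictors
#' `(z_s, 1/k)`, so the constrained solution is found exactly by comparing
#' the unconstrained fit with the two boundary fits.
#'
#' @param jnd_records output of [analyze_exp2()].
#' @param strengths output of [estimate_cue_strengths()] supplying `k` per
#'   (subject, cue, distance).
#' @param min_records minimum usable records per subject (default 4).
#' @return data.frame with `subject_id`, `weber_W`, `constant_c`, `sse`,
#'   `n_records`.
#' @export
fit_weber_model <- function(jnd_records, strengths, min_records = 4L) {
  stopifnot(is.data.frame(jnd_records), is.data.frame(strengths))
  j <- merge(jnd_records[!is.na(jnd_records$jnd_mm), ],
             strengths[, c("subject_id", "cue", "distance_cm", "k")],
             by = c("subject_id", "cue", "distance_cm"))
  j <- j[j$k > 0, , drop = FALSE]
  out <- lapply(split(j, j$subject_id), function(g) {
    if (nrow(g) < min_records) {
      stop("subject ", g$subject_id[1L], " has only ", nrow(g),
           " usable JND records (need >= ", min_records, ")")
    }
    x1 <- g$standard_mm; x2 <- 1 / g$k; y <- g$jnd_mm
    X <- cbind(x1, x2)
    if (qr(X)$rank < 2L) stop("rank-deficient Weber-model design for ",
                              g$subject_id[1L])
    cand <- list()
    b <- stats::coef(stats::lm(y ~ 0 + x1 + x2))
    if (all(b >= 0)) cand[[1L]] <- b
    bW <- c(max(sum(y * x1) / sum(x1^2), 0), 0)       # c = 0
    bc <- c(0, max(sum(y * x2) / sum(x2^2), 0))       # W = 0
    cand <- c(cand, list(bW, bc))
    sse <- vapply(cand, function(bb) sum((y - X %*% bb)^2), numeric(1))
    best <- cand[[which.min(sse)]]
    data.frame(subject_id = g$subject_id[1L], weber_W = best[1L],
               constant_c = best[2L], sse = min(sse), n_records = nrow(g))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grubbs test for a single outlier (type 10)
#'
#' Two-sided single-outlier test based on the maximum absolute deviation
#' from the sample mean, `G = max|x - mean| / sd`, with the classical
#' t-based significance level.
#'
#' @param values numeric vector, `n >= 3`, approximately normal under the
#'   null.
#' @param alpha significance level for the outlier decision.
#' @return a list with `statistic`, `p_value`, `outlier_index`,
#'   `is_outlier`, `n`.
#' @export
grubbs_type10 <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) stop("Grubbs statistic undefined: zero sample SD")
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  gmax2 <- (n - 1)^2 / n
  if (g^2 >= gmax2) {
    p <- 0
  } else {
    t2 <- n * (n - 2) * g^2 / (gmax2 * n - n * g^2)
    p <- min(1, 2 * n * stats::pt(sqrt(t2), df = n - 2, lower.tail = FALSE))
  }
  list(statistic = g, p_value = p, outlier_index = which.max(dev),
       is_outlier = p < alpha, n = n)
}

#' Grubbs-based exclusion of an outlying JND condition
#'
#' Applies [grubbs_type10()] to the condition-mean JNDs (averaged over
#' subjects per cue x distance x size) and, if the test is significant,
#' removes that condition's records.
#'
#' @param jnd_records output of [analyze_exp2()].
#' @param alpha significance level (default 0.05).
#' @return a list with `records` (possibly filtered) and `excluded` (NULL or
#'   the excluded condition with its p-value).
#' @export
exclude_outlier_condition <- function(jnd_records, alpha = 0.05) {
  j <- jnd_records[!is.na(jnd_records$jnd_mm), , drop = FALSE]
  key <- interaction(j$cue, j$distance_cm, j$size, drop = TRUE)
  means <- tapply(j$jnd_mm, key, mean)
  if (length(means) < 3L) return(list(records = jnd_records, excluded = NULL))
  gt <- grubbs_type10(as.numeric(means), alpha = alpha)
  if (!gt$is_outlier) return(list(records = jnd_records, excluded = NULL))
  bad <- names(means)[gt$outlier_index]
  keep <- key != bad
  list(records = j[keep, , drop = FALSE],
       excluded = list(condition = bad, p_value = gt$p_value))
}
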