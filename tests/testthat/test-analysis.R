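test_that("cue strengths are recovered exactly from noiseless data", {
  tab <- noiseless_exp1(k_t = 0.8, k_d = 0.6)
  ks <- estimate_cue_strengths(tab)
  expect_equal(ks$k[ks$cue == "texture"], rep(0.8, 2), tolerance = 1e-10)
  expect_equal(ks$k[ks$cue == "disparity"], rep(0.6, 2), tolerance = 1e-10)
  expect_equal(ks$k[ks$cue == "combined"], rep(1, 2), tolerance = 1e-10)
  expect_equal(ks$intercept, rep(0, 6), tolerance = 1e-10)
  ks0 <- estimate_cue_strengths(tab, intercept = FALSE)
  expect_equal(ks0$intercept, rep(0, 6))
  # constant responses: zero slope, flagged degenerate
  tab$probe_mm <- 5
  ksc <- estimate_cue_strengths(tab)
  expect_true(all(ksc$degenerate))
  expect_equal(ksc$k, rep(0, 6), tolerance = 1e-10)
  # a single depth cannot identify a slope
  expect_error(estimate_cue_strengths(tab[tab$z_mm == 5, ]), "distinct")
})

test_that("parameter-free combined predictions hit unity on IC data", {
  tab <- rbind(noiseless_exp1("S1", 0.7, 1.1), noiseless_exp1("S2", 1.2, 0.9))
  out <- predict_and_compare_combined(estimate_cue_strengths(tab))
  expect_equal(out$regression$slope, 1, tolerance = 1e-8)
  expect_equal(out$regression$r, 1, tolerance = 1e-8)
  expect_equal(out$records$observed, out$records$predicted, tolerance = 1e-8)

  # MLE-generated data fall below the vector-sum prediction
  mle <- make_cohort(mle_population(sigma_texture = 1.5, sigma_disparity = 1.5),
                     8, seed = 17)
  e1 <- generate_exp1(mle, exp1_design(), seed = 17)
  outm <- predict_and_compare_combined(estimate_cue_strengths(e1))
  expect_lt(outm$regression$slope, 0.9)
})

test_that("SD analysis returns per-cell SDs and the MLE prediction", {
  tab <- noiseless_exp1(reps = 3)
  sda <- adjustment_sd_analysis(tab)
  expect_true(all(sda$sd_table$sd_mm == 0))
  expect_null(sda$mle_prediction)          # zero SDs carry no prediction
  expect_error(adjustment_sd_analysis(noiseless_exp1(reps = 2)), ">= 3")

  mle <- make_cohort(mle_population(sigma_texture = 2, sigma_disparity = 2),
                     6, seed = 18)
  e1 <- generate_exp1(mle, exp1_design(), seed = 18)
  sdm <- adjustment_sd_analysis(e1)
  err <- sdm$mle_prediction$sd_combined_obs - sdm$mle_prediction$sd_combined_pred
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 0.05)
})

test_that("standard selection inverts the perceived-depth curve", {
  tab <- noiseless_exp1(k_t = 0.6, k_d = 0.8)
  std <- select_standards(tab)
  expect_equal(nrow(std), 12L)             # 3 cues x 2 distances x 2 sizes
  # the small standard is anchored by the strongest cue at 2.5 mm ...
  small <- std[std$size == "small" & std$distance_cm == 40, ]
  expect_equal(unique(small$target_perceived_mm), 2.5)
  expect_equal(small$z_standard_mm[small$cue == "texture"], 2.5 / 0.6,
               tolerance = 1e-6)
  # ... and all cues' standards are matched in perceived depth
  obs <- toy_ic_observer(k_t = 0.6, k_d = 0.8, W = 0, c = 1)
  for (i in seq_len(nrow(std))) {
    s <- standard_stim <- icdepth:::standard_stimulus(std$cue[i],
                                                      std$z_standard_mm[i],
                                                      std$distance_cm[i])
    expect_equal(ic_percept(obs, s), std$target_perceived_mm[i],
                 tolerance = 1e-6)
  }
  expect_false(any(std$extrapolated))
  # a decreasing (non-monotone) curve raises in error mode
  bad <- tab[tab$distance_cm == 40, ]
  bad$probe_mm <- 20 - bad$probe_mm
  expect_error(select_standards(bad, nonmonotone = "error"), "non-monotone")
  expect_warning(flagged <- select_standards(bad), "non-monotone")
})

test_that("JND predictions combine and interpolate correctly", {
  recs <- data.frame(
    subject_id = "S1", distance_cm = 40,
    cue = rep(c("texture", "disparity", "combined"), each = 2),
    size = rep(c("small", "large"), 3),
    standard_mm = c(5, 12, 4, 10, 3, 8),
    jnd_mm = c(3, 4, 3, 4, 2.2, 2.9),
    pse_mm = NA, n_trials = 100, converged = TRUE)
  vs <- predict_jnd_vector_sum(recs)
  expect_equal(nrow(vs), 2L)
  expect_equal(vs$predicted[vs$size == "small"], combine_jnds(c(3, 3)))
  # a missing single cue degrades to the remaining cue's JND
  vs1 <- predict_jnd_vector_sum(recs[recs$cue != "disparity", ])
  expect_equal(vs1$predicted[vs1$size == "large"], 4)

  ml <- predict_jnd_mle(recs)
  # the two-point line for texture is J = 3 + (z-5)/7; at z = 3: 2.714
  jt <- 3 + (3 - 5) / 7
  jd <- 3 + (3 - 4) / 6
  expect_equal(ml$predicted[ml$size == "small"], combine_jnds(c(jt, jd)),
               tolerance = 1e-8)
})

test_that("the Weber task-noise model is recovered exactly when exact", {
  W <- 0.13; cc <- 1.66
  grid <- expand.grid(cue = c("texture", "disparity", "combined"),
                      distance_cm = c(40, 80), size = c("small", "large"),
                      stringsAsFactors = FALSE)
  k <- c(texture = 0.7, disparity = 1.2, combined = 1.39)[grid$cue]
  grid$subject_id <- "S1"
  grid$standard_mm <- rep(c(4, 6, 11, 13), 3)
  grid$jnd_mm <- W * grid$standard_mm + cc / k
  strengths <- data.frame(subject_id = "S1",
                          cue = rep(c("texture", "disparity", "combined"), 2),
                          distance_cm = rep(c(40, 80), each = 3),
                          k = rep(c(0.7, 1.2, 1.39), 2))
  fit <- fit_weber_model(grid, strengths)
  expect_equal(fit$weber_W, W, tolerance = 1e-8)
  expect_equal(fit$constant_c, cc, tolerance = 1e-8)

  grid$jnd_mm <- cc / k                         # W = 0 world
  fit0 <- fit_weber_model(grid, strengths)
  expect_equal(fit0$weber_W, 0, tolerance = 1e-8)
  expect_error(fit_weber_model(grid[1:2, ], strengths), "usable JND records")
})

test_that("Grubbs type-10 test flags extreme single outliers", {
  g <- grubbs_type10(c(rep(1, 11), 10))
  expect_true(g$is_outlier)
  expect_equal(g$outlier_index, 12L)
  expect_lt(g$p_value, 0.001)
  expect_gt(grubbs_type10(c(1.1, 0.9, 1.0, 1.05, 0.95))$p_value, 0.5)
  expect_error(grubbs_type10(rep(2, 10)), "zero sample SD")
  expect_error(grubbs_type10(c(1, 2)), "n >= 3")

  # automated condition screening drops the outlying condition
  recs <- expand.grid(subject_id = paste0("S", 1:6),
                      cue = c("texture", "disparity", "combined"),
                      distance_cm = c(40, 80), size = c("small", "large"),
                      stringsAsFactors = FALSE)
  set.seed(44)
  recs$standard_mm <- 8
  recs$jnd_mm <- rnorm(nrow(recs), 2, 0.2)
  hot <- recs$cue == "texture" & recs$distance_cm == 40 & recs$size == "large"
  recs$jnd_mm[hot] <- recs$jnd_mm[hot] + 8
  out <- exclude_outlier_condition(recs)
  expect_false(is.null(out$excluded))
  expect_equal(out$excluded$condition, "texture.40.large")
  expect_equal(nrow(out$records), nrow(recs) - sum(hot))
})
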