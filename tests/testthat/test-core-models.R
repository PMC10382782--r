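test_that("perceived_depth applies the linear perceptual function", {
  expect_equal(perceived_depth(perceptual_function(1), 5), 5)
  expect_equal(perceived_depth(perceptual_function(0), 15), 0)
  expect_equal(perceived_depth(perceptual_function(0.8), 10), 8)
  pf <- perceptual_function(0.5, intercept = -4)
  expect_equal(perceived_depth(pf, 2), 0)  # clipped at zero
  expect_error(perceived_depth(pf, -1), "z must be")
  expect_error(perceptual_function(-0.1), "slope_k")
})

test_that("vector_sum is the Euclidean norm with zero-cue dropout", {
  expect_equal(vector_sum(c(3, 4)), 5)
  expect_equal(vector_sum(7.3), 7.3)
  expect_equal(vector_sum(c(6, 0)), 6)
  expect_error(vector_sum(numeric(0)), "at least one")
  expect_error(vector_sum(c(3, -1)), ">= 0")
})

test_that("combined_strength dominates its arguments and scales linearly", {
  expect_equal(combined_strength(c(0.6, 0.8)), 1.0)
  expect_equal(combined_strength(c(1.2, 0)), 1.2)
  expect_equal(combined_strength(c(1, 1)), sqrt(2))
  set.seed(42)
  for (i in 1:25) {
    k <- runif(sample(2:4, 1), 0, 2)
    kc <- combined_strength(k)
    expect_gte(kc, max(k))
    expect_gte(combined_strength(k + c(0.3, rep(0, length(k) - 1))), kc)
    z <- runif(1, 0, 20)
    expect_equal(vector_sum(k * z), kc * z)  # linearity in depth
  }
})

test_that("mle_weights and mle_combine follow reliability weighting", {
  expect_equal(mle_weights(c(1, 1)), c(0.5, 0.5))
  expect_equal(mle_weights(c(1, 2)), c(0.8, 0.2))
  w <- mle_weights(c(1, 1e6))
  expect_equal(w[1], 1, tolerance = 1e-6)
  expect_error(mle_weights(c(1, 0)), "> 0")

  expect_equal(mle_combine(c(10, 20), c(1, 1)), 15)
  expect_equal(mle_combine(c(10, 20), c(1, 2)), 12)
  expect_equal(mle_combine(c(8, 0), c(1, 1e6)), 8, tolerance = 1e-6)
  expect_error(mle_combine(c(1, 2, 3), c(1, 2)), "cue-aligned")
  set.seed(7)
  for (i in 1:25) {
    est <- runif(3, 0, 20); sig <- runif(3, 0.1, 5)
    out <- mle_combine(est, sig)
    expect_gte(out, min(est)); expect_lte(out, max(est))
  }
})

test_that("mle_combined_sigma reduces variance as the rule dictates", {
  expect_equal(mle_combined_sigma(c(1, 1)), 1 / sqrt(2))
  expect_equal(mle_combined_sigma(c(2, 1e9)), 2, tolerance = 1e-6)
  expect_equal(mle_combined_sigma(c(3, 4)), 2.4)
  expect_lt(mle_combined_sigma(c(3, 4)), 3)
})

test_that("JND theory: inverse cue strength, unmeasurable sentinel", {
  expect_equal(jnd_from_strength(2, 1), 2)
  expect_equal(jnd_from_strength(2, 0.5), 4)
  expect_equal(jnd_from_strength(1.3, 1.3), 1)
  expect_true(is.na(jnd_from_strength(2, 0)))
  expect_error(jnd_from_strength(0, 1), "sigma_N")
})

test_that("combine_jnds agrees with mle_combined_sigma everywhere", {
  expect_equal(combine_jnds(c(1, 1)), 1 / sqrt(2))
  expect_equal(combine_jnds(c(3, 1e9)), 3, tolerance = 1e-6)
  expect_equal(combine_jnds(c(3, 4)), 2.4)
  set.seed(11)
  for (i in 1:200) {
    j <- runif(sample(2:5, 1), 1e-3, 1e3)
    expect_equal(combine_jnds(j), mle_combined_sigma(j), tolerance = 1e-12)
  }
})

test_that("weber_jnd and corrected_jnd invert each other", {
  noise <- task_noise_model(0.13, 1.66)
  expect_equal(weber_jnd(10, 1, noise), 2.96)
  expect_equal(weber_jnd(0, 2, noise), 0.83)
  # W = 0 reduces to plain task-noise over strength
  n0 <- task_noise_model(0, 2.5)
  expect_equal(weber_jnd(12, 0.5, n0), jnd_from_strength(2.5, 0.5))
  expect_true(is.na(weber_jnd(10, 0, noise)))

  expect_equal(corrected_jnd(2.96, 10, noise), 1)
  expect_equal(corrected_jnd(0.13 * 7 + 1.66 / 2, 7, noise), 0.5)
  set.seed(3)
  for (i in 1:50) {
    k <- runif(1, 0.1, 3); z <- runif(1, 0, 20)
    expect_equal(corrected_jnd(weber_jnd(z, k, noise), z, noise), 1 / k)
    expect_equal(corrected_jnd(weber_jnd(z, k, noise), z, noise,
                               form = "unscaled"), 1.66 / k)
  }
  expect_error(corrected_jnd(1, 1, task_noise_model(0.1, 0)), "constant_c")
})

test_that("task_noise_model validates its degenerate corner", {
  expect_error(task_noise_model(0, 0), "constant_c")
  expect_equal(task_noise_sd(task_noise_model(0.1, 1), c(0, 10)), c(1, 2))
})

test_that("cue label set is closed and combination rules reject 'combined'", {
  expect_error(cue_label("shading"), "unknown cue")
  expect_error(cue_label("combined", allow_combined = FALSE), "not a valid")
  expect_equal(cue_label("flat_texture"), "flat_texture")
})
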