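test_that("IC percepts are deterministic vector sums with flatness dropout", {
  obs <- toy_ic_observer(k_t = 0.6, k_d = 0.8)
  both <- stimulus("combined", 10, 10, 40)
  expect_equal(ic_percept(obs, both), 10)                  # 3-4-5 scaled
  mono <- stimulus("texture", 10, NA, 40)
  flat <- stimulus("texture", 10, 0, 40)
  expect_identical(ic_percept(obs, mono), ic_percept(obs, flat))
  expect_equal(ic_percept(obs, mono), 6)
  expect_identical(ic_percept(obs, both), ic_percept(obs, both))
  expect_error(ic_percept(obs, stimulus("disparity", NA, 5, 60)),
               "no \\(disparity, 60")
})

test_that("MLE percept samples match the reliability-combination moments", {
  obs <- toy_mle_observer(s_t = 2, s_d = 1)
  s <- stimulus("combined", 10, 10, 40)
  set.seed(8)
  draws <- mle_percept_sample(obs, s, n = 2e4)
  expect_equal(mean(draws), 10, tolerance = 3 * 1 / sqrt(2e4) + 0.02)
  sigma_c <- mle_combined_sigma(c(2, 1))
  expect_equal(sd(draws), sigma_c, tolerance = 3 * sigma_c / sqrt(4e4) + 0.02)

  # a reliable flatness cue pulls the estimate toward zero depth
  obs2 <- toy_mle_observer(s_t = 1, s_d = 1)
  flat <- stimulus("texture", 10, 0, 40)     # null disparity field
  set.seed(9)
  pulled <- mean(mle_percept_sample(obs2, flat, n = 5e3))
  expect_equal(pulled, 5, tolerance = 0.1)   # w_t = 0.5
  # an uninformative flatness cue does not
  obs3 <- toy_mle_observer(s_t = 1, s_d = 1e6)
  set.seed(10)
  expect_equal(mean(mle_percept_sample(obs3, flat, n = 5e3)), 10,
               tolerance = 0.1)
})

test_that("adjustment noise depends only on perceived magnitude (IC)", {
  # two cue conditions engineered to share the same percept
  obs <- toy_ic_observer(k_t = 1, k_d = 1, W = 0.13, c = 1.66)
  s_tex <- stimulus("texture", 10, NA, 40)
  s_dsp <- stimulus("disparity", NA, 10, 40)
  set.seed(12)
  a <- replicate(1500, simulate_adjustment(obs, s_tex))
  b <- replicate(1500, simulate_adjustment(obs, s_dsp))
  expect_equal(sd(a), sd(b), tolerance = 0.15)
  expect_equal(sd(a), 0.13 * 10 + 1.66, tolerance = 0.15)

  # Weber off: SD constant across depths
  obs0 <- toy_ic_observer(k_t = 1, k_d = 1, W = 0, c = 2)
  set.seed(13)
  s1 <- replicate(1500, simulate_adjustment(obs0, stimulus("texture", 3, NA, 40)))
  s2 <- replicate(1500, simulate_adjustment(obs0, stimulus("texture", 14, NA, 40)))
  expect_equal(sd(s2), 2, tolerance = 0.15)
  expect_equal(sd(s1), sd(s2), tolerance = 0.25)  # low depth: mild truncation
})

test_that("MLE adjustment SDs show the combined-cue reduction", {
  obs <- toy_mle_observer(s_t = 2, s_d = 2)
  set.seed(14)
  single <- replicate(2000, simulate_adjustment(obs, stimulus("texture", 12, NA, 40)))
  comb <- replicate(2000, simulate_adjustment(obs, stimulus("combined", 12, 12, 40)))
  expect_equal(sd(comb) / sd(single), 1 / sqrt(2), tolerance = 0.08)
})

test_that("2IFC choice probabilities follow the IC task-noise model", {
  obs <- toy_ic_observer(k_t = 1, k_d = 1, W = 0, c = 2)
  std <- stimulus("texture", 10, NA, 40)
  mk <- function(z) stimulus("texture", z, NA, 40)
  set.seed(15)
  p0 <- mean(replicate(4000, simulate_2ifc(obs, std, mk(10))))
  expect_equal(p0, 0.5, tolerance = 0.03)
  # dz = sigma_N / k puts the comparison at the 84% point
  p84 <- mean(replicate(4000, simulate_2ifc(obs, std, mk(12))))
  expect_equal(p84, 0.84, tolerance = 0.03)
  # per-interval noise inflates the effective SD by sqrt(2)
  set.seed(16)
  p84b <- mean(replicate(4000, simulate_2ifc(obs, std, mk(12),
                                             per_interval_noise = TRUE)))
  expect_equal(p84b, pnorm(1 / sqrt(2)), tolerance = 0.03)
  # vanishing noise: deterministic ordering
  obs0 <- toy_ic_observer(k_t = 1, k_d = 1, W = 0, c = 1e-9)
  expect_true(all(replicate(50, simulate_2ifc(obs0, std, mk(10.01)))))
})

test_that("cohorts are reproducible and encode depth-constancy failure", {
  pop <- ic_population()
  c1 <- make_cohort(pop, 12, seed = 1)
  c2 <- make_cohort(pop, 12, seed = 1)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_cohort(pop, 12, seed = 2)))
  # degenerate point-mass spec yields identical observers (up to id)
  popd <- ic_population(k_texture = 1, k_disparity = 1.2,
                        weber_W = 0.1, constant_c = 1.5)
  cd <- make_cohort(popd, 3, seed = 4)
  expect_equal(cd[[1]]$strengths$k, cd[[2]]$strengths$k)
  # disparity drawn stronger at 40 cm than 80 cm on average
  kd <- sapply(c1, function(o) {
    s <- o$strengths
    s$k[s$cue == "disparity" & s$distance_cm == 40] -
      s$k[s$cue == "disparity" & s$distance_cm == 80]
  })
  expect_gt(mean(kd), 0)
  expect_error(ic_population(k_texture = c(2, 1)) |> make_cohort(2, 1),
               "invalid range")
})

test_that("generate_exp1 builds balanced seeded factorials", {
  cohort <- make_cohort(ic_population(), 1, seed = 3)
  tab <- generate_exp1(cohort, exp1_design(), seed = 3)
  expect_equal(nrow(tab), 2 * 3 * 4 * 7)     # 168
  tab5 <- generate_exp1(cohort, exp1_design(reps = 5), seed = 3)
  expect_equal(nrow(tab5), 120)
  expect_identical(tab, generate_exp1(cohort, exp1_design(), seed = 3))
  counts <- table(tab$cue, tab$z_mm, tab$distance_cm)
  expect_true(all(counts == 7))
  expect_true(all(tab$probe_mm >= 0))
  # disparity-only rows carry no texture signal and vice versa
  expect_true(all(is.na(tab$z_texture_mm[tab$cue == "disparity"])))
  expect_true(all(is.na(tab$z_disparity_mm[tab$cue == "texture"])))
})

test_that("generate_exp2 runs four interleaved staircases per standard", {
  obs <- toy_ic_observer(k_t = 1, k_d = 1)
  standards <- data.frame(subject_id = "T1", cue = "combined",
                          distance_cm = 40, size = c("small", "large"),
                          z_standard_mm = c(5, 12))
  tr <- generate_exp2(list(obs), standards, seed = 6)
  expect_identical(tr, generate_exp2(list(obs), standards, seed = 6))
  for (sz in c("small", "large")) {
    g <- tr[tr$size == sz, ]
    revs <- tapply(g$is_reversal, g$staircase_rule, sum)
    expect_equal(length(revs), 4L)
    expect_true(all(revs == 12))
  }
  # unmeasurable standards are skipped with a warning
  standards$z_standard_mm[2] <- NA
  expect_warning(tr2 <- generate_exp2(list(obs), standards, seed = 6),
                 "unmeasurable")
  expect_equal(unique(tr2$size), "small")
})

test_that("exp3 flatness conditions dissociate the two observer classes", {
  ic <- make_cohort(ic_population(constant_c = 1.0), 4, seed = 9)
  e3 <- generate_exp3(ic, experiment = "A", seed = 9)
  m <- tapply(e3$probe_mm, e3$flatness_condition, mean)
  expect_equal(unname(m["monocular"]), unname(m["binocular"]),
               tolerance = 0.15)
  expect_identical(e3, generate_exp3(ic, experiment = "A", seed = 9))

  mle <- make_cohort(mle_population(sigma_texture = 1.5, sigma_disparity = 1.5,
                                    sigma_flat_texture = 1.5), 4, seed = 9)
  e3b <- generate_exp3(mle, experiment = "B", seed = 9)
  mb <- tapply(e3b$probe_mm, e3b$flatness_condition, mean)
  # reliable textural flatness halves perceived depth under MLE weighting
  expect_lt(mb["flat_texture"], 0.65 * mb["rds"])
})
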