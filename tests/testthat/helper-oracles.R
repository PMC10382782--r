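# Shared fixtures and independent oracles, built in code at test time.

# Bernoulli responder following a cumulative-Gaussian psychometric function
# centred at `threshold` with spread `sigma`.
gaussian_responder <- function(threshold, sigma) {
  function(x) runif(1) < pnorm((x - threshold) / sigma)
}

# A small IC observer with known parameters at both distances.
toy_ic_observer <- function(id = "T1", k_t = 0.6, k_d = 0.8,
                            W = 0.13, c = 1.66) {
  ic_observer(id, data.frame(
    cue = rep(c("texture", "disparity"), 2),
    distance_cm = rep(c(40, 80), each = 2),
    k = rep(c(k_t, k_d), 2)),
    task_noise = task_noise_model(W, c))
}

toy_mle_observer <- function(id = "M1", s_t = 2, s_d = 1, s_flat = 1e6,
                             task_noise = NULL) {
  mle_observer(id, data.frame(
    cue = rep(c("texture", "disparity", "flat_texture"), 2),
    distance_cm = rep(c(40, 80), each = 3),
    sigma = rep(c(s_t, s_d, s_flat), 2)),
    task_noise = task_noise)
}

# Noiseless adjustment table for an exact-recovery scenario:
# probe = k_cue * z with k_combined = sqrt(k_t^2 + k_d^2).
noiseless_exp1 <- function(subjects = "S1", k_t = 0.6, k_d = 0.8,
                           depths = c(2.5, 5, 10, 15), distances = c(40, 80),
                           reps = 2) {
  k_c <- sqrt(k_t^2 + k_d^2)
  g <- expand.grid(subject_id = subjects,
                   cue = c("disparity", "texture", "combined"),
                   z_mm = depths, distance_cm = distances,
                   rep = seq_len(reps),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- c(disparity = k_d, texture = k_t, combined = k_c)[g$cue]
  g$z_texture_mm <- ifelse(g$cue == "disparity", NA_real_, g$z_mm)
  g$z_disparity_mm <- ifelse(g$cue == "texture", NA_real_, g$z_mm)
  g$probe_mm <- unname(k * g$z_mm)
  g
}

# Independent sum-of-squares oracle for the within-subject ANOVA: sequential
# sums of squares from a saturated fixed-effects projection with sum
# contrasts (orthogonal for balanced designs).
anova_ss_oracle <- function(data, dv, subject, within) {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  fml <- as.formula(paste(dv, "~", paste(c(within, subject), collapse = "*")))
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  a <- suppressWarnings(anova(aov(fml, data = data)))
  ss <- a$`Sum Sq`
  names(ss) <- rownames(a)
  ss
}

# Brute-force grid minimiser of the psychometric negative log-likelihood.
psychometric_grid_oracle <- function(x, resp, lapse, mu_grid, sigma_grid) {
  nll <- function(mu, sigma) {
    p <- lapse / 2 + (1 - lapse) * pnorm((x - mu) / sigma)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(log(ifelse(resp, p, 1 - p)))
  }
  g <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  g$nll <- mapply(nll, g$mu, g$sigma)
  g[which.min(g$nll), ]
}
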