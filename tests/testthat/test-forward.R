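test_that("thalamic input peaks at onset, decays in the tails, integrates as a Gaussian", {
  expect_equal(thalamic_input(60, 60, 16, 2.5), 2.5)
  expect_lt(thalamic_input(60 + 5 * 16, 60, 16, 1), 1e-5)
  expect_lt(thalamic_input(60 - 5 * 16, 60, 16, 1), 1e-5)
  # numeric quadrature oracle for the bump mass
  q <- integrate(thalamic_input, -Inf, Inf, onset = 60, width = 16,
                 amplitude = 0.7)$value
  expect_equal(q, 0.7 * 16 * sqrt(2 * pi), tolerance = 1e-6)
  expect_error(thalamic_input(0, 60, -1, 1), "width")
})

test_that("zero input amplitude gives a flat trajectory at the fixed point", {
  cfg <- test_config(u_amp = 0)
  tr <- integrate_trial(config = cfg)
  dev <- sweep(tr$V, 2, tr$equilibrium, "-")
  expect_lt(max(abs(dev)), 1e-8)
})

test_that("condition modulation B drives the deviant/standard difference", {
  cfg <- test_config()
  lat0 <- c(b_r1 = 0, b_r2 = 0)
  s0 <- integrate_trial(lat0, 0, cfg)
  d0 <- integrate_trial(lat0, 1, cfg)
  expect_equal(s0$V, d0$V, tolerance = 1e-12)
  lat1 <- c(b_r1 = 0.3, b_r2 = 0.3)
  s1 <- integrate_trial(lat1, 0, cfg)
  d1 <- integrate_trial(lat1, 1, cfg)
  expect_gt(max(abs(d1$V - s1$V)), 1e-3)
})

test_that("integrator converges under step halving", {
  lat <- c(blk_r1 = 0.2, blk_r2 = 0.2, b_r1 = 0.3, b_r2 = 0.3)
  tr1 <- integrate_trial(lat, 1, test_config(dt = 1))
  tr4 <- integrate_trial(lat, 1, test_config(dt = 0.25))
  idx <- seq(1, 1201, by = 4)
  rng <- diff(range(tr4$V))
  expect_lt(max(abs(tr4$V[idx, ] - tr1$V)), 1e-3 * rng)
})

test_that("trial integration is deterministic", {
  lat <- c(blk_r1 = 0.1, b_r1 = 0.2)
  a <- integrate_trial(lat, 1, test_config())
  b <- integrate_trial(lat, 1, test_config())
  expect_identical(a$V, b$V)
})

test_that("conductances stay non-negative along the trajectory", {
  cfg <- test_config()
  a <- assemble_model(c(b_r1 = 0.3, b_r2 = 0.3), cfg, 1)
  fp <- find_fixed_point(c(b_r1 = 0.3, b_r2 = 0.3), cfg, 1)
  V <- cmm_integrate_cpp(fp$state, 1, 301, a$u_onset, a$u_width, a$u_amp,
                         a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                         a$Cm, a$gL, a$Vrev, a$mg_num, a$sig_slope,
                         a$sig_thresh, a$u_w, a$u_into_g, a$v_bound)
  expect_true(all(is.finite(V)))
  expect_true(all(fp$state[9:32] >= 0))
})

test_that("projection is linear, selective and Hanning-tapered", {
  src <- matrix(rnorm(301 * 8), 301, 8)
  trial <- list(V = src, equilibrium = rep(0, 8))
  # identity-like gain, window off: selected rows returned unchanged
  obs_id <- observation_model(gain = diag(1, 4), hanning = FALSE)
  Y <- project_to_modes(trial, obs_id)
  expect_equal(Y, src[, c(2, 4, 6, 8)], tolerance = 1e-14,
               ignore_attr = TRUE)
  # window on: endpoints of every mode ~ 0
  obs_w <- observation_model(gain = default_gain(), hanning = TRUE)
  Yw <- project_to_modes(trial, obs_w)
  expect_equal(max(abs(Yw[1, ])), 0, tolerance = 1e-12)
  expect_equal(max(abs(Yw[301, ])), 0, tolerance = 1e-12)
  # doubling the gain doubles the output exactly
  obs2 <- observation_model(gain = 2 * default_gain(), hanning = TRUE)
  expect_equal(project_to_modes(trial, obs2), 2 * Yw, tolerance = 1e-14)
  expect_error(project_to_modes(trial, observation_model(gain = matrix(1, 8, 3),
                                                         source_pops = c("sp_r1", "dp_r1", "sp_r2"))),
               NA)
})

test_that("mode reduction captures variance in SVD order", {
  set.seed(5)
  # rank-1 data: one mode captures everything
  u <- rnorm(100); v <- rnorm(12)
  X1 <- outer(u, v) + 1e-8 * matrix(rnorm(1200), 100, 12)
  r1 <- reduce_to_modes(X1, 1)
  expect_gt(r1$var_frac[1], 0.999)
  # complete basis reconstructs exactly
  X <- matrix(rnorm(100 * 12), 100, 12)
  rk <- reduce_to_modes(X, 12)
  expect_equal(rk$modes %*% t(rk$projection), X, tolerance = 1e-10)
  # captured variance is non-increasing
  r8 <- reduce_to_modes(X, 8)
  expect_true(all(diff(r8$var_frac) <= 1e-12))
  expect_error(reduce_to_modes(X, 0), "positive")
  expect_error(reduce_to_modes(X, 13), "exceeds")
})

test_that("window amplitude grows with input amplitude over the working range", {
  amps <- c(0.005, 0.01, 0.02, 0.04)
  lat <- c(b_r1 = 0.3, b_r2 = 0.3)
  w <- sapply(amps, function(am) {
    cfg <- test_config(u_amp = am)
    d <- integrate_trial(lat, 1, cfg)
    s <- integrate_trial(lat, 0, cfg)
    Y <- project_to_modes(d, test_obs()) - project_to_modes(s, test_obs())
    max(abs(Y[141:161, ]))
  })
  expect_true(all(diff(w) > 0))
})
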