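test_that("blockade transform is the exponential with positivity", {
  expect_identical(alpha_from_blockade(0), 1)
  expect_equal(alpha_from_blockade(0.42), exp(0.42))
  expect_equal(alpha_from_blockade(0.42), 1.522, tolerance = 1e-3)
  expect_equal(alpha_from_blockade(-0.125), exp(-0.125))
  expect_equal(alpha_from_blockade(-0.125), 0.8825, tolerance = 1e-4)
  blks <- seq(-3, 3, by = 0.25)
  expect_true(all(alpha_from_blockade(blks) > 0))
  expect_true(all(diff(alpha_from_blockade(blks)) > 0))
  expect_error(alpha_from_blockade(NaN), "finite")
})

test_that("magnesium switch saturates, is bounded and voltage-monotone", {
  expect_equal(mg_switch(1e6, 0), 1.50265, tolerance = 1e-12)
  expect_equal(mg_switch_standard(1e6), 1.5, tolerance = 1e-12)
  # V = 0 collapses the exponent: output independent of the blockade
  for (blk in c(-2, -1, 0, 1, 4))
    expect_equal(mg_switch(0, blk), 1.50265 / 1.33, tolerance = 1e-12)
  # bounds and monotonicity on grids (strict inequalities checked over the
  # physiological range; in double precision the switch saturates at the
  # numerator for very large alpha * V)
  V <- seq(-80, 60, by = 2.5)
  for (blk in c(-1, -0.5, 0, 0.5, 1, 2)) {
    m <- mg_switch(V, blk)
    expect_true(all(m > 0 & m < 1.50265))
    expect_true(all(diff(m) > 0))
  }
  Vwide <- seq(-500, 500, by = 10)
  for (blk in c(-1, 0, 2))
    expect_true(all(mg_switch(Vwide, blk) > 0 &
                      mg_switch(Vwide, blk) <= 1.50265))
  # blockade monotonicity: decreasing in blk at V < 0, increasing at V > 0
  blks <- c(-1, 0, 1, 2, 4)
  expect_true(all(diff(mg_switch(-70, blks)) < 0))
  expect_true(all(diff(mg_switch(35, blks)) > 0))
  # at blk = 0 the modified switch matches the standard curve up to the
  # documented numerator change
  ratio <- mg_switch(V, 0) / mg_switch_standard(V)
  expect_equal(ratio, rep(1.50265 / 1.5, length(V)), tolerance = 1e-12)
})

test_that("firing rate is a bounded monotone sigmoid", {
  expect_equal(firing_rate(-50, 0.1, -50), 0.5)
  expect_equal(firing_rate(-1e4, 0.1, -50), 0, tolerance = 1e-12)
  expect_equal(firing_rate(1e4, 0.1, -50), 1, tolerance = 1e-12)
  # steeper slope above threshold increases output
  expect_gt(firing_rate(-40, 0.2, -50), firing_rate(-40, 0.1, -50))
  V <- seq(-100, 0, by = 1)
  expect_true(all(diff(firing_rate(V, 0.1, -45)) > 0))
  expect_error(firing_rate(-50, -1, -50), "slope")
})

test_that("drift matches the state equations (independent R oracle)", {
  cfg <- test_config()
  lat <- c(blk_r1 = 0.3, blk_r2 = -0.2, b_r1 = 0.25, b_r2 = 0.1,
           t_nmda_r1 = 0.1, g_fwd = 0.05)
  a <- assemble_model(lat, cfg, condition_index = 1)
  set.seed(42)
  for (i in 1:10) {
    x <- c(runif(8, -90, -30), runif(24, 0, 0.5))
    u <- runif(1, 0, 0.05)
    d_pkg <- population_drift(x, lat, cfg, u = u, condition_index = 1)
    d_orc <- r_drift_oracle(x, u, a)
    expect_equal(d_pkg, d_orc, tolerance = 1e-12)
  }
})

test_that("leak equilibrium is a fixed point when couplings vanish", {
  cfg <- test_config(S_exc = matrix(0, 4, 4), S_inh = matrix(0, 4, 4),
                     fwd_gain = 0, bwd_gain = 0)
  x <- leak_equilibrium(cfg)
  d <- population_drift(x, config = cfg, u = 0)
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)
})

test_that("solved fixed point zeroes the drift and is locally stable", {
  cfg <- test_config()
  fp <- find_fixed_point(config = cfg)
  expect_true(fp$converged)
  expect_lt(fp$drift_norm, 1e-8)
  # independent check through the R drift oracle
  a <- assemble_model(numeric(), cfg, 0)
  expect_lt(sqrt(sum(r_drift_oracle(fp$state, 0, a)^2)), 1e-8)
  # small perturbations decay back under input-free integration
  set.seed(7)
  x0 <- fp$state + c(rnorm(8, 0, 0.5), rnorm(24, 0, 0.01))
  V <- cmm_integrate_cpp(x0, 1, 301, 60, 16, 0,
                         a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                         a$Cm, a$gL, a$Vrev, a$mg_num, a$sig_slope,
                         a$sig_thresh, a$u_w, a$u_into_g, a$v_bound)
  drift_end <- max(abs(V[301, ] - fp$state[1:8]))
  drift_start <- max(abs(V[1, ] - fp$state[1:8]))
  expect_lt(drift_end, 0.05 * drift_start)
})

test_that("raising the blockade weakens the NMDA current at hyperpolarised V", {
  cfg <- test_config()
  x <- leak_equilibrium(cfg)
  x[25:32] <- 0.2  # some NMDA conductance
  nmda_current <- function(blk) {
    V <- x[1:8]
    gN <- x[25:32]
    m <- mg_switch(V, blk)
    abs(gN * m * (cfg$V_NMDA - V))
  }
  cur <- sapply(c(0, 0.5, 1, 2), function(b) sum(nmda_current(b)))
  expect_true(all(diff(cur) < 0))
  # and the same ordering appears in the assembled drift
  d0 <- population_drift(x, c(blk_r1 = 0, blk_r2 = 0), cfg)
  d1 <- population_drift(x, c(blk_r1 = 1, blk_r2 = 1), cfg)
  expect_true(all(abs(d1[1:8] - d0[1:8]) > 0))
})

test_that("natural-scale parameters from latents are strictly positive", {
  set.seed(11)
  for (i in 1:20) {
    lat <- setNames(rnorm(length(latent_names()), 0, 0.5), latent_names())
    a <- assemble_model(lat, test_config())
    expect_true(all(a$tauA > 0) && all(a$tauG > 0) && all(a$tauN > 0))
    expect_true(all(a$alpha > 0))
    expect_true(a$u_width > 0 && a$u_amp > 0 && a$gain_scale > 0)
  }
})

test_that("state/parameter layout mismatches raise structural errors", {
  expect_error(population_drift(rep(0, 10)), "length-32")
  expect_error(assemble_model(c(nonsense = 1)), "unknown latent")
  expect_error(cmm_priors(free = "not_a_latent"), "unknown latent")
})

test_that("parameter sets round-trip through JSON", {
  lat <- c(blk_r1 = 0.42, blk_r2 = -0.125, t_ampa_r1 = 0.1)
  pr <- cmm_priors(free = c("blk_r1", "blk_r2"))
  f <- tempfile(fileext = ".json")
  write_params(lat, pr, f)
  back <- read_params(f)
  expect_equal(back$latents[["blk_r1"]], 0.42)
  expect_equal(back$latents[["blk_r2"]], -0.125)
  expect_equal(diag(back$priors$cov), diag(pr$cov), tolerance = 1e-12)
  unlink(f)
})
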