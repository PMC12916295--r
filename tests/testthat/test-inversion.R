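# Variational Laplace inversion: oracle equivalence on linear models,
# self-consistency and parameter recovery on the microcircuit.

test_that("free energy reduces to the exact evidence on a linear model", {
  set.seed(101)
  n <- 30; p <- 2
  A <- matrix(rnorm(n * p), n, p)
  S0 <- diag(c(0.4, 0.25))
  m0 <- c(th1 = 0.1, th2 = -0.2)
  sd_n <- 0.15
  y <- drop(A %*% c(0.4, -0.1)) + rnorm(n, 0, sd_n)
  orc <- linear_conjugate_oracle(y, A, 0, m0, S0, sd_n)
  q <- gaussian_density(setNames(orc$mean, names(m0)), orc$cov)
  resid <- matrix(y - drop(A %*% orc$mean), n, 1)
  Fq <- free_energy(q, gaussian_density(m0, S0), resid, J = A,
                    lambda = log(1 / sd_n^2))
  expect_equal(Fq, orc$logZ, tolerance = 1e-8)
  # KL term vanishes when q equals the prior
  expect_equal(kl_gaussian(gaussian_density(m0, S0),
                           gaussian_density(m0, S0)), 0, tolerance = 1e-12)
  # a much tighter prior that excludes the fitted mean raises the
  # complexity penalty
  kl_wide <- kl_gaussian(q, gaussian_density(m0, S0))
  kl_tight <- kl_gaussian(q, gaussian_density(m0, S0 / 100))
  expect_gt(kl_tight, kl_wide)
})

test_that("VL fixed point equals the conjugate posterior on random linear models", {
  set.seed(202)
  for (rep in 1:3) {
    n <- sample(20:40, 1); p <- sample(2:4, 1)
    A <- matrix(rnorm(n * p), n, p)
    b <- rnorm(n, 0, 0.1)
    m0 <- setNames(rnorm(p, 0, 0.2), paste0("th", seq_len(p)))
    S0 <- diag(runif(p, 0.1, 0.6), p)
    sd_n <- runif(1, 0.05, 0.3)
    theta_true <- rnorm(p, 0, 0.5)
    y <- matrix(drop(A %*% theta_true) + b + rnorm(n, 0, sd_n), n, 1)
    orc <- linear_conjugate_oracle(drop(y), A, b, m0, S0, sd_n)
    res <- invert_vl(y, function(th) matrix(drop(A %*% th) + b, n, 1),
                     gaussian_density(m0, S0),
                     vl_settings(update_noise = FALSE,
                                 lambda_init = log(1 / sd_n^2)))
    expect_equal(unname(res$posterior$mean), unname(orc$mean),
                 tolerance = 1e-6)
    expect_equal(unname(res$posterior$cov), unname(orc$cov),
                 tolerance = 1e-6)
    expect_equal(res$F, orc$logZ, tolerance = 1e-6)
  }
})

test_that("free-energy trace is non-decreasing and posterior covariance PD", {
  set.seed(303)
  cfg <- test_config()
  lat <- c(blk_r1 = 0.3, blk_r2 = 0.3, b_r1 = 0.3, b_r2 = 0.3)
  dat <- simulate_erp(lat, cfg, test_obs(), noise_sd = 0.05)
  pr <- cmm_priors(free = c("blk_r1", "blk_r2"),
                   mean = c(b_r1 = 0.3, b_r2 = 0.3))
  res <- invert_erp(dat, pr, cfg, test_obs())
  expect_true(all(diff(res$F_trace) > -1e-6))
  ev <- eigen(res$posterior$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("noiseless data at the prior mean are explained at the prior mean", {
  cfg <- test_config()
  pr <- cmm_priors(free = c("blk_r1", "blk_r2"),
                   mean = c(b_r1 = 0.3, b_r2 = 0.3))
  dat <- simulate_erp(c(b_r1 = 0.3, b_r2 = 0.3), cfg, test_obs(), noise_sd = 0)
  res <- invert_erp(dat, pr, cfg, test_obs(),
                    vl_settings(update_noise = FALSE, lambda_init = 6))
  expect_lt(max(abs(res$posterior$mean - 0)), 1e-3)
})

test_that("a planted blockade shift in one region is recovered", {
  set.seed(404)
  cfg <- test_config()
  lat <- c(blk_r1 = 0.5, blk_r2 = 0, b_r1 = 0.3, b_r2 = 0.3)
  dat <- simulate_erp(lat, cfg, test_obs(), noise_sd = 0.02)
  pr <- cmm_priors(free = c("blk_r1", "blk_r2"),
                   mean = c(b_r1 = 0.3, b_r2 = 0.3))
  res <- invert_erp(dat, pr, cfg, test_obs())
  expect_lt(abs(res$posterior$mean[["blk_r1"]] - 0.5), 0.2)
  expect_lt(abs(res$posterior$mean[["blk_r2"]] - 0), 0.2)
  # perturbing only one region's blockade changes the prediction
  p0 <- predict_response(res$full_mean, cfg, test_obs())
  th <- res$full_mean; th["blk_r1"] <- th["blk_r1"] + 0.1
  p1 <- predict_response(th, cfg, test_obs())
  expect_gt(max(abs(p1 - p0)), 0)
})

test_that("inversion results round-trip through JSON", {
  set.seed(9)
  pr <- gaussian_density(c(a = 0, b = 0), diag(0.3, 2))
  A <- matrix(rnorm(20 * 2), 20, 2)
  y <- matrix(drop(A %*% c(0.2, -0.1)) + rnorm(20, 0, 0.1), 20, 1)
  res <- invert_vl(y, function(th) matrix(drop(A %*% th), 20, 1), pr)
  f <- tempfile(fileext = ".json")
  write_inversion(res, f)
  back <- read_inversion(f)
  expect_equal(back$posterior$mean, res$posterior$mean, tolerance = 1e-12)
  expect_equal(unname(back$posterior$cov), unname(res$posterior$cov),
               tolerance = 1e-12)
  expect_equal(back$F, res$F, tolerance = 1e-12)
  unlink(f)
})

test_that("an all-fixed prior mask is rejected", {
  pr <- cmm_priors(free = character(0))
  expect_error(invert_vl(matrix(0, 5, 1), function(th) matrix(0, 5, 1), pr),
               "no free parameters")
})
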