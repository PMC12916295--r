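# Parametric Empirical Bayes: trivial identities, the closed-form
# hierarchical oracle, Bayesian model reduction and averaging.

flat_posts <- function(mu, cv, n) {
  rep(list(gaussian_density(mu, cv)), n)
}

test_that("identical subjects with a constant design return the shared mean", {
  prior <- gaussian_density(c(a = 0, b = 0), diag(1 / 64, 2))
  post <- gaussian_density(c(a = 0.3, b = -0.1), diag(1e-5, 2))
  des <- peb_design(matrix(1, 8, 1), names = "const")
  peb <- fit_peb(flat_posts(post$mean, post$cov, 8), prior, des,
                 field = c("a", "b"))
  expect_equal(unname(peb$beta$mean[c("a:const", "b:const")]),
               c(0.3, -0.1), tolerance = 1e-2)
})

test_that("PEB matches the closed-form hierarchical GLS solution", {
  set.seed(21)
  n <- 10; f <- 2
  prior <- gaussian_density(c(p1 = 0, p2 = 0), diag(0.25, f))
  X <- cbind(const = 1, g = scale(rnorm(n), scale = FALSE))
  truthB <- matrix(c(0.2, -0.1, 0.4, 0.0), f, 2)
  # construct exact first-level posteriors from known likelihoods
  L <- diag(c(400, 900))
  nu <- lapply(seq_len(n), function(i)
    drop(truthB %*% X[i, ]) + rnorm(f, 0, 0.05))
  posts <- lapply(nu, function(v) {
    P <- L + solve(prior$cov)
    C <- solve(P)
    gaussian_density(setNames(drop(C %*% (L %*% v)), names(prior$mean)), C)
  })
  des <- peb_design(X, names = c("const", "g"), beta_prior_var = 1 / 16)
  peb <- fit_peb(posts, prior, des, field = c("p1", "p2"))
  Sb <- exp(-peb$gamma) * prior$cov / 16
  orc <- hierarchical_gls_oracle(nu, rep(list(L), n), X, Sb,
                                 diag(1 / 16, f * ncol(X)))
  expect_equal(unname(peb$beta$mean), unname(orc$mean), tolerance = 1e-6)
  expect_equal(unname(peb$beta$cov), unname(orc$cov), tolerance = 1e-6)
})

test_that("Bayesian model reduction identities hold", {
  set.seed(31)
  p <- 3
  prior <- gaussian_density(setNames(rep(0, p), letters[1:p]), diag(0.3, p))
  M <- matrix(rnorm(p * p), p); S <- crossprod(M) / p + diag(0.05, p)
  post <- gaussian_density(setNames(rnorm(p, 0, 0.2), letters[1:p]), S)
  # unchanged priors: dF exactly 0
  expect_equal(bmr_gaussian(prior, post, prior)$dF, 0, tolerance = 1e-8)
  # BMR against a direct refit on a linear-Gaussian model
  A <- matrix(rnorm(20 * p), 20, p)
  y <- drop(A %*% c(0.5, 0, -0.2)) + rnorm(20, 0, 0.1)
  full <- linear_conjugate_oracle(y, A, 0, prior$mean, prior$cov, 0.1)
  red_prior <- gaussian_density(prior$mean,
                                diag(c(0.3, 1e-8, 0.3), p))
  red_direct <- linear_conjugate_oracle(y, A, 0, red_prior$mean,
                                        red_prior$cov, 0.1)
  full_post <- gaussian_density(setNames(full$mean, letters[1:p]), full$cov)
  bm <- bmr_gaussian(prior, full_post, red_prior)
  expect_equal(bm$dF, red_direct$logZ - full$logZ, tolerance = 1e-6)
  expect_equal(unname(bm$posterior$mean), unname(red_direct$mean),
               tolerance = 1e-6)
})

test_that("softmax probabilities are shift-invariant, symmetric and normalised", {
  F <- c(-3, 1, 4.5)
  expect_equal(softmax_prob(F), softmax_prob(F + 123.4), tolerance = 1e-12)
  expect_equal(sum(softmax_prob(F)), 1, tolerance = 1e-12)
  expect_equal(softmax_prob(c(2, 2)), c(0.5, 0.5))
})

test_that("model averaging computes exact mixture moments", {
  m1 <- gaussian_density(c(x = 0.5), matrix(0.04, dimnames = list("x", "x")))
  m2 <- gaussian_density(c(x = -0.5), matrix(0.04, dimnames = list("x", "x")))
  # single model returned unchanged
  one <- bayesian_model_average(list(m1), weights = 1)
  expect_equal(one$mean, m1$mean)
  expect_equal(one$cov, m1$cov)
  # equal weights, means +-a: mean 0, variance includes a^2
  avg <- bayesian_model_average(list(m1, m2), weights = c(0.5, 0.5))
  expect_equal(unname(avg$mean), 0)
  expect_equal(unname(avg$cov[1, 1]), 0.04 + 0.25)
  # degenerate weights pick out one model
  w10 <- bayesian_model_average(list(m1, m2), weights = c(1, 0))
  expect_equal(w10$mean, m1$mean)
})

test_that("a planted group effect is recovered with high posterior probability", {
  set.seed(41)
  n <- 12
  prior <- gaussian_density(c(blk = 0), matrix(1 / 64, dimnames = list("blk", "blk")))
  base <- rnorm(n, 0, 0.125)
  mu <- c(base, base + 0.4)
  posts <- lapply(mu, function(m)
    gaussian_density(c(blk = m + rnorm(1, 0, 0.02)),
                     matrix(4e-4, dimnames = list("blk", "blk"))))
  X <- cbind(const = 1, drug = rep(c(0, 1), each = n))
  peb <- fit_peb(posts, prior, peb_design(X), field = "blk")
  expect_gt(peb$beta$mean[["blk:drug"]], 0)
  expect_lt(abs(peb$beta$mean[["blk:drug"]] - 0.4), 0.1)
  bma <- peb_bma_all(peb, regressors = "drug")
  expect_gt(bma$presence[["blk:drug"]], 0.95)
})

test_that("null effects are rarely flagged (calibration)", {
  set.seed(51)
  flags <- replicate(20, {
    n <- 10
    prior <- gaussian_density(c(blk = 0),
                              matrix(1 / 64, dimnames = list("blk", "blk")))
    base <- rnorm(n, 0, 0.125)
    mu <- c(base, base)  # no effect anywhere
    posts <- lapply(mu, function(m)
      gaussian_density(c(blk = m + rnorm(1, 0, 0.02)),
                       matrix(4e-4, dimnames = list("blk", "blk"))))
    X <- cbind(const = 1, drug = rep(c(0, 1), each = n))
    peb <- fit_peb(posts, prior, peb_design(X), field = "blk")
    peb_bma_all(peb, regressors = "drug")$presence[["blk:drug"]] > 0.95
  })
  expect_lt(mean(flags), 0.1)
})

test_that("design and schema errors are reported", {
  expect_error(peb_design(cbind(1, c(1, 1), c(2, 2))), "rank deficient")
  prior <- gaussian_density(c(a = 0), matrix(1 / 64, dimnames = list("a", "a")))
  post <- gaussian_density(c(a = 0.1), matrix(1e-4, dimnames = list("a", "a")))
  des <- peb_design(matrix(1, 2, 1))
  expect_error(fit_peb(list(post, post), prior, des, field = "zz"),
               "lacks field")
  peb <- fit_peb(list(post, post), prior, des, field = "a")
  expect_error(model_space_compare(peb, list()), "empty hypothesis")
  expect_error(model_space_compare(peb, list(h1 = character(0))), "empty hypothesis")
})
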