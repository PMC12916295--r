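# Parametric Empirical Bayes: a hierarchical GLM over first-level Gaussian
# posteriors, with Bayesian model reduction over parameter-set hypotheses
# and Bayesian model averaging.
#
# The first-level posterior of each subject/session is converted to its
# likelihood-equivalent Gaussian (posterior precision minus prior
# precision), so the second level sees both the estimates and their
# uncertainty. Given the between-subject log-precision gamma the model is
# linear-Gaussian and the group effects and free energy are closed-form;
# gamma is optimised by a bounded 1-D search.

#' Second-level PEB design
#'
#' @param X design matrix, one row per first-level model (subject/session);
#'   the first column should be a constant
#' @param names regressor names (defaults to column names of X)
#' @param beta_prior_var prior variance of each second-level effect
#'   (effects shrink to zero)
#' @param gamma_prior_var prior variance of the between-subject
#'   log-precision scale
#' @export
peb_design <- function(X, names = colnames(X), beta_prior_var = 1 / 16,
                       gamma_prior_var = 1 / 16) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  colnames(X) <- names
  structure(list(X = X, names = names, beta_prior_var = beta_prior_var,
                 gamma_prior_var = gamma_prior_var), class = "peb_design")
}

# likelihood-equivalent Gaussian of one first-level posterior
likelihood_equivalent <- function(post, prior, ridge = 1e-8) {
  Cp <- solve(post$cov)
  P0 <- solve(prior$cov)
  L <- (Cp + t(Cp)) / 2 - (P0 + t(P0)) / 2
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, ridge)
  L <- ev$vectors %*% (vals * t(ev$vectors))
  h <- drop(Cp %*% post$mean - P0 %*% prior$mean)
  nu <- solve(L, h)
  # log normaliser of N(th;mu,C)/N(th;m0,S0) = exp(-1/2 (th-nu)' L (th-nu)) * c
  logc <- -0.5 * (logdet(post$cov) - logdet(prior$cov)) -
    0.5 * (drop(t(post$mean) %*% Cp %*% post$mean) -
             drop(t(prior$mean) %*% P0 %*% prior$mean) -
             drop(t(nu) %*% L %*% nu))
  list(nu = nu, L = L, logc = logc)
}

# evidence and posterior of y = D b + e, e ~ N(0, Ve), b ~ N(0, Vb)
linear_gaussian_evidence <- function(y, D, Ve_inv, logdet_Ve, Vb) {
  Pb <- solve(Vb)
  Ppost <- crossprod(D, Ve_inv %*% D) + Pb
  Ppost <- (Ppost + t(Ppost)) / 2
  Spost <- solve(Ppost)
  mpost <- drop(Spost %*% crossprod(D, Ve_inv %*% y))
  n <- length(y)
  logZ <- -0.5 * (n * log(2 * pi) + logdet_Ve + logdet(Vb) + logdet(Ppost) +
                    drop(t(y) %*% Ve_inv %*% y) -
                    drop(t(mpost) %*% Ppost %*% mpost))
  list(logZ = logZ, mean = mpost, cov = (Spost + t(Spost)) / 2)
}

#' Fit a Parametric Empirical Bayes model over subject posteriors
#'
#' @param posteriors list of first-level `inversion_result`s or
#'   `gaussian_density`s (one per design row)
#' @param priors the first-level prior `gaussian_density` (shared)
#' @param design a [peb_design()]
#' @param field character vector naming the first-level parameters taken to
#'   the second level
#' @return object of class `peb_result`: `beta` (a `gaussian_density` over
#'   `field:regressor` effects), `F`, `gamma`, `expected` (re-estimated
#'   subject-level expected values, rows aligned with the design), plus the
#'   ingredients needed for model reduction
#' @export
fit_peb <- function(posteriors, priors, design, field) {
  stopifnot(inherits(design, "peb_design"))
  qs <- lapply(posteriors, function(p) {
    if (inherits(p, "inversion_result")) p$posterior else p
  })
  n <- length(qs)
  if (nrow(design$X) != n)
    stop("design rows (", nrow(design$X), ") do not match number of posteriors (",
         n, ")", call. = FALSE)
  for (q in qs) {
    miss <- setdiff(field, names(q$mean))
    if (length(miss))
      stop("posterior lacks field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  pr_f <- marginal_density(priors, field)
  f <- length(field); r <- ncol(design$X)

  lik <- lapply(qs, function(q) likelihood_equivalent(marginal_density(q, field), pr_f))
  eta <- unlist(lapply(lik, `[[`, "nu"))
  logc <- sum(vapply(lik, `[[`, numeric(1), "logc"))

  D <- kronecker(design$X, diag(1, f))   # (n f) x (r f), field index fastest
  Vb <- diag(design$beta_prior_var, r * f)
  Sb_base <- pr_f$cov / 16               # between-subject covariance at gamma = 0

  fe_gamma <- function(gamma) {
    Sb <- exp(-gamma) * Sb_base
    blocks <- lapply(lik, function(l) solve(l$L) + Sb)
    Ve_inv_blocks <- lapply(blocks, solve)
    logdet_Ve <- sum(vapply(blocks, logdet, numeric(1)))
    Ve_inv <- matrix(0, n * f, n * f)
    for (i in seq_len(n)) {
      idx <- (i - 1) * f + seq_len(f)
      Ve_inv[idx, idx] <- Ve_inv_blocks[[i]]
    }
    lz <- linear_gaussian_evidence(eta, D, Ve_inv, logdet_Ve, Vb)
    lz$F <- lz$logZ + logc - 0.5 * gamma^2 / design$gamma_prior_var -
      0.5 * log(2 * pi * design$gamma_prior_var)
    lz$Sb <- Sb
    lz
  }

  opt <- optimize(function(g) fe_gamma(g)$F, c(-5, 5), maximum = TRUE, tol = 1e-3)
  fit <- fe_gamma(opt$maximum)

  eff_names <- as.vector(outer(field, design$names, paste, sep = ":"))
  beta <- gaussian_density(setNames(fit$mean, eff_names), fit$cov)

  # re-estimated subject-level expected values under the group model
  Bm <- matrix(fit$mean, f, r)
  expected <- matrix(NA_real_, n, f, dimnames = list(NULL, field))
  for (i in seq_len(n)) {
    xi <- design$X[i, ]
    Xi <- kronecker(matrix(xi, 1), diag(1, f))
    Sg <- fit$Sb + Xi %*% fit$cov %*% t(Xi)
    mg <- drop(Bm %*% xi)
    Pi <- lik[[i]]$L + solve(Sg)
    expected[i, ] <- drop(solve(Pi, lik[[i]]$L %*% lik[[i]]$nu + solve(Sg, mg)))
  }

  structure(list(beta = beta, F = fit$F, gamma = opt$maximum,
                 expected = expected, field = field, design = design,
                 beta_prior = gaussian_density(
                   setNames(rep(0, r * f), eff_names), Vb),
                 lik = lik, logc = logc, eta = eta, D = D,
                 Sb = fit$Sb),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("peb_result: %d effects, F = %.2f, gamma = %.3f\n",
              length(x$beta$mean), x$F, x$gamma))
  print(x$beta)
  invisible(x)
}

#' Bayesian model reduction of a Gaussian posterior
#'
#' Re-scores a model under a reduced prior without refitting: given the
#' prior, the posterior obtained under it, and a reduced prior, returns the
#' change in log evidence and the reduced posterior.
#'
#' @param prior,posterior,reduced_prior `gaussian_density`s with a common
#'   layout
#' @return list(dF, posterior) where `dF` is the log evidence of the
#'   reduced model minus that of the full model
#' @export
bmr_gaussian <- function(prior, posterior, reduced_prior) {
  P0 <- solve(prior$cov); P <- solve(posterior$cov)
  P0r <- solve(reduced_prior$cov)
  Pr <- (P + P0r - P0); Pr <- (Pr + t(Pr)) / 2
  hr <- drop(P %*% posterior$mean + P0r %*% reduced_prior$mean -
               P0 %*% prior$mean)
  Cr <- solve(Pr)
  mr <- drop(Cr %*% hr)
  dF <- -0.5 * logdet(posterior$cov) - 0.5 * logdet(reduced_prior$cov) +
    0.5 * logdet(prior$cov) - 0.5 * logdet(Pr) +
    0.5 * (drop(t(hr) %*% Cr %*% hr) -
             drop(t(posterior$mean) %*% P %*% posterior$mean) -
             drop(t(reduced_prior$mean) %*% P0r %*% reduced_prior$mean) +
             drop(t(prior$mean) %*% P0 %*% prior$mean))
  list(dF = dF, posterior = gaussian_density(setNames(mr, names(posterior$mean)),
                                             (Cr + t(Cr)) / 2))
}

#' Softmax model probabilities from free energies
#' @param F numeric vector of free energies (nats)
#' @export
softmax_prob <- function(F) {
  z <- F - max(F)
  exp(z) / sum(exp(z))
}

# reduced second-level prior: switch off selected effects (variance -> ~0)
reduce_beta_prior <- function(peb, off, eps = 1e-8) {
  v <- diag(peb$beta_prior$cov)
  v[off] <- eps
  gaussian_density(peb$beta_prior$mean, diag(v, length(v)))
}

effect_names_for <- function(peb, fields, regressors) {
  as.vector(outer(fields, regressors, paste, sep = ":"))
}

#' Compare parameter-set hypotheses by Bayesian model reduction
#'
#' Each hypothesis names the first-level parameters whose effects for the
#' tested regressor(s) are allowed to vary; effects of all other
#' parameters on those regressors are switched off (prior variance reduced
#' to ~0) and the model re-scored without refitting. Free energies are
#' converted to posterior model probabilities with the softmax function.
#'
#' @param peb a fitted `peb_result`
#' @param hypotheses named list of character vectors (subsets of
#'   `peb$field`)
#' @param regressors which design regressors the hypotheses constrain
#'   (default: all but the first, i.e. the constant is never reduced)
#' @return data.frame with hypothesis, F (relative to the full model) and
#'   softmax probability
#' @export
model_space_compare <- function(peb, hypotheses,
                                regressors = peb$design$names[-1]) {
  stopifnot(inherits(peb, "peb_result"))
  if (!length(hypotheses)) stop("empty hypothesis list", call. = FALSE)
  dFs <- vapply(seq_along(hypotheses), function(k) {
    h <- hypotheses[[k]]
    if (!length(h)) stop("empty hypothesis: ", names(hypotheses)[k], call. = FALSE)
    bad <- setdiff(h, peb$field)
    if (length(bad))
      stop("hypothesis references unknown field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    off <- effect_names_for(peb, setdiff(peb$field, h), regressors)
    if (!length(off)) return(0)
    bmr_gaussian(peb$beta_prior, peb$beta, reduce_beta_prior(peb, off))$dF
  }, numeric(1))
  data.frame(hypothesis = names(hypotheses), F = dFs,
             probability = softmax_prob(dFs), row.names = NULL)
}

#' Bayesian model averaging over Gaussian posteriors
#'
#' Probability-weighted Gaussian mixture moments: the BMA mean is the
#' weighted mean and the BMA covariance includes the between-model
#' dispersion of the means.
#'
#' @param models list of `gaussian_density`s with a shared layout
#' @param weights model probabilities (normalised internally); or `F`, free
#'   energies converted via [softmax_prob()]
#' @param F free energies (alternative to `weights`)
#' @return a `gaussian_density`
#' @export
bayesian_model_average <- function(models, weights = NULL, F = NULL) {
  if (!length(models)) stop("no models to average", call. = FALSE)
  if (is.null(weights)) {
    if (is.null(F)) stop("supply weights or F", call. = FALSE)
    weights <- softmax_prob(F)
  }
  weights <- weights / sum(weights)
  nm <- names(models[[1]]$mean)
  for (m in models)
    if (!identical(names(m$mean), nm))
      stop("models have mismatched parameter layouts", call. = FALSE)
  mu <- Reduce(`+`, Map(function(m, w) w * m$mean, models, weights))
  S <- Reduce(`+`, Map(function(m, w) {
    d <- m$mean - mu
    w * (m$cov + outer(d, d))
  }, models, weights))
  gaussian_density(mu, S)
}

#' Model comparison and averaging over all on/off effect combinations
#'
#' Enumerates every combination of switching the tested effects on or off
#' (2^k models, k = fields x regressors under test), scores each by
#' Bayesian model reduction, and returns the BMA posterior together with
#' each effect's presence probability (the summed probability of models in
#' which it is on).
#'
#' @param peb a fitted `peb_result`
#' @param regressors regressors under test (default: all but the constant)
#' @param max_effects refuse to enumerate more than 2^max_effects models
#' @return list(bma = `gaussian_density`, presence = named probabilities,
#'   table = per-model F and probability)
#' @export
peb_bma_all <- function(peb, regressors = peb$design$names[-1],
                        max_effects = 12) {
  eff <- effect_names_for(peb, peb$field, regressors)
  k <- length(eff)
  if (k > max_effects)
    stop("model space too large: ", k, " effects", call. = FALSE)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(combos) <- eff
  scores <- numeric(nrow(combos))
  posts <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    off <- eff[!unlist(combos[i, ])]
    if (!length(off)) {
      scores[i] <- 0
      posts[[i]] <- peb$beta
    } else {
      red <- bmr_gaussian(peb$beta_prior, peb$beta,
                          reduce_beta_prior(peb, off))
      scores[i] <- red$dF
      posts[[i]] <- red$posterior
    }
  }
  w <- softmax_prob(scores)
  presence <- vapply(eff, function(e) sum(w[unlist(combos[[e]])]), numeric(1))
  list(bma = bayesian_model_average(posts, weights = w),
       presence = presence,
       table = data.frame(combos, F = scores, probability = w))
}
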