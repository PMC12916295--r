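# Variational Laplace inversion: Gaussian priors -> Gaussian posterior plus
# a free-energy bound on log evidence, by Gauss-Newton ascent with
# Levenberg-Marquardt damping and closed-form mode-wise noise-precision
# updates (ReML-style point estimates).

#' Default inversion settings
#'
#' @param max_iter maximum Gauss-Newton iterations
#' @param tol free-energy convergence tolerance (nats); convergence is
#'   declared after `n_consec` consecutive accepted steps below it
#' @param n_consec consecutive small-improvement steps required
#' @param fd_step central finite-difference step on the latents
#' @param update_noise update the per-mode log-precision hyperparameters
#'   between parameter steps; set `FALSE` to keep `lambda_init` fixed
#' @param lambda_init initial log noise precision, recycled per mode;
#'   `NULL` initialises from the residual variance at the prior mean
#' @export
vl_settings <- function(max_iter = 64, tol = 1e-2, n_consec = 3,
                        fd_step = 1e-3, update_noise = TRUE,
                        lambda_init = NULL) {
  list(max_iter = max_iter, tol = tol, n_consec = n_consec,
       fd_step = fd_step, update_noise = update_noise,
       lambda_init = lambda_init)
}

#' Laplace free energy of a Gaussian posterior
#'
#' Accuracy minus complexity: the expected log-likelihood of the data under
#' the linearised model at the posterior mode (IID Gaussian noise with one
#' log-precision per mode/column) minus the KL divergence from the prior.
#'
#' @param q posterior `gaussian_density` over the free parameters
#' @param priors prior `gaussian_density` with the same layout
#' @param resid residual matrix (samples x modes), data minus prediction at
#'   the posterior mean
#' @param J Jacobian of the stacked prediction w.r.t. the free parameters
#'   (rows ordered as `as.vector(resid)`); `NULL` drops the trace
#'   (uncertainty-propagation) term
#' @param lambda per-mode log noise precisions
#' @return free energy in nats
#' @export
free_energy <- function(q, priors, resid, J = NULL, lambda) {
  resid <- as.matrix(resid)
  M <- ncol(resid); N <- nrow(resid)
  lambda <- rep(lambda, length.out = M)
  h <- exp(lambda)
  rss <- colSums(resid^2)
  tr_m <- numeric(M)
  if (!is.null(J)) {
    JS <- J %*% q$cov
    diag_JSJ <- rowSums(JS * J)
    mode_of_row <- rep(seq_len(M), each = N)
    tr_m <- as.numeric(tapply(diag_JSJ, mode_of_row, sum))
  }
  acc <- -0.5 * sum(h * (rss + tr_m)) + 0.5 * N * sum(lambda) -
    (N * M / 2) * log(2 * pi)
  acc - kl_gaussian(q, priors)
}

#' Invert a nonlinear observation model by variational Laplace
#'
#' Gauss-Newton ascent on the free energy with Levenberg-Marquardt
#' damping: steps that decrease the free energy are rejected and damping is
#' increased. Parameters with prior variance exactly 0 are fixed at their
#' prior mean and excluded from the search. Noise is IID Gaussian with one
#' log-precision hyperparameter per mode (column of `y`), updated in closed
#' form (the update maximises F given the current residuals), so the free
#' energy is non-decreasing over accepted steps.
#'
#' @param y data matrix (samples x modes)
#' @param predictor function mapping a full named latent vector to a
#'   predicted matrix the shape of `y`
#' @param priors `gaussian_density` over the full latent layout (variance-0
#'   entries are fixed)
#' @param settings a [vl_settings()] list
#' @return list of class `inversion_result`: `posterior` (over free
#'   parameters), `full_mean` (all latents), `F`, `F_trace`, `lambda`,
#'   `predicted`, `converged`, `iterations`
#' @export
invert_vl <- function(y, predictor, priors, settings = vl_settings()) {
  y <- as.matrix(y)
  N <- nrow(y); M <- ncol(y)
  pv <- diag(priors$cov)
  free <- names(priors$mean)[pv > 0]
  if (!length(free)) stop("no free parameters (all prior variances 0)", call. = FALSE)
  mu0 <- priors$mean[free]
  S0 <- priors$cov[free, free, drop = FALSE]
  P0 <- solve(S0)
  prior_free <- gaussian_density(mu0, S0)

  full_theta <- function(th) { f <- priors$mean; f[free] <- th; f }
  th <- mu0
  pred <- predictor(full_theta(th))
  resid <- y - pred

  lambda <- settings$lambda_init
  if (is.null(lambda)) lambda <- rep(log(1 / max(mean(resid^2), 1e-12)), M)
  lambda <- rep(lambda, length.out = M)

  jac <- function(th) {
    J <- matrix(0, N * M, length(free))
    d <- settings$fd_step
    for (j in seq_along(free)) {
      tp <- th; tp[j] <- tp[j] + d
      tm <- th; tm[j] <- tm[j] - d
      J[, j] <- as.vector(predictor(full_theta(tp)) -
                            predictor(full_theta(tm))) / (2 * d)
    }
    J
  }
  mode_of_row <- rep(seq_len(M), each = N)

  fe <- function(th, resid, J, Sq, lambda) {
    q <- gaussian_density(th, Sq)
    free_energy(q, prior_free, resid, J, lambda)
  }

  nu <- 1e-4          # LM damping
  F_trace <- numeric(0)
  converged <- FALSE
  n_small <- 0
  J <- jac(th)

  post_cov <- function(J, lambda) {
    W <- exp(lambda)[mode_of_row]
    H <- crossprod(J * W, J) + P0
    solve((H + t(H)) / 2)
  }

  update_lambda <- function(resid, J, Sq) {
    rss <- colSums(resid^2)
    JS <- J %*% Sq
    tr <- as.numeric(tapply(rowSums(JS * J), mode_of_row, sum))
    pmin(pmax(log(N / (rss + tr)), -20), 20)
  }

  Sq <- post_cov(J, lambda)
  if (settings$update_noise) lambda <- update_lambda(resid, J, Sq)
  Sq <- post_cov(J, lambda)
  F_cur <- fe(th, resid, J, Sq, lambda)
  F_trace <- F_cur

  it <- 0
  while (it < settings$max_iter) {
    it <- it + 1
    W <- exp(lambda)[mode_of_row]
    H <- crossprod(J * W, J) + P0
    g <- drop(crossprod(J, W * as.vector(resid))) - drop(P0 %*% (th - mu0))

    accepted <- FALSE
    for (try in 1:8) {
      Hd <- H + nu * diag(diag(H), length(free))
      step <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (is.null(step)) { nu <- nu * 10; next }
      th_new <- th + step
      pred_new <- tryCatch(predictor(full_theta(th_new)), error = function(e) NULL)
      if (is.null(pred_new)) { nu <- nu * 10; next }
      resid_new <- y - pred_new
      Sq_new <- post_cov(J, lambda)
      F_new <- fe(th_new, resid_new, J, Sq_new, lambda)
      if (is.finite(F_new) && F_new > F_cur - 1e-12) {
        accepted <- TRUE
        dF <- F_new - F_cur
        th <- th_new; resid <- resid_new; pred <- pred_new
        nu <- max(nu / 4, 1e-8)
        break
      }
      nu <- nu * 10
    }
    if (!accepted) break

    J <- jac(th)
    Sq <- post_cov(J, lambda)
    if (settings$update_noise) {
      lambda <- update_lambda(resid, J, Sq)
      Sq <- post_cov(J, lambda)
    }
    F_cur <- fe(th, resid, J, Sq, lambda)
    F_trace <- c(F_trace, F_cur)

    n_small <- if (dF < settings$tol) n_small + 1 else 0
    if (n_small >= settings$n_consec) { converged <- TRUE; break }
  }

  Sq <- post_cov(J, lambda)
  structure(list(
    posterior = gaussian_density(th, Sq),
    full_mean = full_theta(th),
    F = F_cur, F_trace = F_trace, lambda = lambda,
    predicted = pred, converged = converged, iterations = it,
    free = free, prior = prior_free
  ), class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion_result: %d free parameters, F = %.2f, %s after %d iterations\n",
              length(x$free), x$F,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Forward prediction of a two-condition evoked response
#'
#' Deterministic forward pass of the microcircuit for the standard and
#' deviant conditions, projected to sensor modes; the row-bound matrix
#' (deviant stacked over standard) matches the layout used during
#' inversion.
#'
#' @param latents full named latent vector
#' @param config a `cmm_config`
#' @param obs an `observation_model`
#' @return matrix (2 x samples) x modes, deviant block first
#' @export
predict_response <- function(latents, config = cmm_config(),
                             obs = observation_model()) {
  make_erp_predictor(config, obs)(latents)
}

# Predictor closure with warm-started fixed points: during finite
# differencing the perturbed fixed points start from the last solution,
# cutting Newton iterations.
make_erp_predictor <- function(config, obs) {
  cache <- new.env(parent = emptyenv())
  cache$fp0 <- NULL; cache$fp1 <- NULL
  nt <- as.integer(round(config$t_end / config$dt)) + 1L

  run_cond <- function(latents, cond, start) {
    a <- assemble_model(latents, config, cond)
    x <- if (is.null(start)) leak_equilibrium(config) else start
    f <- drift_from_args(x, 0, a)
    h <- 1e-6
    for (it in 1:50) {
      if (sqrt(sum(f^2)) < 1e-10) break
      J <- matrix(0, 32, 32)
      for (j in 1:32) {
        xp <- x; xp[j] <- xp[j] + h
        xm <- x; xm[j] <- xm[j] - h
        J[, j] <- (drift_from_args(xp, 0, a) - drift_from_args(xm, 0, a)) / (2 * h)
      }
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        xn <- x + lam * step
        fn <- drift_from_args(xn, 0, a)
        if (all(is.finite(fn)) && sum(fn^2) < sum(f^2)) break
        lam <- lam / 2
        if (lam < 1e-6) { xn <- x; fn <- f; break }
      }
      x <- xn; f <- fn
      if (lam < 1e-6) break
    }
    V <- cmm_integrate_cpp(x, config$dt, nt, a$u_onset, a$u_width, a$u_amp,
                           a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                           a$Cm, a$gL, a$Vrev, a$mg_num,
                           a$sig_slope, a$sig_thresh, a$u_w, a$u_into_g,
                           a$v_bound)
    if (isTRUE(attr(V, "diverged")))
      stop("integration diverged during prediction at latents: ",
           paste(sprintf("%s=%.3g", names(a$latents), a$latents), collapse = ", "),
           call. = FALSE)
    list(Y = project_to_modes(list(V = V, equilibrium = x[1:8]), obs,
                              a$gain_scale),
         fp = x)
  }

  function(latents) {
    s <- run_cond(latents, 0, cache$fp0)
    d <- run_cond(latents, 1, cache$fp1)
    cache$fp0 <- s$fp; cache$fp1 <- d$fp
    rbind(d$Y, s$Y)
  }
}

#' Invert an evoked-response dataset
#'
#' Fits the two-region microcircuit to the deviant and standard responses
#' of one subject/session by variational Laplace. The deviant condition is
#' modelled with the self-connection modulation B active (between-trial
#' regressor 1) and the standard without (regressor 0).
#'
#' @param data an `erp_dataset`
#' @param priors `gaussian_density` over the latent layout (use
#'   [cmm_priors()] with a `free` mask)
#' @param config a `cmm_config`; its time grid must match the data
#' @param obs an `observation_model`
#' @param settings a [vl_settings()] list
#' @return an `inversion_result`
#' @export
invert_erp <- function(data, priors = cmm_priors(), config = cmm_config(),
                       obs = observation_model(), settings = vl_settings()) {
  stopifnot(inherits(data, "erp_dataset"))
  nt <- as.integer(round(config$t_end / config$dt)) + 1L
  if (length(data$time) != nt || abs(data$dt - config$dt) > 1e-9)
    stop("data time grid does not match the model configuration", call. = FALSE)
  y <- rbind(data$deviant, data$standard)
  invert_vl(y, make_erp_predictor(config, obs), priors, settings)
}

#' Serialise an inversion result to JSON
#' @param x an `inversion_result`
#' @param path output file
#' @export
write_inversion <- function(x, path) {
  obj <- list(
    free = x$free,
    posterior = list(mean = as.list(x$posterior$mean),
                     cov = unname(x$posterior$cov)),
    full_mean = as.list(x$full_mean),
    F = x$F, F_trace = x$F_trace, lambda = x$lambda,
    converged = x$converged, iterations = x$iterations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inversion
#' @export
read_inversion <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean <- unlist(obj$posterior$mean)
  cov <- as.matrix(obj$posterior$cov)
  structure(list(
    posterior = gaussian_density(mean, (cov + t(cov)) / 2),
    full_mean = unlist(obj$full_mean),
    F = obj$F, F_trace = obj$F_trace, lambda = obj$lambda,
    converged = obj$converged, iterations = obj$iterations,
    free = obj$free
  ), class = "inversion_result")
}
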