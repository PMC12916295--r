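# Independent oracles used across the suite. These re-derive quantities
# from first principles (plain R, closed forms) and never call the code
# paths they check.

# Drift of the full 32-state microcircuit written directly from the state
# equations, using assembled natural-scale arguments.
r_drift_oracle <- function(state, u, a) {
  V <- state[1:8]; gA <- state[9:16]; gG <- state[17:24]; gN <- state[25:32]
  m <- a$mg_num / (1 + 0.33 * exp(-0.06 * a$alpha * V))
  sig <- 1 / (1 + exp(-a$sig_slope * (V - a$sig_thresh)))
  ui <- u * a$u_w
  dV <- (a$gL * (a$Vrev[1] - V) + gA * (a$Vrev[2] - V) +
           gG * (a$Vrev[3] - V) + gN * m * (a$Vrev[4] - V)) / a$Cm + ui
  ug <- if (a$u_into_g) ui else 0
  dgA <- (as.vector(a$SA %*% sig) - gA) / a$tauA + ug
  dgG <- (as.vector(a$SG %*% sig) - gG) / a$tauG + ug
  dgN <- (as.vector(a$SN %*% sig) - gN) / a$tauN + ug
  c(dV, dgA, dgG, dgN)
}

# Conjugate Bayesian linear regression: posterior and exact log evidence
# for y = A theta + b + e, e ~ N(0, sd^2 I), theta ~ N(m0, S0).
linear_conjugate_oracle <- function(y, A, b, m0, S0, sd_noise) {
  n <- length(y)
  Pi <- 1 / sd_noise^2
  P0 <- solve(S0)
  Sp <- solve(Pi * crossprod(A) + P0)
  mp <- drop(Sp %*% (Pi * crossprod(A, y - b) + P0 %*% m0))
  S_marg <- diag(sd_noise^2, n) + A %*% S0 %*% t(A)
  r <- y - drop(A %*% m0) - b
  logZ <- -0.5 * (n * log(2 * pi) +
                    as.numeric(determinant(S_marg)$modulus) +
                    drop(t(r) %*% solve(S_marg, r)))
  list(mean = mp, cov = Sp, logZ = logZ)
}

# Closed-form two-level hierarchical GLS: first-level "posteriors" are
# exact Gaussians nu_i with known likelihood precision L_i; second level
# theta_i = B x_i + eps, eps ~ N(0, Sb); beta ~ N(0, Vb). Marginal
# posterior over vec(B) (field index fastest).
hierarchical_gls_oracle <- function(nu_list, L_list, X, Sb, Vb) {
  f <- length(nu_list[[1]]); n <- length(nu_list)
  D <- kronecker(X, diag(1, f))
  Vbig <- matrix(0, n * f, n * f)
  for (i in seq_len(n)) {
    idx <- (i - 1) * f + seq_len(f)
    Vbig[idx, idx] <- solve(L_list[[i]]) + Sb
  }
  W <- solve(Vbig)
  eta <- unlist(nu_list)
  P <- t(D) %*% W %*% D + solve(Vb)
  S <- solve(P)
  list(mean = drop(S %*% t(D) %*% W %*% eta), cov = S)
}

# Small default-configuration objects shared across tests
test_config <- function(...) cmm_config(...)
test_obs <- function() observation_model()
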