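# Conductance-based canonical microcircuit with an NMDA blockade parameter.
#
# Two regions (e.g. left/right inferior parietal cortex), four populations
# each: spiny stellate (ss), superficial pyramidal (sp), inhibitory
# interneuron (ii), deep pyramidal (dp). Population order is region-major:
# ss1 sp1 ii1 dp1 ss2 sp2 ii2 dp2. The state of each population is its
# membrane potential plus AMPA, GABA and NMDA conductances (dimensionless
# multiples of the unit conductance).

POP_NAMES <- c("ss_r1", "sp_r1", "ii_r1", "dp_r1",
               "ss_r2", "sp_r2", "ii_r2", "dp_r2")

#' Numerator constants of the magnesium switch
#'
#' The voltage-dependent removal of the magnesium block of NMDA channels is
#' a sigmoid in membrane potential. The modified form (with the blockade
#' parameter) saturates at 1.50265; the standard form saturates at 1.5.
#' Both are exposed because the two variants are both part of the model
#' family; the modified numerator is the documented constant used whenever
#' the blockade parameter is active.
#' @export
MG_NUMERATOR <- 1.50265

#' @rdname MG_NUMERATOR
#' @export
MG_NUMERATOR_STANDARD <- 1.5

#' Positivity transform of the NMDA blockade latent
#'
#' The blockade parameter is estimated as an unconstrained latent with a
#' Gaussian prior and enters the magnesium switch through its exponential,
#' guaranteeing a strictly positive scale factor.
#'
#' @param blk blockade latent (unitless), finite numeric
#' @return `exp(blk)`, strictly positive and monotone increasing in `blk`
#' @export
alpha_from_blockade <- function(blk) {
  if (!is.numeric(blk) || any(!is.finite(blk)))
    stop("blockade latent must be finite numeric", call. = FALSE)
  exp(blk)
}

#' Voltage-dependent magnesium switch of the NMDA channel
#'
#' Gating multiplier applied to the NMDA conductance:
#' \deqn{m(V) = num / (1 + 0.33 exp(-0.06\, e^{blk}\, V))}
#' Higher blockade latents steepen the voltage dependence, so at
#' hyperpolarised potentials (V < 0) the switch output -- and hence NMDA
#' conductance -- decreases with the blockade parameter; at V = 0 the output
#' is independent of it.
#'
#' @param V membrane potential (mV)
#' @param blk blockade latent; its exponential scales the voltage
#'   sensitivity (default 0, i.e. scale 1)
#' @param numerator saturation level; `MG_NUMERATOR` for the modified form,
#'   `MG_NUMERATOR_STANDARD` for the standard form
#' @return gating multiplier in (0, numerator)
#' @export
mg_switch <- function(V, blk = 0, numerator = MG_NUMERATOR) {
  if (any(!is.finite(V)) || any(!is.finite(blk)))
    stop("mg_switch: inputs must be finite", call. = FALSE)
  numerator / (1 + 0.33 * exp(-0.06 * exp(blk) * V))
}

#' Standard magnesium blockade-removal function
#'
#' The unmodified switch, without the blockade parameter:
#' \eqn{m(V) = 1.5 / (1 + 0.33 exp(-0.06 V))}.
#'
#' @param V membrane potential (mV)
#' @return gating multiplier in (0, 1.5)
#' @export
mg_switch_standard <- function(V) {
  if (any(!is.finite(V)))
    stop("mg_switch_standard: V must be finite", call. = FALSE)
  MG_NUMERATOR_STANDARD / (1 + 0.33 * exp(-0.06 * V))
}

#' Presynaptic firing-rate transform
#'
#' Logistic sigmoid of population voltage, bounded in (0, 1); the afferent
#' drive each population sends through the coupling matrices.
#'
#' @param V membrane potential (mV)
#' @param slope sigmoid steepness (1/mV), must be > 0
#' @param threshold midpoint voltage (mV)
#' @export
firing_rate <- function(V, slope, threshold) {
  if (!is.finite(slope) || slope <= 0)
    stop("firing_rate: slope must be positive", call. = FALSE)
  if (any(!is.finite(V)) || !is.finite(threshold))
    stop("firing_rate: inputs must be finite", call. = FALSE)
  1 / (1 + exp(-slope * (V - threshold)))
}

#' Model configuration: fixed biophysical constants and network topology
#'
#' Returns the default configuration of the two-region microcircuit:
#' reversal potentials, capacitance, leak conductance, channel time
#' constants, the firing sigmoid, the signed intrinsic coupling topology,
#' extrinsic (forward/backward) connection targets, the exogenous input
#' shape and its targets, and the observation defaults. All natural-scale
#' magnitudes here are the centres that log-latents scale multiplicatively.
#'
#' Intrinsic topology (within each region; row = target, column = source):
#' excitatory drive ss->sp, ss->ii, sp->ii, sp->dp, dp->ii carried by AMPA
#' and (at reduced weight) NMDA; inhibition ii->ss, ii->sp, ii->dp plus
#' self-inhibition on every population carried by GABA. The condition
#' modulation B log-scales the self-inhibition gains of a region for the
#' deviant condition only.
#'
#' @param ... named overrides of any default entry
#' @return a list of class `cmm_config`
#' @export
cmm_config <- function(...) {
  base <- list(
    n_regions = 2L,
    # membrane constants (per population, recycled)
    C  = 8,      # capacitance (ms * unit conductance)
    g_L = 1,     # leak conductance (unit conductance)
    V_L = -70,   # leak reversal (mV)
    V_AMPA = 60, # AMPA reversal (mV)
    V_GABA = -90,# GABA reversal (mV)
    V_NMDA = 60, # NMDA reversal (mV)
    tau_AMPA = 4,    # ms
    tau_GABA = 16,   # ms
    tau_NMDA = 100,  # ms
    mg_numerator = MG_NUMERATOR,
    sig_slope = 0.1,       # 1/mV
    sig_thresh = -45,      # mV (resting potential + 25 mV)
    # intrinsic coupling magnitudes (4x4, row target, col source)
    S_exc = rbind(            #   ss   sp   ii   dp
      c(0,    0,    0,  0),   # ss
      c(0.8,  0,    0,  0),   # sp <- ss
      c(0.25, 0.25, 0,  0.25),# ii <- ss, sp, dp
      c(0,    0.5,  0,  0)),  # dp <- sp
    S_inh = rbind(
      c(0.8, 0,   0.8, 0),
      c(0,   0.8, 1.0, 0),
      c(0,   0,   0.8, 0),
      c(0,   0,   0.6, 0.8)),
    nmda_frac = 0.25,       # NMDA topology = nmda_frac * S_exc
    # extrinsic gains (sp -> ss,dp forward; dp -> sp,ii backward)
    fwd_gain = 0.4,
    bwd_gain = 0.2,
    # exogenous (thalamic) input: Gaussian bump
    u_onset = 60,   # ms
    u_width = 16,   # ms
    u_amp   = 0.02, # peak drive, delivered to spiny stellate cells
    u_targets = c("ss_r1", "ss_r2"),
    u_into_g = TRUE, # deliver u to the conductance equations as printed
    # integration
    dt = 1,          # ms
    t_end = 300,     # ms
    v_bound = 400,   # |V| divergence bound (mV)
    # observation
    n_modes = 8L,
    hanning = TRUE,
    source_pops = c("sp_r1", "dp_r1", "sp_r2", "dp_r2")
  )
  cfg <- modifyList(base, list(...))
  class(cfg) <- "cmm_config"
  cfg
}

#' Latent parameter vector and Gaussian priors
#'
#' All tunable parameters are unconstrained latents: log-scalings of
#' positive natural quantities around the configuration defaults, except
#' the blockade latents (which enter through the magnesium switch) and the
#' condition modulations B (log-scalings of self-inhibition active for the
#' deviant condition only). Fixing a parameter is expressed by a prior
#' variance of exactly 0 (a prior-variance mask), which the inversion
#' honours by excluding it from the search space.
#'
#' Default prior variances: 1/64 for blockade, time-constant, extrinsic,
#' intrinsic-scale and input latents; 1/16 for the condition modulations;
#' 1/8 for the observation gain.
#'
#' @param free character vector of latent names estimated (prior variance
#'   kept); all others are fixed at their prior mean. `NULL` keeps every
#'   latent free.
#' @param mean named numeric overrides of prior means (default all 0)
#' @param variance named numeric overrides of prior variances
#' @return a `gaussian_density` over the full latent layout
#' @export
cmm_priors <- function(free = NULL, mean = NULL, variance = NULL) {
  nm <- c("blk_r1", "blk_r2",
          "t_ampa_r1", "t_ampa_r2", "t_gaba_r1", "t_gaba_r2",
          "t_nmda_r1", "t_nmda_r2",
          "b_r1", "b_r2",
          "g_fwd", "g_bwd", "s_int_r1", "s_int_r2",
          "u_onset", "u_width", "u_amp", "gain")
  m <- setNames(rep(0, length(nm)), nm)
  v <- setNames(rep(1 / 64, length(nm)), nm)
  v[c("b_r1", "b_r2")] <- 1 / 16
  v["gain"] <- 1 / 8
  if (!is.null(mean)) m[names(mean)] <- mean
  if (!is.null(variance)) v[names(variance)] <- variance
  if (!is.null(free)) {
    bad <- setdiff(free, nm)
    if (length(bad)) stop("unknown latent name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    v[setdiff(nm, free)] <- 0
  }
  gaussian_density(m, diag(v, length(nm)))
}

#' @export
latent_names <- function() names(cmm_priors()$mean)

pop_index <- function(names) match(names, POP_NAMES)

#' Assemble natural-scale model matrices from latents
#'
#' Expands a named latent vector into the quantities the integrator needs:
#' 8x8 coupling matrices per channel (with extrinsic forward/backward
#' entries and, for the deviant condition, B-scaled self-inhibition),
#' per-population time constants and blockade scale factors, and the input
#' bump parameters.
#'
#' @param latents named numeric vector over `latent_names()` (missing names
#'   default to 0)
#' @param config a `cmm_config`
#' @param condition_index 1 for the deviant condition (B active), 0 for the
#'   standard
#' @return list of integrator arguments
#' @export
assemble_model <- function(latents, config = cmm_config(), condition_index = 0) {
  th <- setNames(rep(0, length(latent_names())), latent_names())
  if (length(latents)) {
    bad <- setdiff(names(latents), names(th))
    if (length(bad)) stop("unknown latent name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    th[names(latents)] <- latents
  }
  if (any(!is.finite(th))) stop("latents must be finite", call. = FALSE)

  s_int <- exp(c(th["s_int_r1"], th["s_int_r2"]))
  SA <- matrix(0, 8, 8); SG <- matrix(0, 8, 8); SN <- matrix(0, 8, 8)
  for (r in 1:2) {
    idx <- (r - 1) * 4 + 1:4
    SA[idx, idx] <- config$S_exc * s_int[r]
    SN[idx, idx] <- config$S_exc * config$nmda_frac * s_int[r]
    SG[idx, idx] <- config$S_inh * s_int[r]
  }
  # condition modulation: log-scale self-inhibition for the deviant
  if (condition_index != 0) {
    b <- exp(condition_index * c(th["b_r1"], th["b_r2"]))
    for (r in 1:2) {
      idx <- (r - 1) * 4 + 1:4
      diag(SG[idx, idx]) <- diag(SG[idx, idx]) * b[r]
      SG[idx, idx] <- SG[idx, idx]  # keep explicit
    }
  }
  # extrinsic: forward sp_r1 -> ss_r2, dp_r2; backward dp_r2 -> sp_r1, ii_r1
  fwd <- config$fwd_gain * exp(th["g_fwd"])
  bwd <- config$bwd_gain * exp(th["g_bwd"])
  sp1 <- pop_index("sp_r1"); dp2 <- pop_index("dp_r2")
  for (tgt in pop_index(c("ss_r2", "dp_r2"))) {
    SA[tgt, sp1] <- SA[tgt, sp1] + fwd
    SN[tgt, sp1] <- SN[tgt, sp1] + fwd * config$nmda_frac
  }
  for (tgt in pop_index(c("sp_r1", "ii_r1"))) {
    SA[tgt, dp2] <- SA[tgt, dp2] + bwd
    SN[tgt, dp2] <- SN[tgt, dp2] + bwd * config$nmda_frac
  }

  rep2 <- function(x) rep(unname(x), each = 4)
  tauA <- config$tau_AMPA * rep2(exp(c(th["t_ampa_r1"], th["t_ampa_r2"])))
  tauG <- config$tau_GABA * rep2(exp(c(th["t_gaba_r1"], th["t_gaba_r2"])))
  tauN <- config$tau_NMDA * rep2(exp(c(th["t_nmda_r1"], th["t_nmda_r2"])))
  alpha <- rep2(alpha_from_blockade(c(th["blk_r1"], th["blk_r2"])))

  u_w <- as.numeric(POP_NAMES %in% config$u_targets)

  list(
    SA = SA, SG = SG, SN = SN,
    alpha = alpha, tauA = tauA, tauG = tauG, tauN = tauN,
    Cm = rep(config$C, 8), gL = rep(config$g_L, 8),
    Vrev = c(config$V_L, config$V_AMPA, config$V_GABA, config$V_NMDA),
    mg_num = config$mg_numerator,
    sig_slope = config$sig_slope, sig_thresh = config$sig_thresh,
    u_onset = unname(config$u_onset * exp(th["u_onset"])),
    u_width = unname(config$u_width * exp(th["u_width"])),
    u_amp = unname(config$u_amp * exp(th["u_amp"])),
    u_w = u_w, u_into_g = as.integer(isTRUE(config$u_into_g)),
    v_bound = config$v_bound,
    gain_scale = unname(exp(th["gain"])),
    latents = th
  )
}

#' Time derivatives of the full microcircuit state
#'
#' Evaluates the drift of the 32-dimensional state (8 membrane potentials
#' followed by 8 AMPA, 8 GABA and 8 NMDA conductances) at one instant, for
#' a given exogenous input value. Used by the fixed-point solver and
#' directly testable against the stated state equations.
#'
#' @param state numeric length-32 state vector
#' @param latents named latent vector (see [assemble_model()])
#' @param config a `cmm_config`
#' @param u scalar exogenous input value delivered through the configured
#'   input weights
#' @param condition_index deviant (1) vs standard (0)
#' @return length-32 derivative vector
#' @export
population_drift <- function(state, latents = numeric(), config = cmm_config(),
                             u = 0, condition_index = 0) {
  if (length(state) != 32 || any(!is.finite(state)))
    stop("state must be a finite length-32 vector", call. = FALSE)
  a <- assemble_model(latents, config, condition_index)
  cmm_drift_cpp(state, u, a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                a$Cm, a$gL, a$Vrev, a$mg_num, a$sig_slope, a$sig_thresh,
                a$u_w, a$u_into_g)
}

drift_from_args <- function(state, u, a) {
  cmm_drift_cpp(state, u, a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                a$Cm, a$gL, a$Vrev, a$mg_num, a$sig_slope, a$sig_thresh,
                a$u_w, a$u_into_g)
}

#' Leak equilibrium state (initial guess for the fixed point)
#' @param config a `cmm_config`
#' @export
leak_equilibrium <- function(config = cmm_config()) {
  c(rep(config$V_L, 8), rep(0, 24))
}

#' Numerically solve the input-free fixed point of the microcircuit
#'
#' Damped Newton iteration on the drift with a finite-difference Jacobian,
#' started from the leak equilibrium. With zero exogenous input the model
#' rests at this point, so evoked responses are deviations from it.
#'
#' @param latents named latent vector
#' @param config a `cmm_config`
#' @param condition_index deviant (1) vs standard (0)
#' @param tol drift-norm convergence tolerance
#' @param max_iter Newton iteration cap
#' @return list(state, drift_norm, converged)
#' @export
find_fixed_point <- function(latents = numeric(), config = cmm_config(),
                             condition_index = 0, tol = 1e-10, max_iter = 50) {
  a <- assemble_model(latents, config, condition_index)
  x <- leak_equilibrium(config)
  f <- drift_from_args(x, 0, a)
  h <- 1e-6
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(f^2)) < tol) break
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
  }
  list(state = x, drift_norm = sqrt(sum(f^2)), converged = sqrt(sum(f^2)) < tol)
}

#' Serialise latents + priors to JSON
#'
#' Writes the latent vector, its natural-scale expansions (time constants,
#' blockade scale factors, input shape) and the prior moments to a JSON
#' file; [read_params()] restores the latents and priors.
#'
#' @param latents named latent vector
#' @param priors a `gaussian_density` over the latent layout
#' @param path output file
#' @param config a `cmm_config`
#' @export
write_params <- function(latents, priors, path, config = cmm_config()) {
  a <- assemble_model(latents, config)
  obj <- list(
    latents = as.list(a$latents),
    natural = list(
      alpha_nmda = unname(a$alpha[c(1, 5)]),
      tau_ampa = unname(a$tauA[c(1, 5)]),
      tau_gaba = unname(a$tauG[c(1, 5)]),
      tau_nmda = unname(a$tauN[c(1, 5)]),
      u_onset = a$u_onset, u_width = a$u_width, u_amp = a$u_amp,
      gain_scale = a$gain_scale
    ),
    prior = list(mean = as.list(priors$mean),
                 variance = as.list(diag(priors$cov)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lat <- unlist(obj$latents)
  pm <- unlist(obj$prior$mean)
  pv <- unlist(obj$prior$variance)
  list(latents = lat,
       priors = gaussian_density(pm, diag(pv, length(pv))))
}
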