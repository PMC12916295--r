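# Forward model: integrate the microcircuit over the epoch and project
# source depolarisation to sensor modes.

#' Thalamic input bump
#'
#' Smooth unimodal (Gaussian) exogenous input peaking at `onset`.
#'
#' @param t time (ms), vectorised
#' @param onset peak time (ms)
#' @param width Gaussian standard deviation (ms), > 0
#' @param amplitude peak value
#' @export
thalamic_input <- function(t, onset = 60, width = 16, amplitude = 1) {
  if (!is.finite(width) || width <= 0)
    stop("thalamic_input: width must be positive", call. = FALSE)
  amplitude * exp(-0.5 * ((t - onset) / width)^2)
}

#' Integrate one trial of the microcircuit
#'
#' Fixed-step 4th-order Runge-Kutta integration of the full state over the
#' epoch, started at the input-free fixed point of the condition-specific
#' model, so that with zero input amplitude the output is flat.
#'
#' @param latents named latent vector
#' @param condition_index 1 deviant, 0 standard
#' @param config a `cmm_config` (dt, t_end, input shape, divergence bound)
#' @return list with `time` (ms), `V` (time x 8 membrane potentials),
#'   `equilibrium` (length-8 equilibrium potentials)
#' @export
integrate_trial <- function(latents = numeric(), condition_index = 0,
                            config = cmm_config()) {
  a <- assemble_model(latents, config, condition_index)
  fp <- find_fixed_point(latents, config, condition_index)
  nt <- as.integer(round(config$t_end / config$dt)) + 1L
  V <- cmm_integrate_cpp(fp$state, config$dt, nt,
                         a$u_onset, a$u_width, a$u_amp,
                         a$SA, a$SG, a$SN, a$alpha, a$tauA, a$tauG, a$tauN,
                         a$Cm, a$gL, a$Vrev, a$mg_num,
                         a$sig_slope, a$sig_thresh, a$u_w, a$u_into_g,
                         a$v_bound)
  if (isTRUE(attr(V, "diverged"))) {
    bad <- paste(sprintf("%s=%.3g", names(a$latents), a$latents), collapse = ", ")
    stop("integration diverged (|V| > ", config$v_bound, " mV) at latents: ",
         bad, call. = FALSE)
  }
  colnames(V) <- POP_NAMES
  list(time = seq(0, by = config$dt, length.out = nt), V = V,
       equilibrium = fp$state[1:8])
}

#' Observation model: source-to-mode gain and windowing
#'
#' @param gain numeric matrix (modes x source populations); the default
#'   synthetic gain mixes the four pyramidal sources into eight modes with
#'   a fixed, full-rank pattern
#' @param hanning logical; apply a Hanning taper over the epoch after
#'   projection
#' @param source_pops which populations contribute to the measured signal
#' @export
observation_model <- function(gain = default_gain(), hanning = TRUE,
                              source_pops = c("sp_r1", "dp_r1", "sp_r2", "dp_r2")) {
  gain <- as.matrix(gain)
  if (any(!is.finite(gain))) stop("gain must be finite", call. = FALSE)
  if (ncol(gain) != length(source_pops))
    stop("gain columns must match source populations", call. = FALSE)
  structure(list(gain = gain, hanning = isTRUE(hanning),
                 source_pops = source_pops), class = "observation_model")
}

#' Default synthetic source-to-mode gain matrix
#'
#' A fixed deterministic 8 x 4 mixing pattern standing in for the anatomical
#' lead field (which is out of scope); full column rank, with magnitudes
#' shared across the two regions to echo hemispheric symmetry constraints.
#' @param n_modes number of sensor modes
#' @export
default_gain <- function(n_modes = 8L) {
  s <- seq_len(4)
  G <- outer(seq_len(n_modes), s, function(m, k) {
    sin(pi * m * k / 4.5) + 0.35 * cos(0.7 * m + 1.3 * k)
  })
  0.6 * G
}

#' Hanning taper of length n (zero at both endpoints)
#' @param n window length
#' @export
hanning_window <- function(n) {
  if (n < 2) stop("hanning_window: n must be >= 2", call. = FALSE)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Project source activity to sensor modes
#'
#' Linear projection of the depolarisation of the source populations
#' (relative to equilibrium) through the gain matrix, followed by an
#' optional Hanning taper over the epoch.
#'
#' @param trial result of [integrate_trial()] (or a plain time x 8 matrix
#'   of membrane potentials with an `equilibrium` attribute of zeros)
#' @param obs an `observation_model`
#' @param gain_scale scalar multiplier of the gain (the observation-gain
#'   latent's exponential)
#' @return time x modes numeric matrix
#' @export
project_to_modes <- function(trial, obs = observation_model(), gain_scale = 1) {
  if (is.list(trial)) {
    V <- trial$V
    eq <- trial$equilibrium
  } else {
    V <- trial
    eq <- rep(0, ncol(V))
  }
  idx <- pop_index(obs$source_pops)
  src <- sweep(V[, idx, drop = FALSE], 2, eq[idx], "-")
  Y <- src %*% t(obs$gain) * gain_scale
  if (obs$hanning) Y <- Y * hanning_window(nrow(Y))
  Y
}

#' Reduce multichannel data to leading spatial modes
#'
#' Singular-value decomposition of the (time x channel) data matrix; the
#' first `k` right singular vectors define the spatial modes and the data
#' are projected onto them. Captured-variance fractions are returned and
#' are non-increasing across modes.
#'
#' @param raw time x channel numeric matrix
#' @param k number of modes to keep (1 <= k <= channels)
#' @return list(modes = time x k matrix, projection = channels x k,
#'   var_frac = length-k variance fractions)
#' @export
reduce_to_modes <- function(raw, k = 8L) {
  raw <- as.matrix(raw)
  if (!is.numeric(k) || k <= 0) stop("k must be positive", call. = FALSE)
  k <- as.integer(k)
  if (k > ncol(raw)) stop("k exceeds channel count", call. = FALSE)
  sv <- svd(raw, nu = 0, nv = ncol(raw))
  P <- sv$v[, seq_len(k), drop = FALSE]
  list(modes = raw %*% P, projection = P,
       var_frac = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Simulate a two-condition evoked dataset
#'
#' Runs the forward model for the standard (condition 0) and deviant
#' (condition 1) trials and projects to sensor modes, optionally adding IID
#' Gaussian sensor noise.
#'
#' @param latents named latent vector
#' @param config a `cmm_config`
#' @param obs an `observation_model`
#' @param noise_sd sensor noise standard deviation (0 = noiseless)
#' @param subject,session identifiers stored in the dataset
#' @return an `erp_dataset`
#' @export
simulate_erp <- function(latents = numeric(), config = cmm_config(),
                         obs = observation_model(), noise_sd = 0,
                         subject = "sim", session = "s1") {
  a <- assemble_model(latents, config)
  std <- integrate_trial(latents, 0, config)
  dev <- integrate_trial(latents, 1, config)
  Ys <- project_to_modes(std, obs, a$gain_scale)
  Yd <- project_to_modes(dev, obs, a$gain_scale)
  if (noise_sd > 0) {
    Ys <- Ys + matrix(rnorm(length(Ys), 0, noise_sd), nrow(Ys))
    Yd <- Yd + matrix(rnorm(length(Yd), 0, noise_sd), nrow(Yd))
  }
  erp_dataset(subject = subject, session = session, time = std$time,
              deviant = Yd, standard = Ys, dt = config$dt,
              meta = list(noise_sd = noise_sd))
}
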