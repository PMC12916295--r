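# Synthetic study cohorts with known ground truth. Two designs are
# emulated: a placebo-controlled drug crossover in healthy adults (two
# sessions per subject; the drug shifts the NMDA blockade latent upward)
# and a longitudinal patient cohort (baseline + follow-up, with an
# MMSE-linked gradient and a negative session shift of the blockade).
#
# Only the blockade latents vary across subjects by default; all other
# latents sit at fixed values shared by the cohort (a deliberate
# simplification that keeps recovery well-posed).

#' Cohort specification
#'
#' Defaults encode the emulated study conditions: crossover n = 19 with a
#' drug shift of +0.42 on the blockade latent; longitudinal n = 42 at
#' baseline with 30/42 completing follow-up, an MMSE slope of 0.06 per
#' point and a session shift of -0.125; MMSE ~ N(24.9, 3.61^2) truncated
#' to [10, 30]; scan interval ~ U(0.8, 2.2) years; between-subject SD of
#' the blockade latent 0.125 (the prior SD); sensor noise SD 0.05.
#'
#' @param design "crossover" or "longitudinal"
#' @param n number of subjects
#' @param drug_shift added to the blockade latent (both regions) in the
#'   drug session
#' @param mmse_slope blockade-latent change per MMSE point (about its mean)
#' @param session_shift added to the blockade latent at follow-up
#' @param subject_sd between-subject SD of the blockade latent
#' @param noise_sd sensor noise SD
#' @param mmse_mean,mmse_sd,mmse_range MMSE sampling distribution
#' @param interval_range follow-up interval range (years)
#' @param followup_fraction fraction of subjects scanned twice
#' @param b_latent deviant-condition self-connection modulation (shared)
#' @param blk_mean population mean of the blockade latent
#' @param seed RNG seed recorded in all outputs
#' @export
cohort_spec <- function(design = c("crossover", "longitudinal"),
                        n = if (design[1] == "crossover") 19L else 42L,
                        drug_shift = 0.42,
                        mmse_slope = 0.06,
                        session_shift = -0.125,
                        subject_sd = 0.125,
                        noise_sd = 0.05,
                        mmse_mean = 24.9, mmse_sd = 3.61,
                        mmse_range = c(10, 30),
                        interval_range = c(0.8, 2.2),
                        followup_fraction = 30 / 42,
                        b_latent = 0.3,
                        blk_mean = 0,
                        seed = 1L) {
  design <- match.arg(design)
  if (n < 2) stop("cohort needs n >= 2", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(design = design, n = as.integer(n), drug_shift = drug_shift,
                 mmse_slope = mmse_slope, session_shift = session_shift,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 mmse_range = mmse_range, interval_range = interval_range,
                 followup_fraction = followup_fraction,
                 b_latent = b_latent, blk_mean = blk_mean,
                 seed = as.integer(seed)), class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

subject_latents <- function(blk, b_latent) {
  c(blk_r1 = blk, blk_r2 = blk, b_r1 = b_latent, b_r2 = b_latent)
}

#' Generate a drug/placebo crossover cohort
#'
#' Each subject contributes two sessions. The drug session's blockade
#' latent (both regions) is the subject baseline plus `drug_shift`;
#' responses are simulated by the forward model with IID Gaussian sensor
#' noise. Ground-truth latents are returned alongside the datasets.
#'
#' @param spec a `cohort_spec` with design "crossover"
#' @param config a `cmm_config`
#' @param obs an `observation_model`
#' @return list(datasets, covariates, truth, spec); `covariates` rows align
#'   with `datasets` (subject, session, drug indicator)
#' @export
generate_crossover <- function(spec = cohort_spec("crossover"),
                               config = cmm_config(),
                               obs = observation_model()) {
  stopifnot(inherits(spec, "cohort_spec"), spec$design == "crossover")
  set.seed(spec$seed)
  base_blk <- rnorm(spec$n, spec$blk_mean, spec$subject_sd)
  datasets <- list(); cov <- list(); truth <- list()
  k <- 0
  for (i in seq_len(spec$n)) {
    subj <- sprintf("sub%02d", i)
    for (sess in c("placebo", "drug")) {
      blk <- base_blk[i] + if (sess == "drug") spec$drug_shift else 0
      lat <- subject_latents(blk, spec$b_latent)
      k <- k + 1
      datasets[[k]] <- simulate_erp(lat, config, obs, spec$noise_sd,
                                    subject = subj, session = sess)
      datasets[[k]]$meta$seed <- spec$seed
      cov[[k]] <- data.frame(subject = subj, session = sess,
                             drug = as.integer(sess == "drug"),
                             stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(subject = subj, session = sess,
                               blk_r1 = blk, blk_r2 = blk,
                               stringsAsFactors = FALSE)
    }
  }
  list(datasets = datasets, covariates = do.call(rbind, cov),
       truth = do.call(rbind, truth), spec = spec)
}

#' Generate a longitudinal patient cohort
#'
#' Baseline blockade latents follow an MMSE-linked gradient:
#' `blk = blk_mean + mmse_slope * (MMSE - mean(MMSE)) + N(0, subject_sd^2)`;
#' follow-up (a `followup_fraction` subset of subjects) adds
#' `session_shift`. Scan intervals are uniform on `interval_range` years.
#'
#' @inheritParams generate_crossover
#' @param spec a `cohort_spec` with design "longitudinal"
#' @return list(datasets, covariates, truth, spec); covariates hold
#'   subject, session, MMSE and interval (0 at baseline, years at
#'   follow-up)
#' @export
generate_longitudinal <- function(spec = cohort_spec("longitudinal"),
                                  config = cmm_config(),
                                  obs = observation_model()) {
  stopifnot(inherits(spec, "cohort_spec"), spec$design == "longitudinal")
  set.seed(spec$seed)
  mmse <- rtrunc_norm(spec$n, spec$mmse_mean, spec$mmse_sd,
                      spec$mmse_range[1], spec$mmse_range[2])
  base_blk <- spec$blk_mean + spec$mmse_slope * (mmse - mean(mmse)) +
    rnorm(spec$n, 0, spec$subject_sd)
  n_fu <- round(spec$followup_fraction * spec$n)
  fu_idx <- sort(sample.int(spec$n, n_fu))
  interval <- runif(spec$n, spec$interval_range[1], spec$interval_range[2])

  datasets <- list(); cov <- list(); truth <- list()
  k <- 0
  emit <- function(i, sess, blk, intv) {
    subj <- sprintf("sub%02d", i)
    lat <- subject_latents(blk, spec$b_latent)
    k <<- k + 1
    datasets[[k]] <<- simulate_erp(lat, config, obs, spec$noise_sd,
                                   subject = subj, session = sess)
    datasets[[k]]$meta$seed <<- spec$seed
    cov[[k]] <<- data.frame(subject = subj, session = sess,
                            mmse = mmse[i], interval_years = intv,
                            stringsAsFactors = FALSE)
    truth[[k]] <<- data.frame(subject = subj, session = sess,
                              blk_r1 = blk, blk_r2 = blk, mmse = mmse[i],
                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n)) emit(i, "baseline", base_blk[i], 0)
  for (i in fu_idx) emit(i, "followup", base_blk[i] + spec$session_shift,
                         interval[i])
  list(datasets = datasets, covariates = do.call(rbind, cov),
       truth = do.call(rbind, truth), spec = spec)
}

#' Write a generated cohort to disk
#'
#' ERP files (TSV + JSON sidecars), a covariate CSV and a ground-truth JSON
#' (including the seed) under `dir`.
#' @param cohort result of [generate_crossover()] or
#'   [generate_longitudinal()]
#' @param dir output directory
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in cohort$datasets) write_erp(d, dir)
  write.table(cohort$covariates, file.path(dir, "covariates.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spec = unclass(cohort$spec), truth = cohort$truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
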