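#!/usr/bin/env Rscript
# Patient-cohort experiments: (1) severity - does the NMDA blockade latent
# track baseline MMSE? (2) progression - does it fall between baseline and
# follow-up? Both analyses invert every session with the blockade latents
# free and test second-level effects with PEB.
#
# Writes results/severity_effects.csv and results/progression_effects.csv.

suppressPackageStartupMessages(library(nmdadcm))
dir.create("results", showWarnings = FALSE)

sev <- run_experiment(run_config("severity", seed = 20260927,
                                 out = "results/severity"))
m <- unlist(sev$effects$mean); s <- unlist(sev$effects$sd)
cat("Severity (MMSE) effect on the blockade latent:\n")
cat(sprintf("  region 1: %.4f (sd %.4f), region 2: %.4f (sd %.4f)\n",
            m["blk_r1:mmse"], s["blk_r1:mmse"],
            m["blk_r2:mmse"], s["blk_r2:mmse"]))
cat(sprintf("  sensor-level amplitude-MMSE regression: r = %.2f, p = %.3g\n",
            sev$sensor$mmse_regression$r, sev$sensor$mmse_regression$p))
write.csv(data.frame(effect = names(m), mean = m, sd = s),
          "results/severity_effects.csv", row.names = FALSE)

prog <- run_experiment(run_config("progression", seed = 20260928,
                                  out = "results/progression"))
m <- unlist(prog$effects$mean); s <- unlist(prog$effects$sd)
sc <- prog$session_contrast$blk_r1
cat("\nProgression (follow-up vs baseline) effect on the blockade latent:\n")
cat(sprintf("  raw session coefficient region 1: %.3f (sd %.3f)\n",
            m["blk_r1:session"], s["blk_r1:session"]))
cat(sprintf("  session contrast (change at the average interval): %.3f (sd %.3f), P(< 0) = %.3f\n",
            sc$mean, sc$sd, sc$p_negative))
cat("  note: the session and standardised-interval regressors are\n",
    " collinear by design, so the raw coefficients share the planted\n",
    " shift; the session contrast is the identified quantity\n")
cat(sprintf("  sensor-level paired t: t(%d) = %.2f, p = %.3g\n",
            prog$sensor$paired_t$df, prog$sensor$paired_t$t,
            prog$sensor$paired_t$p))
write.csv(data.frame(effect = names(m), mean = m, sd = s),
          "results/progression_effects.csv", row.names = FALSE)
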