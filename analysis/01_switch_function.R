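#!/usr/bin/env Rscript
# The voltage-dependent magnesium switch of the NMDA channel, and how the
# blockade parameter reshapes it.
#
# Writes results/switch_function.csv: the switch output over a voltage grid
# for a range of blockade latents, for both the modified (numerator
# 1.50265) and standard (numerator 1.5) forms. The printed summary reports
# the saturation levels and the direction of the blockade effect.

suppressPackageStartupMessages(library(nmdadcm))
dir.create("results", showWarnings = FALSE)

V <- seq(-100, 60, by = 1)
blks <- c(-1, -0.5, 0, 0.5, 1, 2, 4)

tab <- do.call(rbind, lapply(blks, function(b) {
  data.frame(V = V, blk = b,
             m_modified = mg_switch(V, b),
             m_standard = mg_switch_standard(V))
}))
write.csv(tab, "results/switch_function.csv", row.names = FALSE)

cat("Saturation of the modified switch (V -> +Inf, blk = 0):",
    mg_switch(1e6, 0), "\n")
cat("Saturation of the standard switch (V -> +Inf):       ",
    mg_switch_standard(1e6), "\n")
at70 <- sapply(blks, function(b) mg_switch(-70, b))
cat("Switch output at V = -70 mV across blk =",
    paste(blks, collapse = ", "), ":\n ",
    paste(signif(at70, 4), collapse = ", "), "\n")
cat("Higher blockade latents reduce the switch output at hyperpolarised\n",
    "potentials: NMDA conductance needs more depolarisation to open.\n")
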