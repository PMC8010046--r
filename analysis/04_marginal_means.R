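#!/usr/bin/env Rscript
# Stage 4 -- condition means inside the detected clusters.
#
# Averages posterior-temporal activity over each significant cluster's
# timepoints, refits the full model on the per-trial averages, and
# reports estimated marginal means per condition with Tukey-adjusted
# pairwise contrasts.

suppressPackageStartupMessages(library(clustlmm))
seed <- 1L

e <- read_epochs("results/epochs/LPTL.h5")

analyses <- list(
  list(name = "adjective_syntactic", preset = "complexity",
       window = c(0.700, 1.100), family = "syntactic"),
  list(name = "noun_definiteness", preset = "noun_definiteness",
       window = c(0.100, 0.500), family = "noun_definiteness"))

for (an in analyses) {
  tr <- preset_trials(e$trials, an$preset)
  spec <- model_preset(an$preset)
  tc <- lrt_timecourse(e$epochs, tr, spec, an$window)
  cl <- find_clusters(tc, chi2_threshold(tc$df))
  if (!nrow(cl)) {
    cat(an$name, ": no suprathreshold cluster\n")
    next
  }
  cat(sprintf("\n== %s: cluster %.3f-%.3f s, mass %.1f ==\n",
              an$name, cl$start_s[1], cl$end_s[1], cl$mass[1]))
  sc <- cluster_average(e$epochs, cl, times = tc$times)
  em <- emm_and_contrasts(sc, tr, spec, family = an$family, adjust = "tukey")
  print(em)
  write.table(em$emmeans, file.path("results", paste0(an$name, "_emmeans.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(em$contrasts, file.path("results", paste0(an$name, "_contrasts.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
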