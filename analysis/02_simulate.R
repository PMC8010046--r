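#!/usr/bin/env Rscript
# Stage 2 -- synthetic single-trial source estimates.
#
# Simulates trials x timepoints activation for four left-hemisphere ROI
# labels. Ground-truth condition effects are injected only into the
# posterior temporal label: an indefinite-over-definite bump after noun
# onset (254-334 ms) and an indefinite-phrase bump after adjective onset
# (867-964 ms). All labels share participant random intercepts,
# Zipf-frequency and log-onset-time covariate slopes, and AR(1) noise.

suppressPackageStartupMessages(library(clustlmm))
dir.create("results/epochs", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

trials <- read.csv("results/trial_table.csv", stringsAsFactors = FALSE)
two_word <- preset_trials(trials, "complexity")

noise <- noise_spec(participant_intercept_sd = 0.5, residual_sd = 1, ar1 = 0.5,
                    slopes = c(noun_zipf = 0.1, adj_zipf = 0.1,
                               onset_time_s = -0.1))
effects_lptl <- list(
  effect_spec("noun_definiteness", c(indefinite = 1, definite = -1),
              window = c(0.254, 0.334), amplitude = 0.35),
  effect_spec("syntactic",
              c(indefinite_phrase = 1, sentence = -0.5, definite_phrase = -0.5),
              window = c(0.867, 0.964), amplitude = 0.35))

rois <- c("LPTL", "LATL", "LIFC", "LAG")
for (i in seq_along(rois)) {
  eff <- if (rois[i] == "LPTL") effects_lptl else list()
  ep <- simulate_roi_epochs(two_word, eff, noise, sfreq = 200,
                            seed = seed + i, roi_id = rois[i])
  path <- file.path("results/epochs", paste0(rois[i], ".h5"))
  write_epochs(ep, two_word, path)
  gt <- attr(ep, "ground_truth")
  jsonlite::write_json(list(roi = rois[i], intercepts = gt$intercepts,
                            n_effects = length(eff)),
                       file.path("results/epochs", paste0(rois[i], "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d trials x %d samples, %d injected effect(s)\n",
              rois[i], nrow(ep$data), ncol(ep$data), length(eff)))
}
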