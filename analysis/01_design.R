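#!/usr/bin/env Rscript
# Stage 1 -- experimental design.
#
# Builds the full factorial reading design: 36 stimulus sets x 20
# condition cells (12 noun-adjective cells crossing three syntactic
# structures with noun specificity and adjective form typicality, plus
# 8 single-word controls), distributed over 10 Latin-square blocks so
# that no word token repeats within a block. Derives the design-based
# syntactic transition probabilities that the information-theoretic
# stage consumes.

suppressPackageStartupMessages(library(clustlmm))
dir.create("results", showWarnings = FALSE)
seed <- 1L

trials <- generate_design(n_sets = 36, n_participants = 12, seed = seed)
write.csv(trials, "results/trial_table.csv", row.names = FALSE)
cat(sprintf("design: %d trials (%d per participant), %d blocks, %d sets\n",
            nrow(trials), nrow(trials) / length(unique(trials$participant_id)),
            length(unique(trials$block_id)), max(trials$set_id)))

tp <- design_transition_probabilities(trials, "noun_definiteness")
write.csv(tp, "results/structure_transitions.csv", row.names = FALSE)
cat("P(structure | noun definiteness):\n")
print(tp, digits = 4)

wt <- design_word_transitions(trials)
write.csv(wt, "results/word_transitions.csv", row.names = FALSE)
cat("\nword-level transition table written; note that an indefinite noun\n")
cat("fixes the continuation (indefinite adjective) while a definite noun\n")
cat("leaves a 50/50 split between sentence and definite phrase.\n")
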