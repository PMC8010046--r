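#!/usr/bin/env Rscript
# Stage 6 -- information-theoretic syntactic metrics.
#
# Computes entropy, entropy reduction, and surprisal along each
# two-word condition's token sequence, from the design-based transition
# probabilities (and, as an optional comparison, from a user-supplied
# corpus table; a synthetic stand-in ships with the package). These
# metrics predict response orderings that differ from a structural
# complexity account, and so serve to adjudicate between explanations.

suppressPackageStartupMessages(library(clustlmm))

wt <- read.csv("results/word_transitions.csv", stringsAsFactors = FALSE)
seqs <- list(indefinite_phrase = c("indefinite_noun", "indefinite_adjective"),
             sentence = c("definite_noun", "indefinite_adjective"),
             definite_phrase = c("definite_noun", "definite_adjective"))

tab <- do.call(rbind, lapply(names(seqs), function(cond) {
  rep <- sequence_metrics(wt, seqs[[cond]])
  data.frame(condition = cond, position = seq_len(nrow(rep)), rep)
}))
cat("design-based metrics (bits):\n")
print(tab, digits = 4)
write.table(tab, "results/infotheory_design.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nnoun-window orderings: indefinite nouns are rarer (surprisal",
    sprintf("%.3f vs %.3f bits)", tab$surprisal[tab$condition == "indefinite_phrase"][1],
            tab$surprisal[tab$condition == "sentence"][1]),
    "\nand collapse structure uncertainty entirely (entropy reduction",
    sprintf("%.3f vs %.3f bits).", tab$entropy_reduction[tab$condition == "indefinite_phrase"][1],
            tab$entropy_reduction[tab$condition == "sentence"][1]), "\n")

corpus_path <- system.file("extdata", "synthetic_corpus_transitions.csv",
                           package = "clustlmm")
if (nzchar(corpus_path)) {
  corpus <- read_transition_table(corpus_path)
  ctab <- do.call(rbind, lapply(names(seqs), function(cond) {
    rep <- sequence_metrics(corpus, seqs[[cond]])
    data.frame(condition = cond, position = seq_len(nrow(rep)), rep)
  }))
  cat("\nsynthetic stand-in corpus table (illustration only):\n")
  print(ctab, digits = 4)
  write.table(ctab, "results/infotheory_corpus_synthetic.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
}
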