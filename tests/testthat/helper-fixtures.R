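# Shared fixtures built in code at test time.

# Small fully-crossed design with z-scored covariates attached.
toy_trials <- function(n_participants = 6, trials_per_cell = 8,
                       factors = list(syntactic = c("indefinite_phrase", "sentence", "definite_phrase")),
                       seed = 11) {
  add_model_covariates(factorial_trials(n_participants, trials_per_cell,
                                        factors = factors, seed = seed))
}

toy_spec <- function() {
  model_spec(~ syntactic + noun_zipf_z + log_onset_z, voi = "syntactic")
}

# Gaussian OLS likelihood-ratio statistic (independent oracle for the
# zero-variance mixed model).
ols_lrt_oracle <- function(Xf, Xr, y) {
  n <- length(y)
  rss <- function(X) sum(lm.fit(X, y)$residuals^2)
  n * (log(rss(Xr)) - log(rss(Xf)))
}

.zscore_test <- function(x) (x - mean(x)) / sd(x)

# Brute-force Benjamini-Hochberg from the step-up definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  # step-up: adjusted value is the minimum over larger ranks, capped at 1
  adj[o] <- pmin(1, rev(cummin(rev(ranked))))
  adj
}
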