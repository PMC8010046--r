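test_that("model presets drop the documented parameter counts", {
  d <- generate_design(12, 2, seed = 1)
  expected <- c(complexity = 2, noun_definiteness = 1,
                block_by_definiteness = 3, category_by_definiteness = 3,
                semantic_composition = 11)
  for (nm in names(expected)) {
    tr <- preset_trials(d, nm)
    dm <- build_design_matrices(tr, model_preset(nm))
    expect_equal(dm$df_interest, unname(expected[nm]), info = nm)
    expect_equal(ncol(dm$X_full) - ncol(dm$X_reduced), unname(expected[nm]))
  }
})

test_that("empty variables of interest give identical models and zero LRT", {
  tr <- toy_trials(4, 4)
  spec <- model_spec(~ syntactic + noun_zipf_z, voi = character(0))
  dm <- build_design_matrices(tr, spec)
  expect_equal(dm$df_interest, 0)
  expect_equal(unname(dm$X_full), unname(dm$X_reduced), ignore_attr = TRUE)
  y <- rnorm(nrow(tr))
  expect_equal(fit_lrt_at_timepoint(y, dm)$chi2, 0, tolerance = 1e-8)
})

test_that("design-matrix validation names its failure modes", {
  tr <- toy_trials(4, 4)
  expect_error(build_design_matrices(tr, model_spec(~ missing_col, "missing_col")),
               "missing from trials")
  tr$dup <- tr$noun_zipf_z
  expect_error(build_design_matrices(tr, model_spec(~ noun_zipf_z + dup, "dup")),
               "aliased columns.*dup")
  tr$onelevel <- "x"
  expect_error(build_design_matrices(tr, model_spec(~ onelevel, "onelevel")),
               "fewer than 2 observed levels")
})

test_that("mixed-model LRT equals the OLS oracle when intercept variance is zero", {
  set.seed(21)
  tr <- toy_trials(8, 6)
  dm <- build_design_matrices(tr, toy_spec())
  for (rep in 1:5) {
    # centring within participant removes all between-group variance, so
    # the ML variance-ratio estimate sits at the zero boundary
    y <- 0.4 * (tr$syntactic == "sentence") + rnorm(nrow(tr))
    y <- y - ave(y, tr$participant_id)
    f <- fit_lrt_at_timepoint(y, dm)
    oracle <- ols_lrt_oracle(dm$X_full, dm$X_reduced, y)
    expect_true(f$converged)
    expect_equal(f$chi2, oracle, tolerance = 1e-4 * max(oracle, 1))
  }
  # constant response: both models saturate identically
  expect_equal(fit_lrt_at_timepoint(rep(2.5, nrow(tr)), dm)$chi2, 0)
  expect_error(fit_lrt_at_timepoint(c(1, NA)[rep(1:2, nrow(tr) / 2)], dm),
               "finite")
})

test_that("profiled ML log-likelihoods agree with lme4 under true random intercepts", {
  set.seed(22)
  tr <- toy_trials(10, 5)
  dm <- build_design_matrices(tr, toy_spec())
  pid <- factor(tr$participant_id)
  b <- rnorm(nlevels(pid), 0, 0.9)
  y <- 0.5 * (tr$syntactic == "definite_phrase") + b[as.integer(pid)] +
    rnorm(nrow(tr))
  f <- fit_lrt_at_timepoint(y, dm)
  dd <- tr
  dd$y <- y
  m1 <- lme4::lmer(y ~ syntactic + noun_zipf_z + log_onset_z + (1 | participant_id),
                   dd, REML = FALSE)
  m0 <- lme4::lmer(y ~ noun_zipf_z + log_onset_z + (1 | participant_id),
                   dd, REML = FALSE)
  expect_equal(f$loglik_full, as.numeric(logLik(m1)), tolerance = 1e-5)
  expect_equal(f$loglik_reduced, as.numeric(logLik(m0)), tolerance = 1e-5)
  expect_equal(f$chi2, as.numeric(2 * (logLik(m1) - logLik(m0))), tolerance = 1e-4)
})

test_that("chi2 is invariant to affine rescaling and monotone under nesting", {
  set.seed(23)
  tr <- toy_trials(6, 6)
  dm <- build_design_matrices(tr, toy_spec())
  y <- rnorm(nrow(tr)) + 0.3 * (tr$syntactic == "sentence")
  f1 <- fit_lrt_at_timepoint(y, dm)
  f2 <- fit_lrt_at_timepoint(5.7 * y - 3.1, dm)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-6 * max(1, f1$chi2))
  # adding any fixed term never decreases the ML log-likelihood
  spec_small <- model_spec(~ noun_zipf_z, voi = character(0))
  spec_big <- model_spec(~ noun_zipf_z + syntactic + log_onset_z, voi = character(0))
  lls <- fit_lrt_at_timepoint(y, build_design_matrices(tr, spec_small))$loglik_full
  llb <- fit_lrt_at_timepoint(y, build_design_matrices(tr, spec_big))$loglik_full
  expect_gte(llb, lls - 1e-6)
})

test_that("null chi2 timecourse has chi-square(df) moments and marginals", {
  tr <- toy_trials(6, 8, seed = 31)
  # 2000 serially-independent timepoints of pure noise (no condition effect)
  ep <- simulate_roi_epochs(tr, list(),
                            noise_spec(participant_intercept_sd = 0.5,
                                       residual_sd = 1, ar1 = 0, slopes = c()),
                            sfreq = 200, seed = 32, tmin = 0, tmax = 1999 / 200)
  tc <- lrt_timecourse(ep, tr, toy_spec())
  expect_equal(tc$df, 2)
  expect_equal(length(tc$chi2), 2000)
  # mean within 2 SE of df (Var chi2_2 = 4 => SE = 2/sqrt(2000))
  expect_lt(abs(mean(tc$chi2) - 2), 2 * 2 / sqrt(2000) + 0.05)
  ks <- suppressWarnings(ks.test(tc$chi2, pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("timecourse windows are closed intervals on the sample grid", {
  tr <- toy_trials(3, 2)
  ep <- simulate_roi_epochs(tr, list(), noise_spec(0.2, 1, 0, slopes = c()),
                            sfreq = 200, seed = 2)
  tc <- lrt_timecourse(ep, tr, toy_spec(), window = c(0.70, 1.10))
  expect_equal(length(tc$times), 81)
  expect_equal(tc$times[1], 0.70)
  expect_equal(tc$times[81], 1.10)
  expect_error(lrt_timecourse(ep, tr, toy_spec(), window = c(2, 3)),
               "empty analysis window")
})

test_that("a noiseless injected effect is suprathreshold exactly on its support", {
  tr <- toy_trials(6, 4, seed = 41)
  eff <- effect_spec("syntactic", c(indefinite_phrase = 1, sentence = -1),
                     window = c(0.70, 0.90), amplitude = 1)
  ep <- simulate_roi_epochs(tr, list(eff),
                            noise_spec(0.5, 0, 0, slopes = c()),
                            sfreq = 200, seed = 42)
  tc <- lrt_timecourse(ep, tr, toy_spec(), window = c(0.6, 1.1))
  thr <- chi2_threshold(tc$df)
  insupport <- tc$times >= 0.70 & tc$times <= 0.90
  expect_true(all(tc$chi2[insupport] > thr))
  expect_true(all(tc$chi2[!insupport] < thr))
})
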