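test_that("cluster averaging reduces to the obvious cases", {
  tr <- toy_trials(2, 2)
  n <- nrow(tr)
  v <- seq_len(n) / 10
  ep <- epoch_set(matrix(v, n, 21), (0:20) / 100, 100, "r")
  cl <- data.frame(start_idx = 4L, end_idx = 9L)
  expect_equal(cluster_average(ep, cl), v)        # constant in time
  one <- data.frame(start_idx = 7L, end_idx = 8L)
  ep2 <- epoch_set(matrix(rnorm(n * 21), n, 21), (0:20) / 100, 100, "r")
  expect_equal(cluster_average(ep2, one), ep2$data[, 7])
  expect_error(cluster_average(ep, cl[0, ]), "empty cluster")
})

test_that("EMMs recover injected cell means in a balanced noiseless design", {
  tr <- toy_trials(6, 8, seed = 101)
  eff <- effect_spec("syntactic",
                     c(indefinite_phrase = 0, sentence = 1, definite_phrase = 1),
                     window = c(0.2, 0.4), amplitude = 1)
  ep <- simulate_roi_epochs(tr, list(eff), noise_spec(0, 0, 0, slopes = c()),
                            sfreq = 100, seed = 102)
  cl <- find_clusters(list(chi2 = rep(10, length(ep$times)), times = ep$times), 1)
  cl <- data.frame(start_idx = which.min(abs(ep$times - 0.2)),
                   end_idx = which.min(abs(ep$times - 0.4)) + 1L)
  sc <- cluster_average(ep, cl)
  em <- suppressWarnings(
    emm_and_contrasts(sc, tr, toy_spec(), family = "syntactic", adjust = "tukey"))
  emm <- setNames(em$emmeans$emm, em$emmeans$cell)
  expect_equal(emm[["indefinite_phrase"]], 0, tolerance = 1e-6)
  expect_equal(emm[["sentence"]], 1, tolerance = 1e-6)
  expect_equal(emm[["definite_phrase"]], 1, tolerance = 1e-6)
  # EMMs equal raw cell means in the balanced design
  raw <- tapply(sc, tr$syntactic, mean)
  expect_equal(emm[names(raw)], unlist(as.list(raw)), tolerance = 1e-6)
  # the equal-vs-equal contrast estimate is zero
  ctr <- em$contrasts
  dsp <- ctr$estimate[ctr$pair == "definite_phrase - sentence"]
  expect_equal(dsp, 0, tolerance = 1e-6)
})

test_that("adjustment methods relate as their definitions require", {
  set.seed(103)
  tr <- toy_trials(6, 6, seed = 1103)
  sc <- rnorm(nrow(tr)) + 0.4 * (tr$syntactic == "sentence")
  none <- suppressWarnings(emm_and_contrasts(sc, tr, toy_spec(), "syntactic",
                                             adjust = "none"))
  bonf <- suppressWarnings(emm_and_contrasts(sc, tr, toy_spec(), "syntactic",
                                             adjust = "bonferroni"))
  tuk <- suppressWarnings(emm_and_contrasts(sc, tr, toy_spec(), "syntactic",
                                            adjust = "tukey"))
  expect_equal(bonf$contrasts$p_adjusted,
               pmin(1, 3 * none$contrasts$p), tolerance = 1e-12)
  expect_true(all(tuk$contrasts$p_adjusted >= none$contrasts$p - 1e-12))
  expect_true(all(none$contrasts$p_adjusted == none$contrasts$p))
  # planned-subset family: adjustment scales by the number requested
  two <- suppressWarnings(emm_and_contrasts(
    sc, tr, toy_spec(), "syntactic", adjust = "tukey",
    contrasts = list(c("sentence", "indefinite_phrase"),
                     c("definite_phrase", "indefinite_phrase"))))
  expect_equal(nrow(two$contrasts), 2)
  expect_equal(two$contrasts$p_adjusted, pmin(1, 2 * two$contrasts$p))
})

test_that("contrasts are antisymmetric and EMMs are coding-invariant", {
  set.seed(104)
  tr <- toy_trials(5, 6, seed = 1104)
  sc <- rnorm(nrow(tr)) + 0.5 * (tr$syntactic == "definite_phrase")
  em <- suppressWarnings(emm_and_contrasts(
    sc, tr, toy_spec(), "syntactic",
    contrasts = list(c("sentence", "definite_phrase"))))
  rev <- suppressWarnings(emm_and_contrasts(
    sc, tr, toy_spec(), "syntactic",
    contrasts = list(c("definite_phrase", "sentence"))))
  expect_equal(em$contrasts$estimate, -rev$contrasts$estimate, tolerance = 1e-10)
  expect_equal(em$contrasts$se, rev$contrasts$se, tolerance = 1e-10)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  em_sum <- suppressWarnings(emm_and_contrasts(sc, tr, toy_spec(), "syntactic"))
  options(old)
  em_trt <- suppressWarnings(emm_and_contrasts(sc, tr, toy_spec(), "syntactic"))
  expect_equal(em_sum$emmeans$emm, em_trt$emmeans$emm, tolerance = 1e-6)
})

test_that("family levels without trials are rejected", {
  tr <- toy_trials(3, 3)
  sc <- rnorm(nrow(tr))
  expect_error(emm_and_contrasts(sc, tr, toy_spec(), family = "nope"),
               "family factors")
})
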