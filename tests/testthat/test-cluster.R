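test_that("chi-square thresholds match the distribution quantiles", {
  expect_equal(chi2_threshold(1), 3.8415, tolerance = 1e-3)
  expect_equal(chi2_threshold(2), 5.9915, tolerance = 1e-3)
  expect_lt(chi2_threshold(3, alpha = 0.999), 0.03)
  expect_error(chi2_threshold(0), "invalid-argument")
})

test_that("cluster finding matches hand enumeration of runs", {
  tc <- list(chi2 = c(1.0, 7.0, 8.0, 2.0, 6.5), times = (0:4) / 10)
  cl <- find_clusters(tc, 5.9915)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$mass, c(15.0, 6.5))
  expect_equal(cl$start_idx, c(2L, 5L))
  expect_equal(cl$end_idx, c(4L, 6L))   # half-open: members start..end-1
  expect_equal(cl$start_s, c(0.1, 0.4))
  expect_equal(cl$end_s, c(0.2, 0.4))
  expect_equal(cl$n_members, c(2L, 1L))

  expect_equal(nrow(find_clusters(list(chi2 = c(1, 2, 3), times = 1:3), 5)), 0)
  all_up <- find_clusters(list(chi2 = c(7, 8, 9), times = 1:3), 5)
  expect_equal(nrow(all_up), 1)
  expect_equal(all_up$mass, 24)
  # strict inequality at the threshold ("exceeding")
  expect_equal(nrow(find_clusters(list(chi2 = c(5, 5, 5), times = 1:3), 5)), 0)
})

test_that("FDR correction matches the brute-force BH definition", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.5), 0.5)
  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- fdr_correct(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "invalid-argument")
})

test_that("a strong injected effect is never beaten by label permutations", {
  tr <- toy_trials(6, 6, seed = 61)
  eff <- effect_spec("syntactic", c(indefinite_phrase = 1, sentence = -0.5,
                                    definite_phrase = -0.5),
                     window = c(0.2, 0.4), amplitude = 5)
  ep <- simulate_roi_epochs(tr, list(eff), noise_spec(0.5, 1, 0.3, slopes = c()),
                            sfreq = 100, seed = 62, tmin = 0, tmax = 0.6)
  res <- permutation_test(ep, tr, toy_spec(), window = c(0.1, 0.5),
                          n_perm = 200, seed = 63)
  expect_equal(res$p_raw, 0)     # literal strictly-greater proportion rule
  expect_equal(length(res$null_masses), 200)
  smooth <- permutation_test(ep, tr, toy_spec(), window = c(0.1, 0.5),
                             n_perm = 200, seed = 63, p_smoothing = TRUE)
  expect_equal(smooth$p_raw, 1 / 201)
  # overlap with the true window
  expect_lte(res$clusters$start_s[1], 0.4)
  expect_gte(res$clusters$end_s[1], 0.2)
  # determinism under the master seed
  res2 <- permutation_test(ep, tr, toy_spec(), window = c(0.1, 0.5),
                           n_perm = 200, seed = 63)
  expect_identical(res$null_masses, res2$null_masses)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration on a toy design", {
  # 2 participants x 4 trials (2 per condition); all within-participant
  # relabelings are enumerable: C(4,2)^2 = 36 distinct assignments.
  tr <- data.frame(participant_id = rep(c("P1", "P2"), each = 4),
                   cond = rep(c("a", "a", "b", "b"), 2))
  set.seed(71)
  y <- matrix(rnorm(8 * 3), 8, 3)
  y[tr$cond == "b", ] <- y[tr$cond == "b", ] + 1.0
  ep <- epoch_set(y, (0:2) / 100, 100, "toy")
  spec <- model_spec(~ cond, voi = "cond")
  thr <- chi2_threshold(1)

  biggest_mass <- function(labels) {
    d <- tr
    d$cond <- labels
    tc <- lrt_timecourse(ep, d, spec)
    cl <- find_clusters(tc, thr)
    if (nrow(cl)) cl$mass[1] else 0
  }
  observed <- biggest_mass(tr$cond)
  combs <- combn(4, 2, simplify = FALSE)
  exhaustive <- unlist(lapply(combs, function(i1) lapply(combs, function(i2) {
    lab <- character(8)
    lab[1:4] <- "b"; lab[(1:4)[i1]] <- "a"
    lab[5:8] <- "b"; lab[4 + i2] <- "a"
    biggest_mass(lab)
  })))
  p_exact <- mean(exhaustive > observed)

  res <- permutation_test(ep, tr, spec, n_perm = 400, seed = 72)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(res$p_raw - p_exact), 2 * se + 1e-9)
  # the Monte-Carlo null can only take values from the exhaustive set
  expect_true(all(res$null_masses %in% c(0, exhaustive)))
})

test_that("observed cluster masses are invariant to trial order", {
  tr <- toy_trials(5, 5, seed = 81)
  eff <- effect_spec("syntactic", c(sentence = 1), window = c(0.1, 0.3),
                     amplitude = 1.2)
  ep <- simulate_roi_epochs(tr, list(eff), noise_spec(0.4, 1, 0, slopes = c()),
                            sfreq = 100, seed = 82, tmin = 0, tmax = 0.5)
  spec <- toy_spec()
  tc1 <- lrt_timecourse(ep, tr, spec)
  perm <- sample(nrow(tr))
  ep2 <- epoch_set(ep$data[perm, ], ep$times, ep$sfreq, ep$roi_id)
  tc2 <- lrt_timecourse(ep2, tr[perm, ], spec)
  thr <- chi2_threshold(tc1$df)
  expect_equal(find_clusters(tc1, thr)$mass, find_clusters(tc2, thr)$mass,
               tolerance = 1e-8)
})

test_that("degenerate permutation-test inputs are rejected or flagged", {
  tr <- toy_trials(3, 3, seed = 91)
  ep <- simulate_roi_epochs(tr, list(), noise_spec(0.2, 1, 0, slopes = c()),
                            sfreq = 100, seed = 92, tmin = 0, tmax = 0.1)
  expect_error(permutation_test(ep, tr, toy_spec(), n_perm = 0), "n_perm")
  spec0 <- model_spec(~ syntactic, voi = character(0))
  expect_error(permutation_test(ep, tr, spec0, n_perm = 10),
               "variables_of_interest")
  # a flat timecourse with no observed cluster reports p = 1 with a flag
  ep0 <- epoch_set(matrix(rep(c(0, 1e-8), length.out = nrow(tr) * 11),
                          nrow(tr), 11),
                   (0:10) / 100, 100, "flat")
  res <- permutation_test(ep0, tr, toy_spec(), n_perm = 10, seed = 93)
  expect_true(res$no_cluster)
  expect_equal(res$p_raw, 1.0)
})
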