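osc_trials <- function(n_subj, n_per, conds = c("a", "b"), seed = 1) {
  factorial_trials(n_subj, n_per, factors = list(cond = conds), seed = seed)
}

test_that("the Morlet transform is tuned, scaled and edge-flagged as documented", {
  tr <- osc_trials(1, 2, conds = "a")
  ep <- simulate_oscillatory_trials(
    tr, list(list(freq = 20, window = c(-0.1, 1.2), amplitude = 1,
                  phase_locked = TRUE)), noise_sd = 0, sfreq = 200, seed = 1)
  pw <- morlet_tfr(ep, freqs = 8:32)
  freqs <- attr(pw, "freqs")
  interior <- ep$times > 0.2 & ep$times < 1.0
  profile <- apply(pw[1, interior, ], 2, mean)
  expect_equal(freqs[which.max(profile)], 20)
  at20 <- pw[1, interior, freqs == 20]
  # analytic-signal convention: unit sinusoid -> power 1/2, stationary
  expect_equal(mean(at20), 0.5, tolerance = 0.01)
  expect_lt((max(at20) - min(at20)) / mean(at20), 0.05)
  edge <- attr(pw, "edge")
  expect_true(edge[1, 1] && edge[length(ep$times), 1])
  expect_false(edge[which.min(abs(ep$times - 0.6)), freqs == 20])

  z <- morlet_tfr(epoch_set(matrix(0, 2, 261), ep$times, 200), freqs = 8:32)
  expect_true(all(z == 0))
  expect_error(morlet_tfr(ep, freqs = c(10, 100)), "Nyquist")
})

test_that("baseline log-ratio and decimation follow their definitions", {
  tr <- osc_trials(2, 4, conds = "a")
  # stationary tone: log-ratio ~ 0 everywhere in the interior. The epoch
  # is padded before the baseline so that the baseline itself is outside
  # the wavelet edge region (edge attenuation is flagged, not corrected).
  ep <- simulate_oscillatory_trials(
    tr, list(list(freq = 15, window = c(-0.5, 1.2), amplitude = 1,
                  phase_locked = TRUE)), noise_sd = 0, sfreq = 200, seed = 2,
    tmin = -0.5)
  pw <- morlet_tfr(ep, freqs = 10:20)
  st <- baseline_and_aggregate(pw, tr, condition = "cond", decim = 1)
  tt <- attr(st, "times")
  interior <- tt > 0.15 & tt < 1.0
  expect_lt(max(abs(st$a[, interior, attr(st, "freqs") == 15])), 0.05)

  # power doubling after onset: log-ratio ~ log10(2) in the band
  # amplitude steps by sqrt(2) at 0.4 s (three wavelet sds past the
  # baseline), doubling power: log-ratio log10(2) beyond the transition
  amp2 <- simulate_oscillatory_trials(
    tr, list(list(freq = 15, window = c(-0.5, 0.4), amplitude = 1, phase_locked = TRUE),
             list(freq = 15, window = c(0.4 + 1 / 200, 1.2), amplitude = sqrt(2),
                  phase_locked = TRUE)),
    noise_sd = 0, sfreq = 200, seed = 3, tmin = -0.5)
  pw2 <- morlet_tfr(amp2, freqs = 15)
  st2 <- baseline_and_aggregate(pw2, tr, condition = "cond", decim = 1)
  tt2 <- attr(st2, "times")
  mid <- tt2 > 0.6 & tt2 < 1.0
  expect_equal(mean(st2$a[, mid, 1]), log10(2), tolerance = 0.05)

  # decimation subsamples exactly
  st5 <- baseline_and_aggregate(pw, tr, condition = "cond", decim = 5)
  keep <- seq(1, length(tt), by = 5)
  expect_equal(st5$a, st$a[, keep, , drop = FALSE])
  expect_equal(attr(st5, "times"), tt[keep])
  expect_error(baseline_and_aggregate(pw, tr, condition = "cond",
                                      baseline = c(5, 6)), "baseline")
})

test_that("log-ratio power is invariant to global amplitude scaling", {
  tr <- osc_trials(2, 3, conds = "a")
  ep <- simulate_oscillatory_trials(
    tr, list(list(freq = 12, window = c(0.2, 0.8), amplitude = 1,
                  phase_locked = FALSE)), noise_sd = 0.5, sfreq = 200, seed = 4)
  pw1 <- morlet_tfr(ep, freqs = 8:16)
  ep2 <- epoch_set(ep$data * 7.3, ep$times, ep$sfreq)
  pw2 <- morlet_tfr(ep2, freqs = 8:16)
  s1 <- baseline_and_aggregate(pw1, tr, condition = "cond")
  s2 <- baseline_and_aggregate(pw2, tr, condition = "cond")
  expect_equal(s1$a, s2$a, tolerance = 1e-9)
})

test_that("identical stacks produce no clusters; tiny designs enumerate exactly", {
  arr <- array(rnorm(2 * 10 * 5), c(2, 10, 5))
  res <- tfr_cluster_test(arr, arr, n_perm = 50, seed = 5)
  expect_equal(nrow(res$clusters), 0)
  expect_equal(res$p_raw, 1.0)

  # two subjects: the sign-flip null has exactly 4 assignments
  a <- array(rnorm(2 * 8 * 4, mean = 1), c(2, 8, 4))
  b <- array(rnorm(2 * 8 * 4), c(2, 8, 4))
  res2 <- tfr_cluster_test(a, b, n_perm = 400, seed = 6)
  d <- a - b
  ns <- 2
  exhaustive <- sapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(s) {
    m <- matrix(d, nrow = 2) * s
    mu <- colMeans(m)
    sdv <- apply(m, 2, sd)
    tm <- matrix(mu / (sdv / sqrt(2)), 8, 4)
    clustlmm:::.biggest_mass(tm, qt(0.95, 1))
  })
  expect_true(all(round(res2$null_masses, 8) %in% round(exhaustive, 8)))
  expect_setequal(round(unique(res2$null_masses), 8), round(unique(exhaustive), 8))
  expect_error(tfr_cluster_test(a[1, , , drop = FALSE], b[1, , , drop = FALSE]),
               ">= 2 subjects")
})

test_that("spectro-temporal clustering uses 4-connectivity", {
  tmap <- matrix(0, 5, 5)
  tmap[1, 1] <- 10          # isolated corner
  tmap[3, 3] <- 8; tmap[3, 4] <- 8; tmap[4, 4] <- 8  # L-shaped cluster
  tmap[5, 1] <- 7           # diagonal neighbour of nothing above threshold
  lab <- clustlmm:::.label_components(tmap > 5)
  expect_equal(max(lab), 3)
  expect_equal(lab[3, 3], lab[3, 4])
  expect_equal(lab[3, 4], lab[4, 4])
  expect_true(lab[1, 1] != lab[3, 3] && lab[5, 1] != lab[1, 1])
  expect_equal(clustlmm:::.biggest_mass(tmap, 5), 24)
})

test_that("evoked TFR cancels induced power but preserves phase-locked power", {
  tr <- osc_trials(6, 50, conds = "a", seed = 7)
  ind <- simulate_oscillatory_trials(
    tr, list(list(freq = 20, window = c(0.3, 0.9), amplitude = 1,
                  phase_locked = FALSE)), noise_sd = 0.1, sfreq = 200, seed = 8)
  band <- 18:22
  inwin <- function(t) t >= 0.4 & t <= 0.8
  single_pw <- morlet_tfr(ind, band)
  single_bp <- mean(single_pw[, inwin(ind$times), ])
  subj <- unique(tr$participant_id)
  avg <- t(sapply(subj, function(s) colMeans(ind$data[tr$participant_id == s, ])))
  ev_pw <- morlet_tfr(epoch_set(avg, ind$times, 200), band)
  ev_bp <- mean(ev_pw[, inwin(ind$times), ])
  expect_lt(ev_bp, 0.2 * single_bp)   # >= 80% attenuation

  pl <- simulate_oscillatory_trials(
    tr, list(list(freq = 20, window = c(0.3, 0.9), amplitude = 1,
                  phase_locked = TRUE)), noise_sd = 0.1, sfreq = 200, seed = 9)
  single_pl <- mean(morlet_tfr(pl, band)[, inwin(pl$times), ])
  avg_pl <- t(sapply(subj, function(s) colMeans(pl$data[tr$participant_id == s, ])))
  ev_pl <- mean(morlet_tfr(epoch_set(avg_pl, pl$times, 200), band)[, inwin(pl$times), ])
  expect_lt(abs(ev_pl - single_pl) / single_pl, 0.1)

  # with one trial per cell the evoked stack equals the single-trial stack
  tr1 <- osc_trials(3, 1, conds = c("a", "b"), seed = 10)
  ep1 <- simulate_oscillatory_trials(
    tr1, list(list(freq = 15, window = c(0.2, 0.8), amplitude = 1,
                   phase_locked = FALSE)), noise_sd = 0.3, sfreq = 200, seed = 11)
  pw1 <- morlet_tfr(ep1, 10:20)
  st1 <- baseline_and_aggregate(pw1, tr1, condition = "cond", decim = 5)
  ev1 <- evoked_tfr(ep1, tr1, condition = "cond", freqs = 10:20, decim = 5)
  expect_equal(ev1$a, st1$a, tolerance = 1e-12)
  expect_equal(ev1$b, st1$b, tolerance = 1e-12)
})
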