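#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet transform (a fixed number of cycles at every
#' frequency) of each epoch, returning power as the squared magnitude.
#' The wavelet is scaled so that a pure sinusoid of amplitude A yields
#' power A^2/2 at its frequency (analytic-signal convention). Samples
#' closer to an epoch edge than the truncated wavelet half-support
#' (3 standard deviations of the Gaussian envelope) are flagged in the
#' `edge` attribute (time x frequency logical matrix).
#'
#' @param epochs An [epoch_set()].
#' @param freqs Frequencies in Hz (default 8-32 Hz in 1 Hz steps); all
#'   must lie below Nyquist.
#' @param n_cycles Wavelet cycles (default 4, all frequencies).
#' @return A 3-d array `trials x times x freqs` of power with attributes
#'   `times`, `freqs`, `sfreq`, `edge`.
#' @export
morlet_tfr <- function(epochs, freqs = 8:32, n_cycles = 4) {
  sfreq <- epochs$sfreq
  if (any(freqs >= sfreq / 2))
    stop("invalid-argument: frequencies must be below Nyquist (sfreq/2)")
  x <- epochs$data
  n_trials <- nrow(x)
  tp <- ncol(x)
  nf <- length(freqs)

  # FFT-based convolution, one frequency at a time, all trials at once.
  sigmas <- n_cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigmas * sfreq)
  nfft <- stats::nextn(tp + 2L * max(half) + 1L, 2)
  Xf <- stats::mvfft(rbind(t(x), matrix(0, nfft - tp, n_trials)))

  power <- array(NA_real_, dim = c(n_trials, tp, nf))
  edge <- matrix(FALSE, tp, nf)
  for (k in seq_len(nf)) {
    h <- half[k]
    tt <- (-h:h) / sfreq
    env <- exp(-tt^2 / (2 * sigmas[k]^2))
    w <- env * exp(1i * 2 * pi * freqs[k] * tt)
    w <- w * sqrt(2) / sum(env)          # unit sinusoid -> |cwt| = 1/sqrt(2)
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(Xf * wf, inverse = TRUE) / nfft
    # wavelet is centred at sample h+1 of its buffer
    rows <- (h + 1L):(h + tp)
    power[, , k] <- t(Mod(conv[rows, , drop = FALSE])^2)
    if (h > 0) edge[c(seq_len(min(h, tp)), seq.int(max(1L, tp - h + 1L), tp)), k] <- TRUE
  }
  attr(power, "times") <- epochs$times
  attr(power, "freqs") <- as.numeric(freqs)
  attr(power, "sfreq") <- sfreq
  attr(power, "edge") <- edge
  power
}

#' Baseline log-ratio and subject-level aggregation
#'
#' Per epoch and frequency, power is expressed as `log10(power / mean
#' baseline power)`; the time axis is then decimated (every `decim`-th
#' sample, subsampling after decomposition) and trials are averaged per
#' subject and condition.
#'
#' @param power Array from [morlet_tfr()].
#' @param trials Trial table aligned with the power array's first axis.
#' @param condition Factor column defining the conditions.
#' @param baseline Baseline window in seconds (default -100-0 ms).
#' @param decim Time decimation factor (>= 1).
#' @param participant Column naming the subject.
#' @return A `tfr_stack`: named list (one entry per condition level) of
#'   subject x time x frequency arrays, with attributes `times`, `freqs`,
#'   `subjects`, and `baseline_edge_warning` if the baseline lies wholly
#'   inside the wavelet edge region.
#' @export
baseline_and_aggregate <- function(power, trials, condition = "syntactic",
                                   baseline = c(-0.1, 0), decim = 5L,
                                   participant = "participant_id") {
  times <- attr(power, "times")
  freqs <- attr(power, "freqs")
  if (decim < 1L) stop("invalid-argument: decim must be >= 1")
  bidx <- which(times >= baseline[1L] - 1e-9 & times <= baseline[2L] + 1e-9)
  if (!length(bidx)) stop("invalid-argument: baseline outside epoch")
  edge <- attr(power, "edge")
  warn_edge <- !is.null(edge) && all(edge[bidx, ])

  # log-ratio per epoch and frequency
  base_mean <- apply(power[, bidx, , drop = FALSE], c(1, 3), mean)
  lr <- log10(sweep(power, c(1, 3), base_mean, "/"))

  tidx <- seq(1L, length(times), by = decim)
  lr <- lr[, tidx, , drop = FALSE]

  subj <- factor(trials[[participant]])
  cond <- factor(trials[[condition]])
  subjects <- levels(subj)
  out <- lapply(levels(cond), function(cl) {
    arr <- array(NA_real_, dim = c(length(subjects), length(tidx), length(freqs)))
    for (i in seq_along(subjects)) {
      rows <- which(subj == subjects[i] & cond == cl)
      if (!length(rows)) stop("invalid-argument: empty subject x condition cell")
      arr[i, , ] <- apply(lr[rows, , , drop = FALSE], c(2, 3), mean)
    }
    arr
  })
  names(out) <- levels(cond)
  structure(out, times = times[tidx], freqs = freqs, subjects = subjects,
            baseline_edge_warning = warn_edge, class = "tfr_stack")
}

# 4-connected components of a logical time x frequency mask; returns an
# integer label matrix (0 = background).
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cl > 1L) p - nr, if (cl < nc) p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

.biggest_mass <- function(tmap, thr) {
  mask <- tmap > thr
  if (!any(mask)) return(0)
  lab <- .label_components(mask)
  max(vapply(seq_len(max(lab)), function(k) sum(tmap[lab == k]), 0))
}

#' Spectro-temporal cluster permutation test (paired, one-tailed)
#'
#' Pointwise paired t statistics on the subject-level difference maps
#' `a - b`, thresholded at the `1 - alpha` quantile of the t distribution
#' with `n_subjects - 1` degrees of freedom; suprathreshold points are
#' clustered with 4-connectivity and a cluster's mass is the sum of its
#' t values. The null exchanges condition labels within subject (random
#' sign flips of the difference maps); the p-value is the proportion of
#' permutation biggest-cluster masses strictly greater than the observed
#' biggest mass.
#'
#' @param stack_a,stack_b Subject x time x frequency arrays sharing axes
#'   (entries of a `tfr_stack`).
#' @param n_perm Number of permutations.
#' @param alpha Tail probability of the cluster-forming threshold.
#' @param seed Integer seed.
#' @param times,freqs Optional axis vectors (taken from `stack_a`
#'   attributes if present).
#' @return List: `tmap`, `threshold`, `clusters` data frame
#'   (`t_start_s`, `t_end_s`, `f_lo_hz`, `f_hi_hz`, `mass`, `n_members`,
#'   `p_raw`), `null_masses`, `labels` matrix.
#' @export
tfr_cluster_test <- function(stack_a, stack_b, n_perm = 1000L, alpha = 0.05,
                             seed = 1L, times = NULL, freqs = NULL) {
  if (!identical(dim(stack_a), dim(stack_b)))
    stop("invalid-argument: stacks must share axes")
  ns <- dim(stack_a)[1L]
  if (ns < 2L) stop("invalid-argument: need >= 2 subjects")
  if (is.null(times)) times <- attr(stack_a, "times")
  if (is.null(freqs)) freqs <- attr(stack_a, "freqs")
  d <- stack_a - stack_b
  dmat <- matrix(d, nrow = ns)        # subjects x (time*freq)
  tmap_vec <- function(m) {
    mu <- colMeans(m)
    s <- sqrt(pmax(colSums(m^2) - ns * mu^2, 0) / (ns - 1))
    tv <- mu / (s / sqrt(ns))
    tv[is.nan(tv)] <- 0        # 0/0: no variance, no difference
    tv
  }
  nt <- dim(d)[2L]; nf <- dim(d)[3L]
  tmap <- matrix(tmap_vec(dmat), nt, nf)
  thr <- stats::qt(1 - alpha, df = ns - 1)

  mask <- tmap > thr
  lab <- .label_components(mask)
  ncl <- max(lab)
  clusters <- if (ncl == 0L) {
    data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
               f_lo_hz = numeric(0), f_hi_hz = numeric(0),
               mass = numeric(0), n_members = integer(0))
  } else {
    do.call(rbind, lapply(seq_len(ncl), function(k) {
      pts <- which(lab == k, arr.ind = TRUE)
      data.frame(t_start_s = if (is.null(times)) min(pts[, 1L]) else times[min(pts[, 1L])],
                 t_end_s = if (is.null(times)) max(pts[, 1L]) else times[max(pts[, 1L])],
                 f_lo_hz = if (is.null(freqs)) min(pts[, 2L]) else freqs[min(pts[, 2L])],
                 f_hi_hz = if (is.null(freqs)) max(pts[, 2L]) else freqs[max(pts[, 2L])],
                 mass = sum(tmap[lab == k]), n_members = nrow(pts))
    }))
  }
  clusters <- clusters[order(-clusters$mass), ]
  rownames(clusters) <- NULL
  observed <- if (nrow(clusters)) clusters$mass[1L] else 0

  rng <- .seeded_rng(seed)
  null_masses <- rng(function() vapply(seq_len(n_perm), function(b) {
    signs <- sample(c(-1, 1), ns, replace = TRUE)
    .biggest_mass(matrix(tmap_vec(dmat * signs), nt, nf), thr)
  }, 0))
  p_raw <- if (nrow(clusters)) mean(null_masses > observed) else 1.0
  if (nrow(clusters)) clusters$p_raw <- c(p_raw, vapply(
    seq_len(nrow(clusters))[-1], function(i) mean(null_masses > clusters$mass[i]), 0))
  list(tmap = tmap, threshold = thr, clusters = clusters,
       null_masses = null_masses, labels = lab, p_raw = p_raw,
       times = times, freqs = freqs)
}

#' Evoked-response time-frequency stack
#'
#' Averages trials in the time domain per subject and condition first
#' (cancelling non-phase-locked components), then applies the Morlet
#' decomposition, baseline log-ratio, and aggregation. Serves as the
#' control that genuine induced oscillations do not survive.
#'
#' @inheritParams baseline_and_aggregate
#' @param epochs An [epoch_set()].
#' @param freqs,n_cycles Passed to [morlet_tfr()].
#' @return A `tfr_stack` (one "trial" per subject x condition before
#'   aggregation).
#' @export
evoked_tfr <- function(epochs, trials, condition = "syntactic",
                       freqs = 8:32, n_cycles = 4, baseline = c(-0.1, 0),
                       decim = 5L, participant = "participant_id") {
  subj <- factor(trials[[participant]])
  cond <- factor(trials[[condition]])
  cells <- expand.grid(s = levels(subj), c = levels(cond),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  avg <- matrix(NA_real_, nrow(cells), ncol(epochs$data))
  for (i in seq_len(nrow(cells))) {
    rows <- which(subj == cells$s[i] & cond == cells$c[i])
    if (!length(rows)) stop("invalid-argument: empty subject x condition cell")
    avg[i, ] <- colMeans(epochs$data[rows, , drop = FALSE])
  }
  ep <- epoch_set(avg, epochs$times, epochs$sfreq, paste0(epochs$roi_id, "_evoked"))
  pw <- morlet_tfr(ep, freqs, n_cycles)
  meta <- data.frame(participant_id = cells$s, cond = cells$c,
                     stringsAsFactors = FALSE)
  names(meta)[1L] <- participant
  baseline_and_aggregate(pw, meta, condition = "cond", baseline = baseline,
                         decim = decim, participant = participant)
}
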