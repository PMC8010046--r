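#' Epoch container for single-trial ROI timecourses
#'
#' Trials x timepoints matrix of signed source activation (dSPM-like
#' arbitrary units) on a uniform time grid.
#'
#' @param data Numeric matrix, trials x timepoints; no NAs.
#' @param times Strictly increasing, uniformly spaced time vector
#'   (seconds).
#' @param sfreq Sampling frequency in Hz; must match `diff(times)`.
#' @param roi_id Region label.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, roi_id = "ROI") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("invalid-argument: epoch data contains NAs")
  if (ncol(data) != length(times))
    stop("invalid-argument: ncol(data) must equal length(times)")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - 1 / sfreq)) > 1e-9)
      stop("invalid-argument: times must be uniform with spacing 1/sfreq")
  }
  structure(list(data = data, times = as.numeric(times),
                 sfreq = as.numeric(sfreq), roi_id = as.character(roi_id)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> roi=%s  %d trials x %d samples  [%.3f, %.3f] s @ %g Hz\n",
              x$roi_id, nrow(x$data), ncol(x$data),
              x$times[1L], x$times[length(x$times)], x$sfreq))
  invisible(x)
}

.epoch_times <- function(sfreq, tmin = -0.1, tmax = 1.2) {
  n <- round((tmax - tmin) * sfreq) + 1L
  tmin + (seq_len(n) - 1L) / sfreq
}

#' Condition-effect specification for the simulator
#'
#' Encodes a ground-truth activation bump tied to a factor: inside the
#' time window, a trial at level `l` of `factor` receives
#' `amplitude * weights[l]` times the temporal kernel.
#'
#' @param factor Factor column name in the trial table.
#' @param weights Named numeric vector of contrast weights per level;
#'   unnamed levels get weight 0.
#' @param window Length-2 numeric, effect window in seconds.
#' @param kernel `"boxcar"` or `"gaussian"` (centred on the window, sd
#'   `sigma`).
#' @param amplitude Effect amplitude (a.u.).
#' @param sigma Gaussian kernel sd in seconds (used if `kernel="gaussian"`).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(factor, weights, window, kernel = c("boxcar", "gaussian"),
                        amplitude = 1, sigma = 0.02) {
  kernel <- match.arg(kernel)
  if (length(window) != 2L || window[2L] < window[1L])
    stop("invalid-argument: window must be [start_s, end_s]")
  if (!all(is.finite(weights))) stop("invalid-argument: weights must be finite")
  structure(list(factor = factor, weights = weights, window = as.numeric(window),
                 kernel = kernel, amplitude = amplitude, sigma = sigma),
            class = "effect_spec")
}

#' Noise specification for the simulator
#'
#' @param participant_intercept_sd SD of the Gaussian participant random
#'   intercept (a.u.).
#' @param residual_sd Marginal SD of the AR(1) residual noise (a.u.).
#' @param ar1 Lag-one autocorrelation of the residual process in time,
#'   in `[0, 1)`.
#' @param slopes Named numeric vector of covariate slopes (a.u. per
#'   z-unit); names must be covariate columns of the trial table
#'   (z-scored globally before use).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(participant_intercept_sd = 0.5, residual_sd = 1,
                       ar1 = 0.5, slopes = c(noun_zipf = 0, adj_zipf = 0, onset_time_s = 0)) {
  if (participant_intercept_sd < 0 || residual_sd < 0)
    stop("invalid-argument: sds must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("invalid-argument: ar1 must be in [0, 1)")
  structure(list(participant_intercept_sd = participant_intercept_sd,
                 residual_sd = residual_sd, ar1 = ar1, slopes = slopes),
            class = "noise_spec")
}

.kernel_on_grid <- function(effect, times) {
  k <- numeric(length(times))
  inwin <- times >= effect$window[1L] - 1e-9 & times <= effect$window[2L] + 1e-9
  if (effect$kernel == "boxcar") {
    k[inwin] <- 1
  } else {
    centre <- mean(effect$window)
    k[inwin] <- exp(-((times[inwin] - centre)^2) / (2 * effect$sigma^2))
  }
  k
}

# z-score with NA -> 0 (mean imputation after scaling); constant columns
# map to 0.
.zscore0 <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mu) / s
  z[is.na(z)] <- 0
  z
}

#' Simulate single-trial ROI activation epochs
#'
#' Generates trials x timepoints activation as the sum of a participant
#' random intercept, global-z-scored covariate contributions, configured
#' condition-effect bumps, and AR(1) Gaussian noise with the stated
#' marginal SD. The per-trial noiseless expected signal and the drawn
#' intercepts are returned as a `ground_truth` attribute for recovery
#' tests.
#'
#' @param trials Trial table (one row per trial).
#' @param effects List of [effect_spec()] objects (may be empty).
#' @param noise A [noise_spec()].
#' @param sfreq Sampling frequency, Hz (default 200).
#' @param seed Integer seed.
#' @param tmin,tmax Epoch limits in seconds (defaults -0.100 to 1.200,
#'   relative to first-word onset).
#' @param roi_id Region label for the result.
#' @return An [epoch_set()] with attribute `ground_truth` (list with
#'   `expected` matrix and `intercepts` named vector).
#' @export
simulate_roi_epochs <- function(trials, effects = list(), noise = noise_spec(),
                                sfreq = 200, seed = 1L, tmin = -0.1, tmax = 1.2,
                                roi_id = "ROI") {
  if (nrow(trials) == 0L) stop("invalid-argument: trials is empty")
  if (sfreq <= 0) stop("invalid-argument: sfreq must be > 0")
  times <- .epoch_times(sfreq, tmin, tmax)
  n <- nrow(trials)
  tp <- length(times)
  for (e in effects) {
    if (e$window[1L] < times[1L] - 1e-9 || e$window[2L] > times[tp] + 1e-9)
      stop("invalid-argument: effect window outside epoch times")
    if (!e$factor %in% names(trials))
      stop("invalid-argument: effect factor '", e$factor, "' not in trials")
  }
  rng <- .seeded_rng(seed)

  expected <- matrix(0, n, tp)
  # Participant intercepts (constant over the epoch)
  pid <- as.character(trials$participant_id)
  participants <- unique(pid)
  intercepts <- rng(function() stats::rnorm(length(participants), 0, noise$participant_intercept_sd))
  names(intercepts) <- participants
  expected <- expected + intercepts[pid]

  # Covariate contributions (constant over the epoch)
  for (nm in names(noise$slopes)) {
    if (noise$slopes[[nm]] == 0) next
    if (!nm %in% names(trials))
      stop("invalid-argument: slope covariate '", nm, "' not in trials")
    x <- trials[[nm]]
    if (nm == "onset_time_s") x <- log(x)
    expected <- expected + noise$slopes[[nm]] * .zscore0(x)
  }

  # Condition-effect bumps
  for (e in effects) {
    k <- .kernel_on_grid(e, times)
    lev <- as.character(trials[[e$factor]])
    w <- ifelse(lev %in% names(e$weights), e$weights[lev], 0)
    expected <- expected + (e$amplitude * w) %o% k
  }

  data <- expected
  if (noise$residual_sd > 0) {
    innov_sd <- noise$residual_sd * sqrt(1 - noise$ar1^2)
    eps <- rng(function() matrix(stats::rnorm(n * tp), n, tp))
    ar <- matrix(0, n, tp)
    ar[, 1L] <- eps[, 1L] * noise$residual_sd
    if (tp > 1L) for (j in 2:tp) ar[, j] <- noise$ar1 * ar[, j - 1L] + innov_sd * eps[, j]
    data <- data + ar
  }
  out <- epoch_set(data, times, sfreq, roi_id)
  attr(out, "ground_truth") <- list(expected = expected, intercepts = intercepts)
  out
}

#' Simulate oscillatory sensor-like trials
#'
#' Each burst adds a windowed sinusoid; phase-locked bursts share one
#' phase across trials (so they survive time-domain averaging, like an
#' evoked component), non-phase-locked bursts draw an i.i.d. uniform
#' phase per trial (induced power: present per trial, cancelled in the
#' average). Additive white Gaussian noise.
#'
#' @param trials Trial table; a burst with a `factor`/`levels` entry is
#'   applied only to trials at those levels.
#' @param bursts List of lists with fields `freq` (Hz), `window`
#'   (seconds), `amplitude`, `phase_locked` (logical) and optionally
#'   `factor`, `levels`.
#' @param noise_sd White noise SD.
#' @param sfreq Sampling frequency, Hz.
#' @param seed Integer seed.
#' @param tmin,tmax Epoch limits (seconds).
#' @param roi_id Label for the result.
#' @return An [epoch_set()].
#' @export
simulate_oscillatory_trials <- function(trials, bursts = list(), noise_sd = 0,
                                        sfreq = 200, seed = 1L,
                                        tmin = -0.1, tmax = 1.2, roi_id = "sensors") {
  if (nrow(trials) == 0L) stop("invalid-argument: trials is empty")
  for (b in bursts) {
    if (b$freq >= sfreq / 2)
      stop("invalid-argument: burst frequency at or above Nyquist")
  }
  times <- .epoch_times(sfreq, tmin, tmax)
  n <- nrow(trials)
  tp <- length(times)
  rng <- .seeded_rng(seed)
  data <- matrix(0, n, tp)
  for (b in bursts) {
    sel <- rep(TRUE, n)
    if (!is.null(b$factor)) sel <- as.character(trials[[b$factor]]) %in% b$levels
    inwin <- times >= b$window[1L] - 1e-9 & times <= b$window[2L] + 1e-9
    phase <- if (isTRUE(b$phase_locked)) rep(0, n) else rng(function() stats::runif(n, 0, 2 * pi))
    carrier <- outer(phase[sel], times[inwin], function(ph, t) cos(2 * pi * b$freq * t + ph))
    data[sel, inwin] <- data[sel, inwin] + b$amplitude * carrier
  }
  if (noise_sd > 0) data <- data + rng(function() matrix(stats::rnorm(n * tp, 0, noise_sd), n, tp))
  epoch_set(data, times, sfreq, roi_id)
}
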