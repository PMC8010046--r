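#' Cluster-forming threshold for chi-square timecourses
#'
#' The 95th percentile (in general, the `1 - alpha` quantile) of the
#' central chi-square distribution with the comparison's degrees of
#' freedom.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Tail probability (default 0.05).
#' @return The threshold value.
#' @export
chi2_threshold <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || df < 1) stop("invalid-argument: df must be >= 1")
  stats::qchisq(1 - alpha, df = df)
}

#' Find temporal clusters of suprathreshold statistics
#'
#' Maximal runs of contiguous timepoints whose statistic strictly exceeds
#' the threshold. Cluster mass is the sum of the member statistics.
#'
#' @param tc An `lrt_timecourse` (or any list with `chi2` and `times`).
#' @param threshold Cluster-forming threshold (>= 0).
#' @return Data frame of clusters sorted by descending mass then start
#'   index: `start_idx`/`end_idx` (half-open, 1-based: members are
#'   `start_idx .. end_idx - 1`), `start_s`/`end_s` (first/last member
#'   sample times), `mass`, `n_members`. Zero rows if nothing exceeds
#'   the threshold.
#' @export
find_clusters <- function(tc, threshold) {
  if (threshold < 0) stop("invalid-argument: threshold must be >= 0")
  x <- tc$chi2
  above <- x > threshold
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      mass = numeric(0), n_members = integer(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(
    start_idx = starts[keep],
    end_idx = ends[keep] + 1L,
    start_s = tc$times[starts[keep]],
    end_s = tc$times[ends[keep]],
    mass = vapply(keep, function(k) sum(x[starts[k]:ends[k]]), 0),
    n_members = r$lengths[keep]
  )
  out <- out[order(-out$mass, out$start_idx), ]
  rownames(out) <- NULL
  out
}

# Shuffle the variable-of-interest columns of the full design matrix by
# permuting trials within each participant; nuisance covariates stay
# bound to their trials.
.permute_voi <- function(X_full, voi_cols, group) {
  idx <- seq_len(nrow(X_full))
  for (lev in levels(group)) {
    rows <- which(group == lev)
    idx[rows] <- rows[sample.int(length(rows))]
  }
  Xp <- X_full
  Xp[, voi_cols] <- X_full[idx, voi_cols, drop = FALSE]
  Xp
}

#' Cluster-mass Monte-Carlo permutation test for one ROI
#'
#' Forms the observed chi-square timecourse, thresholds it at the
#' chi-square `1 - alpha` quantile, and compares the biggest observed
#' cluster mass against a null distribution built by shuffling the
#' condition labels (variables of interest) across trials within each
#' participant and recomputing the full timecourse. The p-value is the
#' proportion of permutations whose biggest cluster mass is strictly
#' greater than the observed one (permutations without clusters
#' contribute mass 0); `p_smoothing = TRUE` applies the conventional
#' `(b + 1) / (m + 1)` correction instead.
#'
#' @param epochs [epoch_set()] for the ROI.
#' @param trials Trial table aligned with `epochs`.
#' @param spec A [model_spec()] with non-empty variables of interest.
#' @param window Analysis window in seconds (closed interval).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Master seed; per-permutation streams are derived from it.
#' @param alpha Cluster-forming tail probability.
#' @param p_smoothing Use the `(b+1)/(m+1)` estimator.
#' @return List of class `permutation_result`: `roi_id`, `timecourse`,
#'   `threshold`, `clusters` (all observed clusters), `observed_mass`,
#'   `null_masses` (length `n_perm`), `p_raw`, `no_cluster` flag,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(epochs, trials, spec, window = NULL,
                             n_perm = 1000L, seed = 1L, alpha = 0.05,
                             p_smoothing = FALSE) {
  if (n_perm < 1L) stop("invalid-argument: n_perm must be >= 1")
  if (!length(spec$voi)) stop("invalid-argument: variables_of_interest is empty")
  dm <- build_design_matrices(trials, spec)
  if (nlevels(dm$group) < 2L) stop("invalid-argument: need >= 2 participants")
  idx <- .window_index(epochs$times, window)
  Y <- epochs$data[, idx, drop = FALSE]

  red <- .ri_ml_loglik(dm$X_reduced, Y, dm$group)
  full <- .ri_ml_loglik(dm$X_full, Y, dm$group)
  thr <- chi2_threshold(dm$df_interest, alpha)
  tc <- structure(list(roi_id = epochs$roi_id, times = epochs$times[idx],
                       chi2 = pmax(2 * (full$loglik - red$loglik), 0),
                       df = dm$df_interest,
                       converged = as.logical(full$ok) & as.logical(red$ok)),
                  class = "lrt_timecourse")
  obs_clusters <- find_clusters(tc, thr)
  observed_mass <- if (nrow(obs_clusters)) obs_clusters$mass[1L] else 0

  rng <- .seeded_rng(seed)
  perm_seeds <- rng(function() sample.int(.Machine$integer.max - 1L, n_perm))
  null_masses <- vapply(seq_len(n_perm), function(b) {
    prng <- .seeded_rng(perm_seeds[b])
    Xp <- prng(function() .permute_voi(dm$X_full, dm$voi_cols, dm$group))
    fp <- .ri_ml_loglik(Xp, Y, dm$group)
    chi2 <- pmax(2 * (fp$loglik - red$loglik), 0)
    cl <- find_clusters(list(chi2 = chi2, times = tc$times), thr)
    if (nrow(cl)) cl$mass[1L] else 0
  }, 0)

  no_cluster <- nrow(obs_clusters) == 0L
  p_raw <- if (no_cluster) 1.0
  else if (p_smoothing) (sum(null_masses > observed_mass) + 1) / (n_perm + 1)
  else mean(null_masses > observed_mass)
  structure(list(roi_id = epochs$roi_id, timecourse = tc, threshold = thr,
                 clusters = obs_clusters, observed_mass = observed_mass,
                 null_masses = null_masses, p_raw = p_raw,
                 no_cluster = no_cluster, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> roi=%s  biggest mass=%.2f  p=%.4g (%d perms)%s\n",
              x$roi_id, x$observed_mass, x$p_raw, x$n_perm,
              if (x$no_cluster) "  [no observed cluster]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values, monotone after sorting and capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_correct <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("invalid-argument: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
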