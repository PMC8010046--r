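#' Nested mixed-model specification
#'
#' Defines the full fixed-effect structure, the variables of interest
#' (the terms absent from the reduced model), and the grouping factor for
#' the participant random intercept. The likelihood-ratio statistic at a
#' timepoint compares full against reduced under maximum likelihood; its
#' null degrees of freedom equal the number of fixed-effect columns
#' dropped.
#'
#' @param fixed One-sided formula for the full fixed-effect structure,
#'   e.g. `~ syntactic + noun_specificity * adj_typicality + noun_zipf_z`.
#' @param voi Character vector of term labels of interest (must be term
#'   labels of `fixed`).
#' @param grouping Column name of the random-intercept grouping factor.
#' @param response Response label (metadata only; epochs carry the data).
#' @return A `model_spec` object.
#' @export
model_spec <- function(fixed, voi, grouping = "participant_id",
                       response = "activation") {
  labs <- attr(stats::terms(fixed), "term.labels")
  voi <- as.character(voi)
  if (!all(voi %in% labs))
    stop("invalid-argument: variables_of_interest must be terms of `fixed`: ",
         paste(setdiff(voi, labs), collapse = ", "))
  structure(list(fixed = fixed, voi = voi, grouping = grouping,
                 response = response),
            class = "model_spec")
}

# Z-scored covariate columns used by the model presets. Zipf frequencies
# are z-scored globally over the trials entering the analysis; onset time
# is log-transformed first. NAs (covariate absent for a trial type) are
# mean-imputed to zero after scaling.
#' Add z-scored covariate columns to a trial table
#'
#' Adds `noun_zipf_z`, `adj_zipf_z`, `word_zipf_z` and `log_onset_z`
#' columns (z-scored over the supplied rows; missing covariates become 0
#' after centring).
#'
#' @param trials Trial table.
#' @return The trial table with the covariate columns appended.
#' @export
add_model_covariates <- function(trials) {
  if ("noun_zipf" %in% names(trials)) trials$noun_zipf_z <- .zscore0(trials$noun_zipf)
  if ("adj_zipf" %in% names(trials)) trials$adj_zipf_z <- .zscore0(trials$adj_zipf)
  if ("word_zipf" %in% names(trials)) trials$word_zipf_z <- .zscore0(trials$word_zipf)
  if ("onset_time_s" %in% names(trials)) trials$log_onset_z <- .zscore0(log(trials$onset_time_s))
  trials
}

#' Model presets for the five nested comparisons
#'
#' Ready-made [model_spec()] objects mirroring the analyses of the
#' two-word and single-word designs:
#' \describe{
#'   \item{`complexity`}{syntactic structure (3 levels) on two-word
#'     trials, adjective window; drops 2 columns.}
#'   \item{`noun_definiteness`}{noun definiteness on two-word trials,
#'     noun window; drops 1 column.}
#'   \item{`block_by_definiteness`}{block type x noun definiteness on
#'     two-word plus single-noun trials; drops 3 columns.}
#'   \item{`category_by_definiteness`}{word category x word definiteness
#'     on single-word trials; drops 3 columns.}
#'   \item{`semantic_composition`}{noun type (high/low/none) x adjective
#'     typicality x adjective definiteness on two-word plus
#'     single-adjective trials; drops 11 columns.}
#' }
#' Optionally includes the gender covariate.
#'
#' @param name Preset name.
#' @param include_gender Add the `gender` factor as a nuisance term
#'   (default `FALSE` for synthetic runs).
#' @return A [model_spec()].
#' @export
model_preset <- function(name = c("complexity", "noun_definiteness",
                                  "block_by_definiteness",
                                  "category_by_definiteness",
                                  "semantic_composition"),
                         include_gender = FALSE) {
  name <- match.arg(name)
  g <- if (include_gender) "+ gender" else ""
  f <- switch(name,
    complexity = paste("~ syntactic + noun_specificity * adj_typicality",
                       "+ noun_zipf_z + adj_zipf_z + log_onset_z", g),
    noun_definiteness = paste("~ noun_definiteness + noun_specificity * adj_typicality",
                              "+ noun_zipf_z + adj_zipf_z + log_onset_z", g),
    block_by_definiteness = paste("~ block_type * noun_definiteness + noun_specificity",
                                  "+ noun_zipf_z + log_onset_z", g),
    category_by_definiteness = paste("~ word_category * word_definiteness",
                                     "+ word_zipf_z + log_onset_z", g),
    semantic_composition = paste("~ noun_type * adj_typicality * adj_definiteness",
                                 "+ adj_zipf_z + log_onset_z", g)
  )
  voi <- switch(name,
    complexity = "syntactic",
    noun_definiteness = "noun_definiteness",
    block_by_definiteness = c("block_type", "noun_definiteness",
                              "block_type:noun_definiteness"),
    category_by_definiteness = c("word_category", "word_definiteness",
                                 "word_category:word_definiteness"),
    semantic_composition = c("noun_type", "adj_typicality", "adj_definiteness",
                             "noun_type:adj_typicality", "noun_type:adj_definiteness",
                             "adj_typicality:adj_definiteness",
                             "noun_type:adj_typicality:adj_definiteness")
  )
  model_spec(stats::as.formula(f), voi)
}

#' Subset and derive columns for a preset analysis
#'
#' Restricts the trial table to the rows a preset analyses and derives
#' the columns it needs (`word_definiteness` for single-word trials,
#' `noun_type` with level `none` for single-adjective trials), then adds
#' z-scored covariates.
#'
#' @param trials Full trial table from [generate_design()].
#' @param name Preset name as in [model_preset()].
#' @return The filtered, augmented trial table.
#' @export
preset_trials <- function(trials, name) {
  out <- switch(name,
    complexity = ,
    noun_definiteness = trials[trials$block_type == "two_word", , drop = FALSE],
    block_by_definiteness = trials[trials$block_type == "two_word" |
                                     trials$word_category == "noun", , drop = FALSE],
    category_by_definiteness = {
      d <- trials[trials$block_type == "one_word", , drop = FALSE]
      d$word_definiteness <- ifelse(d$word_category == "noun",
                                    d$noun_definiteness, d$adj_definiteness)
      d
    },
    semantic_composition = {
      d <- trials[trials$block_type == "two_word" |
                    trials$word_category == "adjective", , drop = FALSE]
      d$noun_type <- ifelse(d$block_type == "two_word", d$noun_specificity, "none")
      d$adj_zipf <- ifelse(is.na(d$adj_zipf), d$word_zipf, d$adj_zipf)
      d
    },
    stop("invalid-argument: unknown preset '", name, "'")
  )
  add_model_covariates(out)
}

#' Build full and reduced design matrices
#'
#' Treatment coding with the alphabetically first level as reference.
#' The reduced matrix is the full matrix minus the columns of the
#' variables-of-interest terms; the dropped-column count is the null df
#' of the likelihood-ratio statistic.
#'
#' @param trials Trial table containing every model variable.
#' @param spec A [model_spec()].
#' @return List with `X_full`, `X_reduced`, `group` (factor), `voi_cols`
#'   (indices into `X_full`), `df_interest`.
#' @export
build_design_matrices <- function(trials, spec) {
  vars <- all.vars(spec$fixed)
  miss <- setdiff(vars, names(trials))
  if (length(miss))
    stop("invalid-argument: model variables missing from trials: ",
         paste(miss, collapse = ", "))
  dat <- trials
  for (v in vars) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2L)
        stop("invalid-argument: factor '", v, "' has fewer than 2 observed levels")
    }
  }
  tt <- stats::terms(spec$fixed)
  X <- stats::model.matrix(tt, dat)
  asn <- attr(X, "assign")
  labs <- attr(tt, "term.labels")
  voi_cols <- which(asn %in% match(spec$voi, labs))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design matrix; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  Xr <- X[, setdiff(seq_len(ncol(X)), voi_cols), drop = FALSE]
  group <- factor(dat[[spec$grouping]])
  list(X_full = X, X_reduced = Xr, group = group,
       voi_cols = voi_cols, df_interest = length(voi_cols))
}

# Profiled ML log-likelihoods for the random-intercept model, for every
# column of Y at once (one shared design). Returns loglik, theta, ok.
.ri_ml_loglik <- function(X, Y, group) {
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n <= ncol(X))
    stop("invalid-argument: fewer trials than fixed-effect columns")
  g <- as.integer(group)
  ng <- as.numeric(tabulate(g, nbins = nlevels(group)))
  ZtY <- rowsum(Y, g, reorder = TRUE)
  ZtX <- rowsum(X, g, reorder = TRUE)
  res <- ri_ml_profile_cpp(crossprod(X), t(ZtX), crossprod(X, Y), ZtY,
                           colSums(Y^2), ng, n)
  res
}

#' Likelihood-ratio statistic at a single timepoint
#'
#' Fits the full and reduced random-intercept models by maximum
#' likelihood (not REML) and returns `chi2 = 2 (l_full - l_reduced)`,
#' clipped at zero. On a non-finite fit the OLS likelihood-ratio
#' statistic is substituted and the timepoint flagged.
#'
#' @param y Numeric response vector (one trial per element).
#' @param dm Design matrices from [build_design_matrices()].
#' @return List with `chi2`, `loglik_full`, `loglik_reduced`, `converged`.
#' @export
fit_lrt_at_timepoint <- function(y, dm) {
  if (!all(is.finite(y))) stop("invalid-argument: y must be finite")
  full <- .ri_ml_loglik(dm$X_full, cbind(y), dm$group)
  red <- .ri_ml_loglik(dm$X_reduced, cbind(y), dm$group)
  ll_f <- full$loglik[1L]
  ll_r <- red$loglik[1L]
  conv <- isTRUE(full$ok[1L]) && isTRUE(red$ok[1L]) && is.finite(ll_f) && is.finite(ll_r)
  if (!conv) {
    ols <- .ols_lrt(dm$X_full, dm$X_reduced, y)
    return(list(chi2 = ols$chi2, loglik_full = ols$ll_full,
                loglik_reduced = ols$ll_red, converged = FALSE))
  }
  list(chi2 = max(0, 2 * (ll_f - ll_r)), loglik_full = ll_f,
       loglik_reduced = ll_r, converged = TRUE)
}

# Gaussian OLS log-likelihoods and LRT (used as fallback and as the
# zero-variance oracle in tests).
.ols_lrt <- function(Xf, Xr, y) {
  n <- length(y)
  ll <- function(X) {
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  ll_full <- ll(Xf)
  ll_red <- ll(Xr)
  list(chi2 = max(0, 2 * (ll_full - ll_red)), ll_full = ll_full, ll_red = ll_red)
}

#' Likelihood-ratio chi-square timecourse
#'
#' Runs the nested model comparison at every timepoint of an analysis
#' window (boundary samples included) and returns the chi-square
#' timecourse with its degrees of freedom and convergence flags.
#'
#' @param epochs An [epoch_set()] whose rows align with `trials`.
#' @param trials Trial table.
#' @param spec A [model_spec()].
#' @param window Length-2 numeric window in seconds (closed interval);
#'   `NULL` analyses the whole epoch.
#' @return An object of class `lrt_timecourse`: list with `roi_id`,
#'   `times`, `chi2`, `df`, `converged`.
#' @export
lrt_timecourse <- function(epochs, trials, spec, window = NULL) {
  if (nrow(epochs$data) != nrow(trials))
    stop("invalid-argument: epochs and trials disagree on trial count")
  idx <- .window_index(epochs$times, window)
  dm <- build_design_matrices(trials, spec)
  Y <- epochs$data[, idx, drop = FALSE]
  full <- .ri_ml_loglik(dm$X_full, Y, dm$group)
  red <- .ri_ml_loglik(dm$X_reduced, Y, dm$group)
  chi2 <- 2 * (full$loglik - red$loglik)
  conv <- as.logical(full$ok) & as.logical(red$ok) & is.finite(chi2)
  if (any(!conv)) {
    for (j in which(!conv)) {
      ols <- .ols_lrt(dm$X_full, dm$X_reduced, Y[, j])
      chi2[j] <- ols$chi2
    }
  }
  chi2 <- pmax(chi2, 0)
  structure(list(roi_id = epochs$roi_id, times = epochs$times[idx],
                 chi2 = as.numeric(chi2), df = dm$df_interest,
                 converged = conv),
            class = "lrt_timecourse")
}

.window_index <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  if (length(window) != 2L || window[2L] < window[1L])
    stop("invalid-argument: window must be [start_s, end_s]")
  idx <- which(times >= window[1L] - 1e-9 & times <= window[2L] + 1e-9)
  if (!length(idx)) stop("invalid-argument: empty analysis window")
  idx
}

#' @export
print.lrt_timecourse <- function(x, ...) {
  cat(sprintf("<lrt_timecourse> roi=%s  %d timepoints  df=%d  max chi2=%.2f\n",
              x$roi_id, length(x$times), x$df, max(x$chi2)))
  invisible(x)
}

#' Fit the random-intercept model at one timepoint (coefficients)
#'
#' Convenience estimator returning the ML fixed-effect estimates,
#' variance components and coefficient covariance for a single response
#' vector (used for parameter-recovery checks and marginal-mean
#' computations that bypass lme4).
#'
#' @param X Fixed-effect design matrix.
#' @param y Response vector.
#' @param group Grouping factor.
#' @return List with `beta`, `theta` (variance ratio), `sigma2`,
#'   `loglik`, `vcov_beta`.
#' @export
ri_ml_fit <- function(X, y, group) {
  group <- factor(group)
  res <- .ri_ml_loglik(X, cbind(y), group)
  theta <- res$theta[1L]
  g <- as.integer(group)
  ng <- tabulate(g, nbins = nlevels(group))
  w <- theta / (1 + theta * ng)
  ZtX <- rowsum(X, g)
  Zty <- rowsum(cbind(y), g)[, 1L]
  A <- crossprod(X) - t(ZtX) %*% (ZtX * w)
  b <- crossprod(X, y) - t(ZtX) %*% (w * Zty)
  # Jacobi scaling keeps the solve stable when theta is large and
  # between-group columns carry little information
  d <- sqrt(diag(A))
  As <- A / tcrossprod(d)
  beta <- solve(As, b / d) / d
  q <- sum(y^2) - sum(w * Zty^2)
  rss <- max(q - sum(b * beta), 1e-13 * max(q, 1e-300))
  sigma2 <- rss / length(y)
  list(beta = drop(beta), theta = theta, sigma2 = sigma2,
       loglik = res$loglik[1L], vcov_beta = sigma2 * (solve(As) / tcrossprod(d)))
}
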