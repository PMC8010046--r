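#' Average epoch activity over a cluster's timepoints
#'
#' @param epochs An [epoch_set()].
#' @param cluster One row of a [find_clusters()] result (or any list with
#'   `start_idx` and `end_idx`, half-open indices into the timecourse the
#'   cluster was found on). If the cluster was found on a windowed
#'   timecourse, pass its `times` so indices can be mapped back onto the
#'   epoch grid.
#' @param times Time vector the cluster indices refer to (defaults to
#'   `epochs$times`).
#' @return Numeric vector with one mean activation per trial.
#' @export
cluster_average <- function(epochs, cluster, times = epochs$times) {
  if (is.data.frame(cluster)) {
    if (nrow(cluster) == 0L) stop("invalid-argument: empty cluster")
    cluster <- cluster[1L, ]
  }
  member_times <- times[cluster$start_idx:(cluster$end_idx - 1L)]
  cols <- match(round(member_times, 9), round(epochs$times, 9))
  if (anyNA(cols)) stop("invalid-argument: cluster indices outside epochs")
  rowMeans(epochs$data[, cols, drop = FALSE])
}

#' Estimated marginal means and multiplicity-adjusted contrasts
#'
#' Refits the full fixed-effect structure (participant random intercept,
#' REML via lme4) on a per-trial scalar response, then computes estimated
#' marginal means over the reference grid: predictions on the full cross
#' of the model's factor levels, with covariates fixed at their observed
#' means, averaged with equal weights over the factors not in `family`.
#' All pairwise contrasts within the family (or a requested subset) are
#' tested with the named multiplicity adjustment; the Tukey adjustment
#' uses the studentized-range distribution with the family size as the
#' number of means.
#'
#' @param scalars Per-trial response vector (e.g. from
#'   [cluster_average()]).
#' @param trials Trial table aligned with `scalars`.
#' @param spec A [model_spec()]; its full fixed structure is refit.
#' @param family Character vector of factor names defining the EMM cells.
#' @param adjust `"tukey"`, `"bonferroni"` or `"none"`.
#' @param contrasts Optional list of length-2 character vectors naming
#'   the cell pairs to test (default: all pairwise). The adjustment
#'   family size is the number of requested contrasts.
#' @return List of class `emm_table` with data frames `emmeans`
#'   (`cell`, `emm`, `se`) and `contrasts` (`pair`, `estimate`, `se`,
#'   `t`, `df`, `p`, `p_adjusted`).
#' @export
emm_and_contrasts <- function(scalars, trials, spec, family,
                              adjust = c("tukey", "bonferroni", "none"),
                              contrasts = NULL) {
  adjust <- match.arg(adjust)
  vars <- all.vars(spec$fixed)
  if (!all(family %in% vars))
    stop("invalid-argument: family factors must appear in the model")
  dat <- trials
  dat$.y <- scalars
  fac_vars <- vars[vapply(vars, function(v) is.character(dat[[v]]) || is.factor(dat[[v]]), TRUE)]
  num_vars <- setdiff(vars, fac_vars)
  for (v in fac_vars) dat[[v]] <- droplevels(factor(dat[[v]]))
  for (v in family) {
    if (any(table(dat[[v]]) == 0L))
      stop("invalid-argument: family level with zero trials")
  }

  fml <- stats::update(spec$fixed, paste(".y ~ . + (1 |", spec$grouping, ")"))
  fit <- lme4::lmer(fml, data = dat,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  Vb <- as.matrix(stats::vcov(fit))

  # Reference grid: full cross of factor levels, covariates at means
  grid <- expand.grid(lapply(dat[fac_vars], levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in fac_vars) grid[[v]] <- factor(grid[[v]], levels = levels(dat[[v]]))
  for (v in num_vars) grid[[v]] <- mean(dat[[v]])
  tt <- stats::delete.response(stats::terms(spec$fixed))
  L_grid <- stats::model.matrix(tt, grid)
  L_grid <- L_grid[, names(beta), drop = FALSE]

  # Equal-weight average over non-family factors within each family cell
  cell <- interaction(grid[family], sep = ":", drop = FALSE)
  L <- rowsum(L_grid, cell) / as.vector(table(cell))
  emm <- drop(L %*% beta)
  se <- sqrt(rowSums((L %*% Vb) * L))
  emmeans <- data.frame(cell = rownames(L), emm = emm, se = se,
                        row.names = NULL, stringsAsFactors = FALSE)

  cells <- emmeans$cell
  if (is.null(contrasts)) {
    pairs <- utils::combn(cells, 2, simplify = FALSE)
  } else {
    pairs <- lapply(contrasts, function(p) {
      if (!all(p %in% cells))
        stop("invalid-argument: unknown cells in contrast: ", paste(p, collapse = " vs "))
      p
    })
  }
  df_resid <- nrow(dat) - length(beta)
  k_family <- if (is.null(contrasts)) length(cells) else NA_integer_
  ctr <- do.call(rbind, lapply(pairs, function(p) {
    lrow <- L[p[1L], ] - L[p[2L], ]
    est <- sum(lrow * beta)
    s <- sqrt(drop(t(lrow) %*% Vb %*% lrow))
    tval <- est / s
    praw <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
    data.frame(pair = paste(p[1L], "-", p[2L]), estimate = est, se = s,
               t = tval, df = df_resid, p = praw, stringsAsFactors = FALSE)
  }))
  m <- nrow(ctr)
  # For a requested subset of contrasts the studentized range does not
  # apply; the family size is then the number of requested contrasts and
  # a Bonferroni-type scaling is used in its place.
  ctr$p_adjusted <- switch(adjust,
    none = ctr$p,
    bonferroni = pmin(1, m * ctr$p),
    tukey = if (!is.na(k_family)) {
      stats::ptukey(abs(ctr$t) * sqrt(2), nmeans = k_family, df = df_resid,
                    lower.tail = FALSE)
    } else {
      pmin(1, m * ctr$p)
    })
  ctr$p_adjusted <- pmax(ctr$p_adjusted, ctr$p)
  structure(list(emmeans = emmeans, contrasts = ctr, adjust = adjust,
                 family = family, fit = fit),
            class = "emm_table")
}

#' @export
print.emm_table <- function(x, ...) {
  cat("Estimated marginal means (", paste(x$family, collapse = " x "), "):\n", sep = "")
  print(x$emmeans, digits = 4)
  cat("\nContrasts (", x$adjust, "-adjusted):\n", sep = "")
  print(x$contrasts, digits = 4)
  invisible(x)
}
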