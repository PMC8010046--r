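#' Shannon entropy of a probability distribution
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. Base 2 gives
#' bits.
#'
#' @param dist Probability vector (non-negative, sums to 1 within 1e-9).
#' @param base Logarithm base (default 2).
#' @return Entropy (bits for base 2).
#' @export
entropy <- function(dist, base = 2) {
  .check_dist(dist)
  p <- dist[dist > 0]
  -sum(p * log(p, base = base))
}

.check_dist <- function(dist) {
  if (!is.numeric(dist) || any(is.na(dist)) || any(dist < 0))
    stop("invalid-argument: probabilities must be non-negative")
  if (abs(sum(dist) - 1) > 1e-9)
    stop("invalid-argument: probabilities must sum to 1")
  invisible(TRUE)
}

#' Entropy reduction between successive states
#'
#' The drop in uncertainty about continuations after an observation,
#' `max(0, H(prior) - H(posterior))`; `signed = TRUE` returns the raw
#' difference.
#'
#' @param prior,posterior Probability vectors.
#' @param base Logarithm base.
#' @param signed Return the signed difference instead of flooring at 0.
#' @return Entropy reduction in bits (base 2).
#' @export
entropy_reduction <- function(prior, posterior, base = 2, signed = FALSE) {
  d <- entropy(prior, base) - entropy(posterior, base)
  if (signed) d else max(0, d)
}

#' Surprisal of an outcome
#'
#' `-log2(p)`: the unlikelihood of the current observation given its
#' context. Zero-probability outcomes are rejected rather than mapped to
#' infinity.
#'
#' @param p Probability in `(0, 1]`.
#' @param base Logarithm base.
#' @return Surprisal in bits (base 2).
#' @export
surprisal <- function(p, base = 2) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("invalid-argument: p must lie in (0, 1]")
  -log(p, base = base)
}

.table_dist <- function(table, context) {
  rows <- table[table$context == context, , drop = FALSE]
  if (!nrow(rows)) stop("missing-context: no transition entries for context '", context, "'")
  stats::setNames(rows$probability, rows$outcome)
}

# Total remaining entropy of the chain from a given state: the entropy
# of the distribution over complete continuations,
#   H_rem(c) = H(P(. | c)) + sum_o P(o | c) H_rem(o),
# with H_rem = 0 at terminal states (outcomes that are not contexts).
.remaining_entropy <- function(table, context, base = 2, depth = 0L) {
  if (depth > 100L)
    stop("invalid-argument: transition table recursion exceeds depth 100 (cyclic?)")
  if (!context %in% table$context) return(0)
  dist <- .table_dist(table, context)
  h <- entropy(dist, base)
  for (o in names(dist)) {
    if (dist[[o]] > 0)
      h <- h + dist[[o]] * .remaining_entropy(table, o, base, depth + 1L)
  }
  h
}

#' Incremental information metrics along a token sequence
#'
#' Walks a token sequence through a transition table, reporting for each
#' token its surprisal given the previous context, the remaining entropy
#' after it, and the entropy reduction relative to the previous state.
#' Entropy at a state is the total uncertainty over complete
#' continuations of the trial (chain-rule sum over the transition table),
#' so in the balanced two-word design the pre-trial entropy equals the
#' structure entropy log2(3) and an indefinite noun removes all of it
#' while a definite noun removes log2(3) - 1 bits. The first token is
#' conditioned on `start_context`; after the final token the trial is
#' over, so the posterior entropy is defined as zero.
#'
#' @param table Transition table: data frame with `context`, `outcome`,
#'   `probability` columns (e.g. from [design_word_transitions()]).
#' @param sequence Character vector of tokens.
#' @param start_context Context conditioning the first token.
#' @param base Logarithm base.
#' @return A `metric_report` data frame with one row per token: `token`,
#'   `surprisal`, `entropy_after`, `entropy_reduction`; attribute
#'   `provenance`.
#' @export
sequence_metrics <- function(table, sequence, start_context = "<start>",
                             base = 2) {
  stopifnot(all(c("context", "outcome", "probability") %in% names(table)))
  ctx <- start_context
  h_prev <- .remaining_entropy(table, ctx, base)
  rows <- lapply(seq_along(sequence), function(i) {
    tok <- sequence[i]
    dist <- .table_dist(table, ctx)
    if (!tok %in% names(dist) || dist[[tok]] <= 0)
      stop("missing-context: token '", tok, "' has no probability in context '", ctx, "'")
    s <- surprisal(dist[[tok]], base)
    h_after <- if (i == length(sequence)) 0 else {
      .remaining_entropy(table, tok, base)
    }
    out <- data.frame(token = tok, surprisal = s, entropy_after = h_after,
                      entropy_reduction = max(0, h_prev - h_after),
                      stringsAsFactors = FALSE)
    ctx <<- tok
    h_prev <<- h_after
    out
  })
  rep <- do.call(rbind, rows)
  attr(rep, "provenance") <- attr(table, "provenance") %||% "design"
  class(rep) <- c("metric_report", "data.frame")
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a corpus transition-probability table
#'
#' CSV with columns `context`, `outcome`, `probability`; each context's
#' distribution must sum to one.
#'
#' @param path CSV file path.
#' @return Transition table with `provenance = "corpus"`.
#' @export
read_transition_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("context", "outcome", "probability") %in% names(tab)))
  if (any(tab$probability < 0)) stop("invalid-argument: negative probability")
  sums <- tapply(tab$probability, tab$context, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("invalid-argument: context distributions must sum to 1")
  attr(tab, "provenance") <- "corpus"
  tab
}
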