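#' Enumerate the factorial condition cells
#'
#' A full stimulus set crosses, for two-word trials, three syntactic
#' structures (indefinite phrase, sentence, definite phrase) with two
#' levels of noun conceptual specificity and two levels of adjectival
#' form typicality (12 cells); single-word controls cross word category
#' with definiteness and the category-matched lexical factor (8 cells).
#' The syntactic structure of a two-word cell fully determines the
#' definiteness of both words: an indefinite phrase is indefinite noun +
#' indefinite adjective, a sentence is definite noun + bare (indefinite)
#' adjective, and a definite phrase carries the article on both words.
#'
#' @return A data frame with one row per cell (20 rows) and columns
#'   `cell_id`, `block_type`, `syntactic`, `noun_specificity`,
#'   `adj_typicality`, `noun_definiteness`, `adj_definiteness`,
#'   `word_category`.
#' @export
condition_cells <- function() {
  syn_map <- data.frame(
    syntactic = c("indefinite_phrase", "sentence", "definite_phrase"),
    noun_definiteness = c("indefinite", "definite", "definite"),
    adj_definiteness = c("indefinite", "indefinite", "definite"),
    stringsAsFactors = FALSE
  )
  two <- expand.grid(
    syntactic = syn_map$syntactic,
    noun_specificity = c("high", "low"),
    adj_typicality = c("high", "low"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  two <- merge(two, syn_map, by = "syntactic", sort = FALSE)
  two$block_type <- "two_word"
  two$word_category <- "both"

  nouns <- expand.grid(
    noun_specificity = c("high", "low"),
    noun_definiteness = c("definite", "indefinite"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  nouns$syntactic <- "none"
  nouns$adj_typicality <- "none"
  nouns$adj_definiteness <- "none"
  nouns$block_type <- "one_word"
  nouns$word_category <- "noun"

  adjs <- expand.grid(
    adj_typicality = c("high", "low"),
    adj_definiteness = c("definite", "indefinite"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  adjs$syntactic <- "none"
  adjs$noun_specificity <- "none"
  adjs$noun_definiteness <- "none"
  adjs$block_type <- "one_word"
  adjs$word_category <- "adjective"

  cols <- c("block_type", "syntactic", "noun_specificity", "adj_typicality",
            "noun_definiteness", "adj_definiteness", "word_category")
  cells <- rbind(two[, cols], nouns[, cols], adjs[, cols])
  cells <- cells[order(cells$block_type == "one_word", cells$word_category,
                       cells$syntactic, cells$noun_specificity,
                       cells$adj_typicality, cells$noun_definiteness,
                       cells$adj_definiteness), ]
  rownames(cells) <- NULL
  cells$cell_id <- seq_len(nrow(cells))
  cells[, c("cell_id", cols)]
}

# Within-block cell pairings such that the two cells of a (set, block)
# share no word token. Two-word: 6 pairs over the 12 cells; the pair in a
# block uses both nouns (high/low specificity) and both adjectives
# (high/low typicality). One-word: 4 pairs over the 8 cells, one noun +
# one adjective cell each.
.block_pairs <- function(cells) {
  two <- cells[cells$block_type == "two_word", ]
  pairs2 <- vector("list", 6L)
  k <- 1L
  for (syn in c("indefinite_phrase", "sentence", "definite_phrase")) {
    for (j in 1:2) {
      if (j == 1L) {
        a <- two$cell_id[two$syntactic == syn & two$noun_specificity == "high" & two$adj_typicality == "high"]
        b <- two$cell_id[two$syntactic == syn & two$noun_specificity == "low" & two$adj_typicality == "low"]
      } else {
        a <- two$cell_id[two$syntactic == syn & two$noun_specificity == "high" & two$adj_typicality == "low"]
        b <- two$cell_id[two$syntactic == syn & two$noun_specificity == "low" & two$adj_typicality == "high"]
      }
      pairs2[[k]] <- c(a, b)
      k <- k + 1L
    }
  }
  one <- cells[cells$block_type == "one_word", ]
  n_cell <- function(spec, def) one$cell_id[one$word_category == "noun" &
                                              one$noun_specificity == spec & one$noun_definiteness == def]
  a_cell <- function(typ, def) one$cell_id[one$word_category == "adjective" &
                                             one$adj_typicality == typ & one$adj_definiteness == def]
  pairs1 <- list(
    c(n_cell("high", "definite"),   a_cell("high", "indefinite")),
    c(n_cell("high", "indefinite"), a_cell("high", "definite")),
    c(n_cell("low", "definite"),    a_cell("low", "indefinite")),
    c(n_cell("low", "indefinite"),  a_cell("low", "definite"))
  )
  list(two_word = pairs2, one_word = pairs1)
}

# Word tokens used by a cell, as "<set>.<token>" ids. Two-word cells use a
# noun (by specificity) and an adjective (by typicality); one-word cells
# use a single token.
.cell_tokens <- function(cell, set_id) {
  toks <- character(0)
  if (cell$block_type == "two_word") {
    toks <- c(paste0("s", set_id, ".noun_", cell$noun_specificity),
              paste0("s", set_id, ".adj_", cell$adj_typicality))
  } else if (cell$word_category == "noun") {
    toks <- paste0("s", set_id, ".noun_", cell$noun_specificity)
  } else {
    toks <- paste0("s", set_id, ".adj_", cell$adj_typicality)
  }
  toks
}

#' Generate the full factorial trial table
#'
#' Builds the complete experimental design for `n_participants`
#' participants: `n_sets` stimulus sets of 20 condition cells each
#' (12 two-word + 8 single-word), distributed over 10 blocks (6 two-word,
#' 4 single-word) by a Latin-square rotation so that every word token
#' appears at most once per block. Block order and within-block trial
#' order are randomised per participant; trial onset times accumulate the
#' stated presentation timing (300 ms on / 300 ms off screen elements and
#' a uniform 466.66-700 ms inter-trial jitter). One third of the trials
#' carry a task item (half good, a quarter grammatical violation, a
#' quarter plausibility violation), counterbalanced round-robin across
#' cells before shuffling.
#'
#' @param n_sets Number of stimulus sets; must be a positive multiple of
#'   12 (the Latin-square row count, lcm of 6 two-word and 4 one-word
#'   blocks). The experiment as stated uses 36.
#' @param n_participants Number of participants (positive integer).
#' @param seed Integer seed; the design is bit-reproducible given the seed.
#' @return A data frame (one row per trial, `n_sets * 20` rows per
#'   participant) with identifier, factor, covariate and task columns; see
#'   [condition_cells()] for the factor coding.
#' @export
generate_design <- function(n_sets = 36L, n_participants = 1L, seed = 1L) {
  if (!is.numeric(n_sets) || length(n_sets) != 1L || is.na(n_sets) || n_sets <= 0)
    stop("invalid-argument: n_sets must be a positive integer")
  if (!is.numeric(n_participants) || length(n_participants) != 1L || n_participants <= 0)
    stop("invalid-argument: n_participants must be a positive integer")
  n_sets <- as.integer(n_sets)
  n_participants <- as.integer(n_participants)
  if (n_sets %% 12L != 0L)
    stop("design-infeasible: n_sets must be a multiple of 12 so that the ",
         "Latin-square rotation over 6 two-word and 4 one-word blocks closes")

  cells <- condition_cells()
  pairs <- .block_pairs(cells)

  rng <- .seeded_rng(seed)

  # Stimulus properties shared across participants: gender by set half,
  # one Zipf frequency per word token (truncated normal, Zipf scale).
  set_gender <- ifelse(seq_len(n_sets) <= n_sets / 2L, "masc", "fem")
  token_names <- as.vector(outer(c("noun_high", "noun_low", "adj_high", "adj_low"),
                                 seq_len(n_sets),
                                 function(w, s) paste0("s", s, ".", w)))
  zipf <- rng(function() {
    z <- stats::rnorm(length(token_names), mean = 4.5, sd = 0.7)
    pmin(pmax(z, 1), 7)
  })
  names(zipf) <- token_names

  # Static (participant-independent) trial skeleton: set x cell -> block.
  skel <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
    rot2 <- (s - 1L) %% 6L
    rot1 <- (s - 1L) %% 4L
    rows <- vector("list", 10L)
    for (b in 1:6) {
      pair <- pairs$two_word[[((b - 1L + rot2) %% 6L) + 1L]]
      rows[[b]] <- data.frame(set_id = s, block_id = paste0("tw", b), cell_id = pair)
    }
    for (b in 1:4) {
      pair <- pairs$one_word[[((b - 1L + rot1) %% 4L) + 1L]]
      rows[[6L + b]] <- data.frame(set_id = s, block_id = paste0("ow", b), cell_id = pair)
    }
    do.call(rbind, rows)
  }))
  skel <- merge(skel, cells, by = "cell_id", sort = FALSE)
  skel$gender <- set_gender[skel$set_id]
  noun_tok <- ifelse(skel$noun_specificity == "none", NA,
                     paste0("s", skel$set_id, ".noun_", skel$noun_specificity))
  adj_tok <- ifelse(skel$adj_typicality == "none", NA,
                    paste0("s", skel$set_id, ".adj_", skel$adj_typicality))
  skel$noun_token <- noun_tok
  skel$adj_token <- adj_tok
  skel$noun_zipf <- ifelse(is.na(noun_tok), NA_real_, zipf[noun_tok])
  skel$adj_zipf <- ifelse(is.na(adj_tok), NA_real_, zipf[adj_tok])
  skel$word_zipf <- ifelse(skel$block_type == "one_word",
                           ifelse(skel$word_category == "noun", skel$noun_zipf, skel$adj_zipf),
                           NA_real_)

  # Task assignment, counterbalanced round-robin within cell across sets
  # (period 12: 1/3 task items, of which 1/2 good, 1/4 each violation).
  task_cycle <- c("good", "none", "none", "gram_violation", "none", "none",
                  "good", "none", "none", "plaus_violation", "none", "none")
  skel <- skel[order(skel$cell_id, skel$set_id), ]
  skel$task_type <- unlist(lapply(split(seq_len(nrow(skel)), skel$cell_id), function(idx) {
    offset <- skel$cell_id[idx[1L]]
    task_cycle[((seq_along(idx) - 1L + offset) %% 12L) + 1L]
  }), use.names = FALSE)
  skel$is_task <- skel$task_type != "none"

  block_ids <- c(paste0("tw", 1:6), paste0("ow", 1:4))

  per_participant <- lapply(seq_len(n_participants), function(p) {
    d <- skel
    d$participant_id <- sprintf("P%02d", p)
    border <- rng(function() sample(block_ids))
    d$block_order <- match(d$block_id, border)
    d <- d[order(d$block_order), ]
    within <- unlist(lapply(split(seq_len(nrow(d)), d$block_order), function(idx) {
      idx[rng(function() sample.int(length(idx)))]
    }), use.names = FALSE)
    d <- d[within, ]
    # Accumulated presentation clock (seconds): fixation + word(s) +
    # trial-end element, each 300 ms on / 300 ms off, then jitter.
    n_words <- ifelse(d$block_type == "two_word", 2L, 1L)
    dur <- 0.6 * (1L + n_words + 1L) +
      rng(function() stats::runif(nrow(d), min = 0.46666, max = 0.700))
    onset <- cumsum(c(0, dur[-length(dur)])) + 0.6  # first-word onset follows fixation
    d$onset_time_s <- onset
    d
  })
  out <- do.call(rbind, per_participant)
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  cols <- c("trial_id", "participant_id", "set_id", "block_id", "block_order",
            "block_type", "syntactic", "noun_specificity", "adj_typicality",
            "noun_definiteness", "adj_definiteness", "word_category", "gender",
            "noun_token", "adj_token", "noun_zipf", "adj_zipf", "word_zipf",
            "onset_time_s", "is_task", "task_type", "cell_id")
  out[, cols]
}

# Local RNG sandbox: runs `f()` under a private RNG stream advanced across
# calls, leaving the caller's .Random.seed untouched.
.seeded_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state$seed <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state$seed, globalenv())
    res <- f()
    state$seed <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    res
  }
}

#' Empirical transition probabilities from the design
#'
#' Conditional relative frequencies of an outcome factor given a context
#' factor, computed over the two-word trials of a trial table. In the
#' balanced design, e.g., an indefinite noun is followed by an indefinite
#' phrase with probability 1, while a definite noun splits evenly between
#' sentence and definite phrase.
#'
#' @param trials Trial table from [generate_design()].
#' @param context Name of the conditioning factor column.
#' @param outcome Name of the outcome factor column (default the syntactic
#'   structure).
#' @return A data frame with columns `context`, `outcome`, `probability`
#'   (conditional) and `p_context` (marginal probability of the context
#'   value among two-word trials). Each context's conditional distribution
#'   sums to one.
#' @export
design_transition_probabilities <- function(trials, context, outcome = "syntactic") {
  for (col in c(context, outcome)) {
    if (!col %in% names(trials))
      stop("invalid-argument: unknown factor '", col, "'")
  }
  tw <- trials[trials$block_type == "two_word", , drop = FALSE]
  if (nrow(tw) == 0L) stop("invalid-argument: no two-word trials present")
  tab <- table(tw[[context]], tw[[outcome]])
  ctx_n <- rowSums(tab)
  res <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(res) <- c("context", "outcome", "n")
  res$probability <- res$n / ctx_n[res$context]
  res$p_context <- ctx_n[res$context] / sum(ctx_n)
  res <- res[res$n > 0 | TRUE, c("context", "outcome", "probability", "p_context")]
  res <- res[order(res$context, res$outcome), ]
  rownames(res) <- NULL
  res
}

#' Word-level transition table for incremental metrics
#'
#' Derives the first-word marginal distribution and word-to-word
#' conditional distributions from the two-word trials, keyed by
#' definiteness-marked word labels (e.g. `definite_noun`,
#' `indefinite_adjective`), with a `<start>` context for the first word.
#' Suitable input for [sequence_metrics()].
#'
#' @param trials Trial table from [generate_design()].
#' @return A transition table data frame (`context`, `outcome`,
#'   `probability`).
#' @export
design_word_transitions <- function(trials) {
  tw <- trials[trials$block_type == "two_word", , drop = FALSE]
  if (nrow(tw) == 0L) stop("invalid-argument: no two-word trials present")
  noun <- paste0(tw$noun_definiteness, "_noun")
  adj <- paste0(tw$adj_definiteness, "_adjective")
  start <- as.data.frame(prop.table(table(noun)), stringsAsFactors = FALSE)
  names(start) <- c("outcome", "probability")
  start$context <- "<start>"
  cond <- as.data.frame(prop.table(table(noun, adj), margin = 1), stringsAsFactors = FALSE)
  names(cond) <- c("context", "outcome", "probability")
  cond <- cond[cond$probability > 0, ]
  out <- rbind(start[, c("context", "outcome", "probability")],
               cond[, c("context", "outcome", "probability")])
  rownames(out) <- NULL
  out
}

#' Small fully-crossed trial table for simulations
#'
#' A minimal trial scaffold (participants crossed with condition cells and
#' replicates) for calibration and power studies that do not need the full
#' Latin-square design: every participant sees `trials_per_cell` trials in
#' every cell of the supplied factor levels, with Zipf-frequency and
#' onset-time covariates drawn as in the full generator.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Replicates per participant x cell.
#' @param factors Named list of factor level vectors, e.g.
#'   `list(syntactic = c("indefinite_phrase", "sentence", "definite_phrase"))`.
#' @param seed Integer seed.
#' @return A trial table data frame with `participant_id`, the factors,
#'   and `noun_zipf`, `adj_zipf`, `onset_time_s` covariates.
#' @export
factorial_trials <- function(n_participants, trials_per_cell,
                             factors = list(syntactic = c("indefinite_phrase", "sentence", "definite_phrase")),
                             seed = 1L) {
  if (n_participants < 1L || trials_per_cell < 1L)
    stop("invalid-argument: n_participants and trials_per_cell must be positive")
  grid <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = trials_per_cell), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    d <- grid
    d$participant_id <- sprintf("P%02d", p)
    d
  }))
  rng <- .seeded_rng(seed)
  n <- nrow(out)
  out$noun_zipf <- rng(function() pmin(pmax(stats::rnorm(n, 4.5, 0.7), 1), 7))
  out$adj_zipf <- rng(function() pmin(pmax(stats::rnorm(n, 4.5, 0.7), 1), 7))
  per <- table(out$participant_id)[unique(out$participant_id)]
  out$onset_time_s <- rng(function()
    unlist(lapply(per, function(k) cumsum(stats::runif(k, 2.3, 3.1))), use.names = FALSE))
  out$trial_id <- seq_len(n)
  rownames(out) <- NULL
  out
}
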