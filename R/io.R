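#' Write an epoch set to an HDF5 container with a CSV trial sidecar
#'
#' The HDF5 file holds the `data` (trials x timepoints) and `times`
#' datasets with `sfreq` and `roi_id` attributes; the trial table is
#' written next to it as `<path stem>_trials.csv`. The round trip is
#' bit-exact for the numeric arrays.
#'
#' @param epochs An [epoch_set()].
#' @param trials Trial table aligned with `epochs` (optional).
#' @param path Output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, trials = NULL, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$times, path, "times")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(epochs$sfreq, fid, "sfreq")
  rhdf5::h5writeAttribute(epochs$roi_id, fid, "roi_id")
  if (!is.null(trials))
    utils::write.csv(trials, .trials_sidecar(path), row.names = FALSE)
  invisible(path)
}

.trials_sidecar <- function(path) paste0(sub("\\.h5$", "", path), "_trials.csv")

#' Read an epoch set written by [write_epochs()]
#'
#' @param path `.h5` path.
#' @return List with `epochs` ([epoch_set()]) and `trials` (data frame or
#'   `NULL` if no sidecar exists). Extra sidecar columns are preserved.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("invalid-argument: no such file: ", path)
  contents <- rhdf5::h5ls(path)
  missing <- setdiff(c("data", "times"), contents$name)
  if (length(missing))
    stop("schema error: missing datasets: ", paste(missing, collapse = ", "))
  data <- rhdf5::h5read(path, "data")
  times <- as.numeric(rhdf5::h5read(path, "times"))
  fid <- rhdf5::H5Fopen(path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  for (a in c("sfreq", "roi_id")) {
    if (is.null(attrs[[a]]))
      stop("schema error: missing attribute: ", a)
  }
  ep <- epoch_set(data, times, as.numeric(attrs$sfreq), as.character(attrs$roi_id))
  sidecar <- .trials_sidecar(path)
  trials <- if (file.exists(sidecar)) utils::read.csv(sidecar, stringsAsFactors = FALSE) else NULL
  if (!is.null(trials) && nrow(trials) != nrow(ep$data))
    stop("schema error: trial sidecar row count does not match data")
  list(epochs = ep, trials = trials)
}

#' Analysis run configuration
#'
#' Collects and validates every tunable of the synthetic replication:
#' design size, simulation specs, the analysis windows (adjective
#' 0.700-1.100 s, noun 0.100-0.500 s, semantic 0.750-0.950 s, occipital
#' 0-0.200 s from trial onset), the model preset per analysis, and the
#' permutation/adjustment settings.
#'
#' @param n_sets,n_participants,seed Design parameters.
#' @param sfreq Simulated sampling rate (Hz).
#' @param n_perm Permutations per test (>= 1).
#' @param alpha Cluster-forming and decision level.
#' @param adjust Contrast multiplicity adjustment.
#' @param rois ROI labels to simulate; effects are injected only into
#'   those named in `effect_rois`.
#' @param effect_rois ROIs receiving the injected condition effects.
#' @param effect_amplitude Amplitude (a.u.) of the injected bumps.
#' @param noise A [noise_spec()].
#' @param windows Named list of analysis windows (seconds).
#' @param out_dir Output directory for [run_pipeline()].
#' @return Validated `run_config` list (with a config hash).
#' @export
run_config <- function(n_sets = 36L, n_participants = 21L, seed = 1L,
                       sfreq = 200, n_perm = 1000L, alpha = 0.05,
                       adjust = "tukey",
                       rois = c("LPTL", "LATL", "LIFC", "LAG"),
                       effect_rois = "LPTL",
                       effect_amplitude = 0.6,
                       noise = noise_spec(participant_intercept_sd = 0.5,
                                          residual_sd = 1, ar1 = 0.5),
                       windows = list(adjective = c(0.700, 1.100),
                                      noun = c(0.100, 0.500),
                                      semantic = c(0.750, 0.950),
                                      occipital = c(0.000, 0.200)),
                       out_dir = "results") {
  if (n_perm < 1L) stop("invalid-argument: n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("invalid-argument: alpha in (0,1)")
  for (w in windows) {
    if (length(w) != 2L || w[2L] <= w[1L])
      stop("invalid-argument: malformed window")
  }
  cfg <- list(n_sets = as.integer(n_sets), n_participants = as.integer(n_participants),
              seed = as.integer(seed), sfreq = sfreq, n_perm = as.integer(n_perm),
              alpha = alpha, adjust = adjust, rois = rois,
              effect_rois = effect_rois, effect_amplitude = effect_amplitude,
              noise = unclass(noise), windows = windows, out_dir = out_dir)
  # hash covers the statistical configuration only, not output locations
  cfg$config_hash <- digest::digest(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "noise")
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$noise)) args$noise <- do.call(noise_spec, raw$noise)
  do.call(run_config, args)
}

.log_stage <- function(msg) {
  message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S] "), msg)
}

#' Run the full synthetic replication pipeline
#'
#' Generates the factorial design, simulates ROI epochs (condition-effect
#' bumps only in the configured effect ROIs), runs the adjective-window
#' syntactic and noun-window definiteness cluster permutation tests per
#' ROI with FDR correction across ROIs, computes cluster-averaged
#' estimated marginal means and contrasts for significant ROIs, runs the
#' induced/evoked beta-band spectro-temporal analysis, and writes the
#' design-based information-theoretic report. All outputs are TSV/JSON
#' files under the configured directory; a manifest records the
#' configuration, seeds and output paths.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  paths <- list()
  wtag <- function(df) { df$config_hash <- config$config_hash; df }
  write_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(wtag(df), p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
    p
  }

  .log_stage("design: generating trial table")
  trials <- generate_design(config$n_sets, config$n_participants, seed = config$seed)

  .log_stage("simulate: ROI epochs")
  noise <- do.call(noise_spec, config$noise)
  tw <- preset_trials(trials, "complexity")
  analyses <- list(
    list(name = "adjective_syntactic", preset = "complexity",
         window = config$windows$adjective, family = "syntactic",
         effects = list(effect_spec("syntactic",
                                    c(indefinite_phrase = 1, sentence = -0.5, definite_phrase = -0.5),
                                    window = c(0.867, 0.964),
                                    amplitude = config$effect_amplitude)),
         trials = tw),
    list(name = "noun_definiteness", preset = "noun_definiteness",
         window = config$windows$noun, family = "noun_definiteness",
         effects = list(effect_spec("noun_definiteness",
                                    c(indefinite = 1, definite = -1),
                                    window = c(0.254, 0.334),
                                    amplitude = config$effect_amplitude)),
         trials = tw)
  )

  stats_rows <- list()
  emm_written <- character(0)
  for (an in analyses) {
    results <- list()
    for (i in seq_along(config$rois)) {
      roi <- config$rois[i]
      eff <- if (roi %in% config$effect_rois) an$effects else list()
      ep <- simulate_roi_epochs(an$trials, eff, noise, sfreq = config$sfreq,
                                seed = config$seed + 1000L * i, roi_id = roi)
      spec <- model_preset(an$preset)
      .log_stage(sprintf("%s: permutation test in %s (n_perm=%d)",
                         an$name, roi, config$n_perm))
      results[[roi]] <- permutation_test(ep, an$trials, spec, an$window,
                                         n_perm = config$n_perm,
                                         seed = config$seed + 7L * i,
                                         alpha = config$alpha)
      attr(results[[roi]], "epochs") <- ep
    }
    p_fdr <- fdr_correct(vapply(results, function(r) r$p_raw, 0))
    tab <- do.call(rbind, lapply(seq_along(results), function(i) {
      r <- results[[i]]
      has <- nrow(r$clusters) > 0
      data.frame(roi = r$roi_id,
                 cluster_start_s = if (has) r$clusters$start_s[1L] else NA_real_,
                 cluster_end_s = if (has) r$clusters$end_s[1L] else NA_real_,
                 mass = r$observed_mass, p_raw = r$p_raw, p_fdr = p_fdr[i])
    }))
    write_tsv(tab, paste0(an$name, "_clusters.tsv"))
    stats_rows[[an$name]] <- tab

    for (i in seq_along(results)) {
      r <- results[[i]]
      if (p_fdr[i] < config$alpha && nrow(r$clusters)) {
        .log_stage(sprintf("%s: EMM contrasts in %s", an$name, r$roi_id))
        sc <- cluster_average(attr(r, "epochs"), r$clusters, times = r$timecourse$times)
        emm <- emm_and_contrasts(sc, an$trials, model_preset(an$preset),
                                 family = an$family, adjust = config$adjust)
        write_tsv(emm$emmeans, paste0(an$name, "_", r$roi_id, "_emmeans.tsv"))
        write_tsv(emm$contrasts, paste0(an$name, "_", r$roi_id, "_contrasts.tsv"))
        emm_written <- c(emm_written, r$roi_id)
      }
    }
  }

  .log_stage("spectral: induced vs evoked beta-band analysis")
  sp_trials <- tw[tw$participant_id %in% unique(tw$participant_id), ]
  bursts <- list(
    # induced beta increase for the syntactically complex conditions
    list(freq = 18, window = c(0.78, 1.2), amplitude = 1.2,
         phase_locked = FALSE, factor = "syntactic",
         levels = c("sentence", "definite_phrase")),
    # phase-locked evoked component common to all conditions
    list(freq = 10, window = c(0, 1.2), amplitude = 2, phase_locked = TRUE))
  osc <- simulate_oscillatory_trials(sp_trials, bursts, noise_sd = 1,
                                     sfreq = config$sfreq, seed = config$seed + 99L)
  pw <- morlet_tfr(osc, freqs = 8:32, n_cycles = 4)
  stack <- baseline_and_aggregate(pw, sp_trials, condition = "syntactic", decim = 5L)
  comparisons <- list(c("sentence", "indefinite_phrase"),
                      c("definite_phrase", "indefinite_phrase"),
                      c("sentence", "definite_phrase"))
  sp_p <- vapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    res <- tfr_cluster_test(stack[[cmp[1L]]], stack[[cmp[2L]]],
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed + 31L * i,
                            times = attr(stack, "times"), freqs = attr(stack, "freqs"))
    res$p_raw
  }, 0)
  sp_tab <- data.frame(comparison = vapply(comparisons, paste, "", collapse = " > "),
                       p_raw = sp_p, p_fdr = fdr_correct(sp_p))
  write_tsv(sp_tab, "spectral_clusters.tsv")

  .log_stage("infotheory: design-based metrics")
  wt <- design_word_transitions(trials)
  seqs <- list(indefinite_phrase = c("indefinite_noun", "indefinite_adjective"),
               sentence = c("definite_noun", "indefinite_adjective"),
               definite_phrase = c("definite_noun", "definite_adjective"))
  it_tab <- do.call(rbind, lapply(names(seqs), function(cond) {
    rep <- sequence_metrics(wt, seqs[[cond]])
    rep$condition <- cond
    rep$position <- seq_len(nrow(rep))
    rep
  }))
  write_tsv(it_tab, "infotheory_design.tsv")

  manifest <- list(config = unclass(config),
                   started = format(t0), finished = format(Sys.time()),
                   outputs = paths,
                   emm_rois = unique(emm_written),
                   versions = list(R = as.character(getRversion()),
                                   package = as.character(utils::packageVersion("clustlmm"))))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_stage("pipeline complete")
  invisible(manifest)
}
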