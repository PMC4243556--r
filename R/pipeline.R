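#' Configuration for a full experiment emulation
#'
#' Bundles every parameter of the three-session whisker-pairing emulation:
#' ground-truth network generation, stimulus protocol, pairing effects per
#' session, dataset assembly, DBN inference and the network feature space.
#' Defaults follow the study conditions the analysis is designed for: ~23
#' units, 3 whiskers x 900 trials of 100-ms deflections at 1 Hz, 1-ms bins,
#' 100 datasets of 180 trials (18 s) per whisker, Markov lags 1--5, at most
#' 10 parents per neuron, 2 principal components.  Every stochastic stage
#' derives its own seed from `seed`.
#'
#' @param n_neurons units per simulated subject.
#' @param whiskers stimulated whisker labels (one barrel each).
#' @param paired the two paired whiskers.
#' @param connectivity_ratio,inhibitory_fraction,weight_range,background_rate,delay_range
#'   ground-truth network parameters (see [generate_network()]).
#' @param trials_per_whisker,trial_window,baseline_window,inter_trial_interval,peak_gain,peak_latency,decay_tau
#'   protocol parameters (see [stimulus_protocol()]).
#' @param pairing_strengths named numeric vector, one strength per session
#'   (names become session labels; the first session is the control).
#' @param convergence_modifiers signed in-degree modifiers per session.
#' @param pairing_mode,pairing_boost see [pairing_effect()].
#' @param n_subjects simulated subjects (independent seeds).
#' @param n_datasets datasets per whisker per session (M).
#' @param trials_per_dataset trials concatenated per dataset.
#' @param max_lag,max_parents,ess DBN scoring parameters.
#' @param n_components principal components of the feature space (p).
#' @param anneal list of annealing settings: `iterations`, `restarts`,
#'   `t0`, `cooling`.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_neurons = 23,
                              whiskers = c("D4", "D5", "D6"),
                              paired = c("D4", "D5"),
                              connectivity_ratio = 0.1,
                              inhibitory_fraction = 0.2,
                              weight_range = c(0.08, 0.25),
                              background_rate = 5,
                              delay_range = 1:5,
                              trials_per_whisker = 900,
                              trial_window = 100,
                              baseline_window = 100,
                              inter_trial_interval = 900,
                              peak_gain = 0.08,
                              peak_latency = 8,
                              decay_tau = 25,
                              pairing_strengths = c(control = 0,
                                                    post_1_2d = 0.4,
                                                    post_6_7d = 0.8),
                              convergence_modifiers = c(control = 0,
                                                        post_1_2d = 0.3,
                                                        post_6_7d = -0.1),
                              pairing_mode = "strengthen_cross_edges",
                              pairing_boost = 1.25,
                              n_subjects = 4,
                              n_datasets = 100,
                              trials_per_dataset = 180,
                              max_lag = 5,
                              max_parents = 10,
                              ess = 1,
                              n_components = 2,
                              anneal = list(iterations = 2e5, restarts = 3,
                                            t0 = 10, cooling = 0.9999),
                              seed = 1) {
  stopifnot(all(paired %in% whiskers), length(paired) == 2,
            length(pairing_strengths) == length(convergence_modifiers),
            length(pairing_strengths) >= 1)
  if (is.null(names(pairing_strengths)))
    names(pairing_strengths) <-
      paste0("session_", seq_along(pairing_strengths))
  names(convergence_modifiers) <- names(pairing_strengths)
  cfg <- list(n_neurons = n_neurons, whiskers = whiskers, paired = paired,
              connectivity_ratio = connectivity_ratio,
              inhibitory_fraction = inhibitory_fraction,
              weight_range = weight_range,
              background_rate = background_rate,
              delay_range = delay_range,
              trials_per_whisker = trials_per_whisker,
              trial_window = trial_window,
              baseline_window = baseline_window,
              inter_trial_interval = inter_trial_interval,
              peak_gain = peak_gain, peak_latency = peak_latency,
              decay_tau = decay_tau,
              pairing_strengths = pairing_strengths,
              convergence_modifiers = convergence_modifiers,
              pairing_mode = pairing_mode, pairing_boost = pairing_boost,
              n_subjects = n_subjects, n_datasets = n_datasets,
              trials_per_dataset = trials_per_dataset,
              max_lag = max_lag, max_parents = max_parents, ess = ess,
              n_components = n_components, anneal = anneal, seed = seed)
  class(cfg) <- "experiment_config"
  cfg
}

#' Hash of an experiment configuration
#'
#' MD5 of the YAML serialization; embedded in every output so results can be
#' traced back to the exact configuration.
#'
#' @param config an [experiment_config()].
#' @return hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full experiment emulation
#'
#' For every simulated subject: generate a control network, apply the
#' per-session pairing effect, simulate each session, assemble M datasets
#' per whisker, infer a DBN per dataset by simulated annealing, and collapse
#' lags into adjacency matrices.  A network feature space is then fitted per
#' subject jointly over all sessions and whiskers (so distances are
#' comparable across sessions), and the network-similarity, convergence and
#' single-neuron response statistics are aggregated across subjects with
#' two-sample t-tests between sessions.
#'
#' Deterministic given `config$seed`; when `out_dir` is given all tables are
#' written as CSV together with the configuration, its hash and a JSONL
#' stage log.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return a list of result tables (see Details) of class
#'   `experiment_result`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sessions <- names(config$pairing_strengths)
  protocol <- stimulus_protocol(
    whiskers = config$whiskers,
    trials_per_whisker = config$trials_per_whisker,
    trial_window = config$trial_window,
    baseline_window = config$baseline_window,
    inter_trial_interval = config$inter_trial_interval,
    peak_gain = config$peak_gain, peak_latency = config$peak_latency,
    decay_tau = config$decay_tau)
  hash <- config_hash(config)
  log <- list()
  note <- function(stage, secs) {
    log[[length(log) + 1]] <<- list(stage = stage,
                                    seconds = round(secs, 3))
    if (verbose) message(sprintf("[%s] %.1fs", stage, secs))
  }

  sim_rows <- list(); samp_rows <- list(); conv_rows <- list()
  resp_rows <- list(); proj_rows <- list(); truth_rows <- list()

  for (s in seq_len(config$n_subjects)) {
    net0 <- generate_network(
      config$n_neurons, config$connectivity_ratio, config$delay_range,
      config$inhibitory_fraction, config$weight_range,
      config$background_rate, barrels = config$whiskers,
      max_parents = config$max_parents,
      seed = derive_seed(config$seed, 1L, s))
    subj_adj <- list(); subj_meta <- list()

    for (ei in seq_along(sessions)) {
      sess <- sessions[ei]
      eff <- pairing_effect(
        config$paired,
        strength = unname(config$pairing_strengths[ei]),
        mode = config$pairing_mode,
        convergence_modifier = unname(config$convergence_modifiers[ei]),
        boost = config$pairing_boost)
      net <- apply_pairing(net0, eff, seed = derive_seed(config$seed, 2L, s))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject = s, session = sess, n_edges = nrow(net$edges),
        mean_in_degree = nrow(net$edges) / net$n_neurons)

      t0 <- proc.time()[3]
      ens <- simulate_session(net, protocol,
                              seed = derive_seed(config$seed, 3L, s, ei))
      note(sprintf("simulate subject %d %s", s, sess), proc.time()[3] - t0)

      rs <- response_summary(ens)
      for (metric in c("evoked_count", "latency")) {
        col <- if (metric == "evoked_count") "evoked_mean" else "latency_mean"
        v1 <- rs[rs$whisker == config$paired[1], col]
        v2 <- rs[rs$whisker == config$paired[2], col]
        ns <- neuron_similarity(v1, v2)
        resp_rows[[length(resp_rows) + 1]] <- data.frame(
          subject = s, session = sess, metric = metric,
          neuron = ns$neuron, similarity = ns$similarity)
      }

      t0 <- proc.time()[3]
      for (w in config$whiskers) {
        ds <- assemble_datasets(
          ens, w, n_datasets = config$n_datasets,
          trials_per_dataset = config$trials_per_dataset,
          seed = derive_seed(config$seed, 4L, s, ei, match(w, config$whiskers)))
        for (m in seq_along(ds)) {
          fit <- anneal_search(
            ds[[m]], lags = seq_len(config$max_lag),
            max_parents = config$max_parents,
            iterations = config$anneal$iterations,
            restarts = config$anneal$restarts,
            t0 = config$anneal$t0, cooling = config$anneal$cooling,
            ess = config$ess,
            seed = derive_seed(config$seed, 5L, s, ei,
                               match(w, config$whiskers), m))
          subj_adj[[length(subj_adj) + 1]] <- collapse_lags(fit)
          subj_meta[[length(subj_meta) + 1]] <- data.frame(
            subject = s, session = sess, whisker = w, dataset = m)
        }
      }
      note(sprintf("infer subject %d %s", s, sess), proc.time()[3] - t0)
      rm(ens)
    }

    t0 <- proc.time()[3]
    meta <- do.call(rbind, subj_meta)
    space <- build_feature_space(subj_adj, meta, p = config$n_components)
    rep <- similarity_report(space)
    rep$subject <- s
    sim_rows[[length(sim_rows) + 1]] <- rep
    norm_const <- attr(rep, "norm_const")
    for (sess in sessions) {
      dd <- dataset_distances(space, config$paired[1], config$paired[2],
                              session = sess)
      samp_rows[[length(samp_rows) + 1]] <- data.frame(
        subject = s, session = sess, dataset = dd$dataset,
        similarity = if (norm_const > 0) 1 - dd$distance / norm_const
                     else rep(1, nrow(dd)))
    }
    conv_rows[[length(conv_rows) + 1]] <- data.frame(
      meta, value = presynaptic_convergence(subj_adj))
    proj_rows[[length(proj_rows) + 1]] <- data.frame(
      meta, q1 = space$scores[, 1],
      q2 = if (config$n_components >= 2) space$scores[, 2] else 0)
    note(sprintf("analyze subject %d", s), proc.time()[3] - t0)
  }

  similarity <- do.call(rbind, sim_rows)
  samples <- do.call(rbind, samp_rows)
  convergence <- do.call(rbind, conv_rows)
  response <- do.call(rbind, resp_rows)
  projections <- do.call(rbind, proj_rows)

  paired_sel <- similarity$w1 %in% config$paired &
    similarity$w2 %in% config$paired
  similarity_summary <- do.call(rbind, lapply(sessions, function(sess) {
    x <- similarity$similarity[paired_sel & similarity$session == sess]
    data.frame(session = sess, mean = mean(x), sd = sd(x), n = length(x))
  }))
  convergence_summary <- do.call(rbind, lapply(sessions, function(sess) {
    x <- convergence$value[convergence$session == sess]
    data.frame(session = sess, mean = mean(x), sd = sd(x), n = length(x))
  }))
  response_summary_tbl <- do.call(rbind, lapply(sessions, function(sess) {
    do.call(rbind, lapply(c("evoked_count", "latency"), function(metric) {
      x <- response$similarity[response$session == sess &
                                 response$metric == metric]
      data.frame(session = sess, metric = metric, mean = mean(x),
                 sd = sd(x), n = length(x))
    }))
  }))

  metric_samples <- function(metric, sess) {
    switch(metric,
      network_similarity = samples$similarity[samples$session == sess],
      convergence = convergence$value[convergence$session == sess],
      evoked_count_similarity =
        response$similarity[response$session == sess &
                              response$metric == "evoked_count"],
      latency_similarity =
        response$similarity[response$session == sess &
                              response$metric == "latency"])
  }
  tests <- list()
  for (metric in c("network_similarity", "convergence",
                   "evoked_count_similarity", "latency_similarity"))
    for (k in seq_along(sessions)) for (l in seq_along(sessions))
      if (k < l) {
        ct <- compare_sessions(metric_samples(metric, sessions[k]),
                               metric_samples(metric, sessions[l]))
        tests[[length(tests) + 1]] <- data.frame(
          metric = metric,
          comparison = paste0(sessions[k], "_vs_", sessions[l]),
          t = ct$t, p = ct$p, mean_a = ct$mean_a, mean_b = ct$mean_b)
      }
  tests <- do.call(rbind, tests)

  result <- structure(list(
    config = config, config_hash = hash,
    similarity = similarity, similarity_summary = similarity_summary,
    similarity_samples = samples,
    convergence = convergence, convergence_summary = convergence_summary,
    response = response, response_summary = response_summary_tbl,
    tests = tests, projections = projections,
    ground_truth = do.call(rbind, truth_rows),
    log = log), class = "experiment_result")

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$config$n_subjects, "subjects,",
      length(x$config$pairing_strengths), "sessions, hash", x$config_hash,
      "\n\nPaired-whisker network similarity:\n")
  print(x$similarity_summary, row.names = FALSE)
  cat("\nPre-synaptic convergence (normalized in-degree):\n")
  print(x$convergence_summary, row.names = FALSE)
  invisible(x)
}

## Write every result table; file set is stable across configurations.
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(result$similarity, "similarity_report.csv")
  w(result$similarity_summary, "similarity_summary.csv")
  w(result$similarity_samples, "similarity_samples.csv")
  w(result$convergence, "convergence.csv")
  w(result$convergence_summary, "convergence_summary.csv")
  w(result$response, "response_similarity.csv")
  w(result$response_summary, "response_summary.csv")
  w(result$tests, "session_tests.csv")
  w(result$projections, "projections.csv")
  w(result$ground_truth, "ground_truth.csv")
  yaml::write_yaml(c(unclass(result$config),
                     list(config_hash = result$config_hash)),
                   file.path(out_dir, "config.yaml"))
  con <- file(file.path(out_dir, "run_log.jsonl"), "w")
  for (entry in result$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  close(con)
  invisible(out_dir)
}

#' Load a recording from plain-text files
#'
#' Reads the `spikes.csv` / `trials.csv` / `meta.yaml` schema written by
#' [write_ensemble()]; real recordings in the same format are
#' interchangeable with synthetic output.  Trials whose onset leaves no full
#' baseline window are excluded with a warning; spikes of units absent from
#' the meta table are rejected with their line numbers.
#'
#' @param spikes_file CSV with columns `unit_id`, `time_ms`, `site_id`.
#' @param trials_file CSV with columns `whisker`, `onset_ms`.
#' @param meta_file YAML with `bin_ms`, `trial_window`, `baseline_window`,
#'   `n_bins`, `unit_ids`, `site_ids`.
#' @return a [trial_ensemble()].
#' @export
load_recording <- function(spikes_file, trials_file, meta_file) {
  meta <- yaml::read_yaml(meta_file)
  need <- c("bin_ms", "trial_window", "baseline_window", "n_bins",
            "unit_ids", "site_ids")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("meta file lacks field(s): ", paste(miss, collapse = ", "))
  spikes <- read.csv(spikes_file)
  if (!all(c("unit_id", "time_ms", "site_id") %in% names(spikes)))
    stop("spikes file must have columns unit_id, time_ms, site_id")
  trials <- read.csv(trials_file)
  if (!all(c("whisker", "onset_ms") %in% names(trials)))
    stop("trials file must have columns whisker, onset_ms")

  unit_ids <- meta$unit_ids
  bad <- which(!(spikes$unit_id %in% unit_ids))
  if (length(bad))
    stop("unknown unit id(s) in spikes file at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (ids: ", paste(unique(spikes$unit_id[bad]), collapse = ", "), ")")

  n <- length(unit_ids)
  raster <- matrix(0L, n, meta$n_bins)
  bins <- floor(spikes$time_ms / meta$bin_ms) + 1L
  if (any(bins < 1 | bins > meta$n_bins))
    stop("spike time(s) outside the recording at line(s) ",
         paste(utils::head(which(bins < 1 | bins > meta$n_bins) + 1L, 10),
               collapse = ", "))
  raster[cbind(match(spikes$unit_id, unit_ids), bins)] <- 1L

  onset_bins <- as.integer(round(trials$onset_ms / meta$bin_ms)) + 1L
  ok <- onset_bins - meta$baseline_window >= 1 &
    onset_bins + meta$trial_window - 1 <= meta$n_bins
  if (any(!ok))
    warning(sum(!ok), " trial(s) without a full baseline or trial window ",
            "excluded (rows ",
            paste(utils::head(which(!ok), 10), collapse = ", "), ")")
  trial_ensemble(raster, onset_bins[ok], trials$whisker[ok],
                 trial_window = meta$trial_window,
                 baseline_window = meta$baseline_window,
                 bin_ms = meta$bin_ms,
                 unit_ids = unit_ids, site_ids = meta$site_ids)
}
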