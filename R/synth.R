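#' Generate a ground-truth effective-connectivity network
#'
#' Draws a directed network with a fixed edge count, per-edge synaptic delays
#' and signed coupling weights, emulating the circuit properties a
#' spike-train connectivity analysis assumes: sparse connectivity (default
#' 10% of ordered pairs), delays of 1--5 ms, and a configurable
#' excitation/inhibition split.  Neurons are assigned to barrels (one barrel
#' per stimulated whisker), evenly unless the number of neurons does not
#' divide.
#'
#' Weights are per-bin spike-probability increments delivered to the target
#' when the source spiked `delay` bins earlier (see [simulate_session()]).
#'
#' @param n_neurons number of neurons (>= 2).
#' @param connectivity_ratio fraction of the `n_neurons * (n_neurons - 1)`
#'   ordered pairs that carry an edge; the realized edge count is
#'   `round(connectivity_ratio * n_neurons * (n_neurons - 1))`.
#' @param delay_range integer vector of admissible delays in bins (subset of
#'   1:5).
#' @param inhibitory_fraction probability that an edge is inhibitory.
#' @param weight_range range of coupling magnitudes (per-bin probability).
#' @param background_rate background firing rate, spikes/s (recycled across
#'   neurons).
#' @param barrels character vector of barrel labels; neurons are split evenly
#'   across them.
#' @param allow_self allow self-edges at lag >= 1 (default off).
#' @param max_parents optional cap on expected in-degree used for validation:
#'   generation is rejected when `connectivity_ratio * (n_neurons - 1)`
#'   exceeds it.
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @return an object of class `ground_truth_network`: a list with
#'   `n_neurons`, `edges` (data frame `pre`, `post`, `delay`, `weight`,
#'   `sign`), `barrel` (label per neuron), `background_rate`, and the
#'   generation parameters in `$params`.
#' @examples
#' net <- generate_network(10, connectivity_ratio = 0.1, seed = 1)
#' nrow(net$edges)  # round(0.1 * 10 * 9) = 9
#' @export
generate_network <- function(n_neurons,
                             connectivity_ratio = 0.1,
                             delay_range = 1:5,
                             inhibitory_fraction = 0.2,
                             weight_range = c(0.08, 0.25),
                             background_rate = 5,
                             barrels = "A",
                             allow_self = FALSE,
                             max_parents = NULL,
                             seed = 1) {
  stopifnot(n_neurons >= 2, connectivity_ratio >= 0, connectivity_ratio <= 1)
  if (!all(delay_range %in% 1:5))
    stop("delay_range must be a subset of 1:5 (1-ms bins)")
  if (!is.null(max_parents) &&
      connectivity_ratio * (n_neurons - 1) > max_parents)
    stop(sprintf(paste0(
      "connectivity_ratio %.3f implies an expected in-degree of %.2f, ",
      "exceeding max_parents = %d"),
      connectivity_ratio, connectivity_ratio * (n_neurons - 1),
      as.integer(max_parents)))

  n_edges <- round(connectivity_ratio * n_neurons * (n_neurons - 1))
  cand <- expand.grid(pre = seq_len(n_neurons), post = seq_len(n_neurons))
  if (!allow_self) cand <- cand[cand$pre != cand$post, , drop = FALSE]

  edges <- withr::with_seed(seed, {
    take <- sample(nrow(cand), n_edges)
    data.frame(
      pre = cand$pre[take],
      post = cand$post[take],
      delay = sample(delay_range, n_edges, replace = TRUE),
      weight = runif(n_edges, weight_range[1], weight_range[2]),
      sign = ifelse(runif(n_edges) < inhibitory_fraction,
                    "inhibitory", "excitatory"),
      stringsAsFactors = FALSE
    )
  })
  edges <- edges[order(edges$pre, edges$post), , drop = FALSE]
  rownames(edges) <- NULL

  nb <- length(barrels)
  sizes <- rep(n_neurons %/% nb, nb)
  if (n_neurons %% nb) sizes[seq_len(n_neurons %% nb)] <-
      sizes[seq_len(n_neurons %% nb)] + 1
  structure(list(
    n_neurons = n_neurons,
    edges = edges,
    barrel = rep(barrels, times = sizes),
    background_rate = rep_len(background_rate, n_neurons),
    input_overlap = NULL,
    params = list(connectivity_ratio = connectivity_ratio,
                  delay_range = delay_range,
                  inhibitory_fraction = inhibitory_fraction,
                  weight_range = weight_range,
                  allow_self = allow_self,
                  seed = seed)
  ), class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("<ground_truth_network>", x$n_neurons, "neurons,",
      nrow(x$edges), "edges,",
      length(unique(x$barrel)), "barrel(s)\n")
  invisible(x)
}

#' Stimulus protocol for a recording session
#'
#' One block of trials per whisker: each whisker is deflected
#' `trials_per_whisker` times for `trial_window` ms at an inter-trial
#' interval of `inter_trial_interval` ms (defaults: 900 deflections of
#' 100 ms at 1 Hz).  The evoked-rate profile within a trial rises linearly
#' to `peak_gain` at `peak_latency` ms and decays exponentially with time
#' constant `decay_tau` ms; the gain adds to the per-bin spike probability
#' of neurons in the stimulated whisker's barrel.
#'
#' @param whiskers character vector of whisker labels (must match barrel
#'   labels of the simulated network).
#' @param trials_per_whisker deflections per whisker.
#' @param trial_window deflection duration, ms.
#' @param baseline_window pre-stimulus window required before every trial, ms.
#' @param inter_trial_interval ms between trial offset and the next onset.
#' @param peak_gain peak added spike probability per 1-ms bin.
#' @param peak_latency ms from onset to peak gain.
#' @param decay_tau exponential decay constant of the gain, ms.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(whiskers = c("D4", "D5", "D6"),
                              trials_per_whisker = 900,
                              trial_window = 100,
                              baseline_window = 100,
                              inter_trial_interval = 900,
                              peak_gain = 0.08,
                              peak_latency = 8,
                              decay_tau = 25) {
  stopifnot(trials_per_whisker >= 1, trial_window >= 1, baseline_window >= 0)
  if (baseline_window > inter_trial_interval)
    stop("baseline_window must not exceed inter_trial_interval: ",
         "consecutive trial windows would overlap their baselines")
  structure(list(whiskers = whiskers,
                 trials_per_whisker = trials_per_whisker,
                 trial_window = trial_window,
                 baseline_window = baseline_window,
                 inter_trial_interval = inter_trial_interval,
                 peak_gain = peak_gain,
                 peak_latency = peak_latency,
                 decay_tau = decay_tau),
            class = "stimulus_protocol")
}

## Evoked-gain profile over the trial window (per-bin probability increment).
rate_profile <- function(protocol) {
  tau <- seq_len(protocol$trial_window) - 1
  ifelse(tau < protocol$peak_latency,
         protocol$peak_gain * tau / protocol$peak_latency,
         protocol$peak_gain *
           exp(-(tau - protocol$peak_latency) / protocol$decay_tau))
}

#' Construct a trial-aligned binned spike ensemble
#'
#' Low-level constructor used by [simulate_session()] and
#' [load_recording()], and handy for building small ensembles by hand in
#' tests.  `raster` entries are 0/1; `r[i, t] == 1` means neuron `i` spiked
#' in 1-ms bin `t`.
#'
#' @param raster binary matrix, neurons x bins.
#' @param trial_onsets 1-based onset bin per trial.
#' @param whisker_of_trial whisker label per trial.
#' @param trial_window,baseline_window window lengths in ms (= bins).
#' @param bin_ms bin width (only 1 ms is used by the analysis).
#' @param unit_ids,site_ids unit labels and electrode-site ids per neuron.
#' @return object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(raster, trial_onsets, whisker_of_trial,
                           trial_window = 100, baseline_window = 100,
                           bin_ms = 1, unit_ids = NULL, site_ids = NULL) {
  raster <- as.matrix(raster)
  if (!all(raster %in% c(0L, 1L))) stop("raster entries must be 0 or 1")
  storage.mode(raster) <- "integer"
  if (length(trial_onsets) != length(whisker_of_trial))
    stop("trial_onsets and whisker_of_trial lengths differ")
  if (any(trial_onsets - baseline_window < 1))
    stop("every trial needs a full baseline_window inside the recording")
  if (any(trial_onsets + trial_window - 1 > ncol(raster)))
    stop("trial windows extend past the end of the raster")
  n <- nrow(raster)
  structure(list(raster = raster,
                 trial_onsets = as.integer(trial_onsets),
                 whisker_of_trial = as.character(whisker_of_trial),
                 trial_window = trial_window,
                 baseline_window = baseline_window,
                 bin_ms = bin_ms,
                 unit_ids = unit_ids %||% seq_len(n),
                 site_ids = site_ids %||% (((seq_len(n) - 1) %% 32) + 1)),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat("<trial_ensemble>", nrow(x$raster), "neurons x", ncol(x$raster),
      "bins;", length(x$trial_onsets), "trials over",
      length(unique(x$whisker_of_trial)), "whisker(s)\n")
  invisible(x)
}

#' Simulate one recording session
#'
#' Runs the inhomogeneous Bernoulli spiking model: in every 1-ms bin each
#' neuron spikes with probability
#' `clip(p_background + stimulus gain + sum of coupling terms, 0, 1)`,
#' where the coupling term of an edge contributes its signed weight whenever
#' the source neuron spiked `delay` bins earlier.  Whiskers are deflected in
#' blocks according to `protocol`; a neuron receives the evoked gain when the
#' deflected whisker maps to its barrel (or partially, under a
#' `correlate_inputs` pairing, see [apply_pairing()]).
#'
#' A warning reports the number of bins whose pre-clip probability exceeded
#' 1; the counts are kept in `attr(, "n_clipped_high")` / `"n_clipped_low"`.
#'
#' @param network a `ground_truth_network` whose barrel labels include every
#'   protocol whisker.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed; the raster is bit-reproducible given
#'   `(network, protocol, seed)`.
#' @return a [trial_ensemble()].
#' @export
simulate_session <- function(network, protocol, seed = 1) {
  stopifnot(inherits(network, "ground_truth_network"),
            inherits(protocol, "stimulus_protocol"))
  if (!all(protocol$whiskers %in% network$barrel))
    stop("protocol whiskers not present among network barrels: ",
         paste(setdiff(protocol$whiskers, network$barrel), collapse = ", "))

  n <- network$n_neurons
  W <- protocol$trial_window
  period <- W + protocol$inter_trial_interval
  K <- length(protocol$whiskers)
  ntr <- protocol$trials_per_whisker
  T_total <- protocol$baseline_window + K * ntr * period

  block <- rep(seq_len(K) - 1L, each = ntr)
  within <- rep(seq_len(ntr) - 1L, times = K)
  onset0 <- protocol$baseline_window + (block * ntr + within) * period
  whisker_of_trial <- rep(protocol$whiskers, each = ntr)

  barrel_levels <- unique(network$barrel)
  gain_nb <- matrix(0, n, length(barrel_levels))
  gain_nb[cbind(seq_len(n), match(network$barrel, barrel_levels))] <- 1
  ov <- network$input_overlap
  if (!is.null(ov))
    for (r in seq_len(nrow(ov))) {
      resp <- which(network$barrel == ov$responding_barrel[r])
      gain_nb[resp, match(ov$stimulated_barrel[r], barrel_levels)] <-
        pmax(gain_nb[resp, match(ov$stimulated_barrel[r], barrel_levels)],
             ov$gain_fraction[r])
    }
  trial_barrel <- match(whisker_of_trial, barrel_levels)

  e <- network$edges
  w_signed <- e$weight * ifelse(e$sign == "inhibitory", -1, 1)
  p_bg <- network$background_rate / 1000  # spikes/s -> probability per 1-ms bin

  sim <- withr::with_seed(seed,
    simulate_engine(n, T_total,
                    as.integer(e$pre) - 1L, as.integer(e$post) - 1L,
                    as.integer(e$delay), as.numeric(w_signed),
                    as.numeric(p_bg), gain_nb,
                    as.integer(onset0), as.integer(trial_barrel),
                    as.integer(W), rate_profile(protocol)))
  if (sim$n_clipped_high > 0)
    warning(sprintf(
      "per-bin spike probability exceeded 1 before clipping in %d bin(s)",
      as.integer(sim$n_clipped_high)))

  ens <- trial_ensemble(sim$raster, onset0 + 1L, whisker_of_trial,
                        trial_window = W,
                        baseline_window = protocol$baseline_window,
                        bin_ms = 1)
  attr(ens, "n_clipped_high") <- sim$n_clipped_high
  attr(ens, "n_clipped_low") <- sim$n_clipped_low
  attr(ens, "seed") <- seed
  ens
}

#' Describe a whisker-pairing manipulation
#'
#' @param paired_barrels character vector of the two paired barrel labels.
#' @param strength effect strength in \[0, 1\]; 0 reproduces the control
#'   network exactly.
#' @param mode `"strengthen_cross_edges"` scales the weights of existing
#'   edges between the paired barrels by `1 + strength * boost`;
#'   `"add_cross_edges"` adds a `strength` fraction of the candidate
#'   cross-barrel edges (monotone in `strength` for a fixed seed);
#'   `"correlate_inputs"` makes neurons of each paired barrel respond to the
#'   other paired whisker with a `strength` fraction of the evoked gain.
#' @param convergence_modifier signed fraction applied to the edge count:
#'   positive adds that fraction of new random edges, negative removes that
#'   fraction of existing non-cross-barrel edges (cross-barrel edges between
#'   the paired barrels are never removed, keeping the pairing effect
#'   monotone).
#' @param boost weight-scaling coefficient for `strengthen_cross_edges`.
#' @param new_edge_weight weight of edges added by `add_cross_edges`
#'   (default: midpoint of the network's weight range).
#' @return object of class `pairing_effect`.
#' @export
pairing_effect <- function(paired_barrels, strength,
                           mode = c("strengthen_cross_edges",
                                    "add_cross_edges",
                                    "correlate_inputs"),
                           convergence_modifier = 0,
                           boost = 1.25,
                           new_edge_weight = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(paired_barrels) == 2, strength >= 0, strength <= 1)
  structure(list(paired_barrels = paired_barrels, strength = strength,
                 mode = mode, convergence_modifier = convergence_modifier,
                 boost = boost, new_edge_weight = new_edge_weight),
            class = "pairing_effect")
}

#' Apply a pairing manipulation to a ground-truth network
#'
#' Returns a modified copy of `network` emulating experience-dependent
#' plasticity between two paired barrels; `strength = 0` returns the control
#' network unchanged, edge for edge.  For `add_cross_edges`, the candidate
#' cross-barrel edges included at a smaller strength are a subset of those
#' included at a larger strength under the same seed.
#'
#' @param network a `ground_truth_network`.
#' @param effect a [pairing_effect()].
#' @param seed integer seed controlling which candidate edges are touched.
#' @return a modified `ground_truth_network`.
#' @export
apply_pairing <- function(network, effect, seed = 1) {
  stopifnot(inherits(network, "ground_truth_network"),
            inherits(effect, "pairing_effect"))
  pb <- effect$paired_barrels
  if (!all(pb %in% network$barrel))
    stop("unknown barrel label(s): ",
         paste(setdiff(pb, network$barrel), collapse = ", "))
  if (effect$strength == 0 && effect$convergence_modifier == 0)
    return(network)

  net <- network
  b <- net$barrel
  is_cross <- function(e)
    b[e$pre] %in% pb & b[e$post] %in% pb & b[e$pre] != b[e$post]

  withr::with_seed(seed, {
    if (effect$strength > 0) {
      if (effect$mode == "strengthen_cross_edges") {
        cx <- is_cross(net$edges)
        net$edges$weight[cx] <- pmin(
          net$edges$weight[cx] * (1 + effect$strength * effect$boost), 0.95)
      } else if (effect$mode == "add_cross_edges") {
        i1 <- which(b == pb[1]); i2 <- which(b == pb[2])
        cand <- rbind(expand.grid(pre = i1, post = i2),
                      expand.grid(pre = i2, post = i1))
        cand <- cand[order(cand$pre, cand$post), , drop = FALSE]
        have <- paste(net$edges$pre, net$edges$post)
        cand <- cand[!(paste(cand$pre, cand$post) %in% have), , drop = FALSE]
        u <- runif(nrow(cand))              # one draw per candidate, in
        take <- which(u <= effect$strength) # canonical order -> monotone sets
        if (length(take)) {
          wr <- net$params$weight_range %||% c(0.08, 0.25)
          add <- data.frame(
            pre = cand$pre[take], post = cand$post[take],
            delay = sample(net$params$delay_range %||% 1:5,
                           length(take), replace = TRUE),
            weight = rep_len(effect$new_edge_weight %||% mean(wr),
                             length(take)),
            sign = "excitatory", stringsAsFactors = FALSE)
          net$edges <- rbind(net$edges, add)
        }
      } else { # correlate_inputs
        net$input_overlap <- data.frame(
          stimulated_barrel = pb, responding_barrel = rev(pb),
          gain_fraction = effect$strength, stringsAsFactors = FALSE)
      }
    }

    cm <- effect$convergence_modifier
    if (cm != 0) {
      k <- round(abs(cm) * nrow(net$edges))
      if (cm > 0 && k > 0) {
        # New parents emulate potentiation of co-active inputs: candidates
        # are cross-barrel pairs between the paired barrels first, then
        # pairs within them, then anywhere.
        all_pairs <- expand.grid(pre = seq_len(net$n_neurons),
                                 post = seq_len(net$n_neurons))
        all_pairs <- all_pairs[all_pairs$pre != all_pairs$post, , drop = FALSE]
        have <- paste(net$edges$pre, net$edges$post)
        free <- all_pairs[!(paste(all_pairs$pre, all_pairs$post) %in% have), ,
                          drop = FALSE]
        in_paired <- b[free$pre] %in% pb & b[free$post] %in% pb
        tier <- ifelse(in_paired & b[free$pre] != b[free$post], 1L,
                       ifelse(in_paired, 2L, 3L))
        k <- min(k, nrow(free))
        take <- unlist(lapply(1:3, function(tr) {
          pool <- which(tier == tr)
          pool[sample.int(length(pool), min(length(pool), k))]
        }))[seq_len(k)]
        wr <- net$params$weight_range %||% c(0.08, 0.25)
        add <- data.frame(
          pre = free$pre[take], post = free$post[take],
          delay = sample(net$params$delay_range %||% 1:5, k, replace = TRUE),
          weight = runif(k, wr[1], wr[2]),
          sign = "excitatory",
          stringsAsFactors = FALSE)
        net$edges <- rbind(net$edges, add)
      } else if (cm < 0 && k > 0) {
        removable <- which(!is_cross(net$edges))
        k <- min(k, length(removable))
        drop <- sample(removable, k)
        net$edges <- net$edges[-drop, , drop = FALSE]
      }
    }
  })
  net$edges <- net$edges[order(net$edges$pre, net$edges$post), , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Write an ensemble to plain-text files
#'
#' Writes `spikes.csv` (`unit_id`, `time_ms`, `site_id`), `trials.csv`
#' (`whisker`, `onset_ms`) and `meta.yaml` (bin width, windows, unit/site
#' table) under `dir`.  [load_recording()] reads the same schema, so
#' synthetic output and real recordings are interchangeable.
#'
#' @param ensemble a [trial_ensemble()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- which(ensemble$raster == 1L, arr.ind = TRUE)
  spikes <- data.frame(
    unit_id = ensemble$unit_ids[sp[, 1]],
    time_ms = (sp[, 2] - 1) * ensemble$bin_ms,
    site_id = ensemble$site_ids[sp[, 1]])
  spikes <- spikes[order(spikes$time_ms, spikes$unit_id), , drop = FALSE]
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  write.csv(data.frame(whisker = ensemble$whisker_of_trial,
                       onset_ms = (ensemble$trial_onsets - 1) *
                         ensemble$bin_ms),
            file.path(dir, "trials.csv"), row.names = FALSE)
  yaml::write_yaml(list(bin_ms = ensemble$bin_ms,
                        trial_window = ensemble$trial_window,
                        baseline_window = ensemble$baseline_window,
                        n_bins = ncol(ensemble$raster),
                        unit_ids = as.integer(ensemble$unit_ids),
                        site_ids = as.integer(ensemble$site_ids),
                        seed = attr(ensemble, "seed")),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Write a ground-truth network as an edge list and GraphML
#'
#' @param network a `ground_truth_network`.
#' @param edges_csv path of the edge-list CSV (`pre`, `post`, `delay_bins`,
#'   `weight`, `sign`).
#' @param graphml optional path of a GraphML export (vertex attribute
#'   `barrel`, edge attributes `delay_bins`, `weight`, `sign`).
#' @return `edges_csv`, invisibly.
#' @export
write_network <- function(network, edges_csv, graphml = NULL) {
  stopifnot(inherits(network, "ground_truth_network"))
  e <- network$edges
  write.csv(data.frame(pre = e$pre, post = e$post, delay_bins = e$delay,
                       weight = e$weight, sign = e$sign),
            edges_csv, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$pre, to = e$post, delay_bins = e$delay,
                 weight = e$weight, sign = e$sign),
      directed = TRUE,
      vertices = data.frame(name = seq_len(network$n_neurons),
                            barrel = network$barrel))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(edges_csv)
}
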