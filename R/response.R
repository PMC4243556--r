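#' Assemble analysis datasets for one whisker
#'
#' Builds `n_datasets` datasets, each the concatenation of the post-onset
#' trial windows of `trials_per_dataset` trials sampled uniformly without
#' replacement from the whisker's trials (independently across datasets).
#' With the defaults of 180 trials of 100 ms this yields 18-s (18,000-bin)
#' datasets, 100 of them per whisker.
#'
#' @param ensemble a [trial_ensemble()].
#' @param whisker whisker label to extract.
#' @param n_datasets number of datasets.
#' @param trials_per_dataset trials concatenated into each dataset.
#' @param seed integer seed; the same seed reproduces the trial selections.
#' @return list of `analysis_dataset` objects (fields `raster`, `trials`,
#'   `whisker`, `id`).
#' @export
assemble_datasets <- function(ensemble, whisker, n_datasets = 100,
                              trials_per_dataset = 180, seed = 1) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  idx <- which(ensemble$whisker_of_trial == whisker)
  if (length(idx) < trials_per_dataset)
    stop(sprintf(
      "whisker '%s' has %d trials; %d are needed per dataset",
      whisker, length(idx), as.integer(trials_per_dataset)))
  W <- ensemble$trial_window
  withr::with_seed(seed, lapply(seq_len(n_datasets), function(m) {
    take <- sample(idx, trials_per_dataset)   # without replacement
    cols <- as.vector(vapply(ensemble$trial_onsets[take],
                             function(o) o:(o + W - 1L),
                             integer(W)))
    structure(list(raster = ensemble$raster[, cols, drop = FALSE],
                   trials = take, whisker = whisker, id = m),
              class = "analysis_dataset")
  }))
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("<analysis_dataset>", x$id, "whisker", x$whisker, ":",
      nrow(x$raster), "neurons x", ncol(x$raster), "bins (",
      length(x$trials), "trials )\n")
  invisible(x)
}

trial_window_of <- function(ensemble, trial) {
  o <- ensemble$trial_onsets[trial]
  list(win = o:(o + ensemble$trial_window - 1L),
       base = (o - ensemble$baseline_window):(o - 1L))
}

#' Evoked spike count of one neuron in one trial
#'
#' Number of spikes in the 100-ms trial window minus the number in the
#' 100-ms window immediately preceding the onset.  Negative values are
#' retained (suppressed responses).  Windows are half-open:
#' `[onset, onset + window)` and `[onset - baseline, onset)`, with the onset
#' bin counted in the trial window.
#'
#' @param ensemble a [trial_ensemble()].
#' @param neuron neuron index.
#' @param trial trial index.
#' @return signed integer count.
#' @export
evoked_count <- function(ensemble, neuron, trial) {
  w <- trial_window_of(ensemble, trial)
  sum(ensemble$raster[neuron, w$win]) - sum(ensemble$raster[neuron, w$base])
}

#' First-spike latency of one neuron in one trial
#'
#' Time (ms) from stimulus onset to the neuron's first spike within the
#' trial window; a spike in the onset bin has latency 0.  `NA` when the
#' neuron does not spike in the window (such trials are excluded from
#' latency means).
#'
#' @inheritParams evoked_count
#' @return latency in ms, or `NA`.
#' @export
first_spike_latency <- function(ensemble, neuron, trial) {
  w <- trial_window_of(ensemble, trial)
  hit <- which(ensemble$raster[neuron, w$win] == 1L)
  if (!length(hit)) return(NA_real_)
  (hit[1] - 1) * ensemble$bin_ms
}

#' Per-neuron, per-whisker response summary
#'
#' Mean evoked count and mean first-spike latency of every neuron for every
#' whisker, plus the number of trials contributing a spike (latency means
#' exclude spike-free trials).
#'
#' @param ensemble a [trial_ensemble()].
#' @return data frame with columns `neuron`, `whisker`, `evoked_mean`,
#'   `latency_mean`, `n_trials_with_spike`, `n_trials`.
#' @export
response_summary <- function(ensemble) {
  n <- nrow(ensemble$raster)
  W <- ensemble$trial_window
  B <- ensemble$baseline_window
  onsets <- ensemble$trial_onsets
  ntr <- length(onsets)

  win_counts <- matrix(0L, n, ntr)
  base_counts <- matrix(0L, n, ntr)
  first_lat <- matrix(NA_real_, n, ntr)
  for (tr in seq_len(ntr)) {
    seg <- ensemble$raster[, onsets[tr]:(onsets[tr] + W - 1L), drop = FALSE]
    win_counts[, tr] <- rowSums(seg)
    base_counts[, tr] <-
      rowSums(ensemble$raster[, (onsets[tr] - B):(onsets[tr] - 1L),
                              drop = FALSE])
    fired <- which(win_counts[, tr] > 0L)
    if (length(fired))
      first_lat[fired, tr] <-
        (max.col(seg[fired, , drop = FALSE] == 1L, ties.method = "first") -
           1) * ensemble$bin_ms
  }
  ev <- win_counts - base_counts

  out <- do.call(rbind, lapply(unique(ensemble$whisker_of_trial), function(w) {
    tr <- ensemble$whisker_of_trial == w
    data.frame(
      neuron = seq_len(n),
      whisker = w,
      evoked_mean = rowMeans(ev[, tr, drop = FALSE]),
      latency_mean = rowMeans(first_lat[, tr, drop = FALSE], na.rm = TRUE),
      n_trials_with_spike = rowSums(!is.na(first_lat[, tr, drop = FALSE])),
      n_trials = sum(tr),
      stringsAsFactors = FALSE)
  }))
  out$latency_mean[is.nan(out$latency_mean)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Cross-whisker similarity of a per-neuron response metric
#'
#' For each neuron, `1 - |v_w1 - v_w2| / max_j |v_w1,j - v_w2,j|`: the
#' absolute cross-whisker difference normalized by the largest difference in
#' the population, subtracted from 1.  Values lie in \[0, 1\]; the neuron(s)
#' attaining the maximum difference score 0, and when every difference is 0
#' all neurons score 1.
#'
#' Neurons with an undefined metric (e.g. latency of a neuron that never
#' spiked) are dropped before normalization.
#'
#' @param values_w1,values_w2 per-neuron metric values, same neuron order.
#' @return data frame (`neuron`, `difference`, `similarity`) with the
#'   normalization constant in `attr(, "norm_const")`.
#' @export
neuron_similarity <- function(values_w1, values_w2) {
  if (length(values_w1) != length(values_w2))
    stop("metric vectors must cover the same neuron set")
  keep <- which(!is.na(values_w1) & !is.na(values_w2))
  if (!length(keep)) stop("no neuron has the metric defined for both whiskers")
  d <- abs(values_w1[keep] - values_w2[keep])
  mx <- max(d)
  sim <- if (mx == 0) rep(1, length(d)) else 1 - d / mx
  structure(data.frame(neuron = keep, difference = d, similarity = sim),
            norm_const = mx)
}
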