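## Independent oracles and small fixture builders used across the suite.

## Sequential-predictive (Polya-urn) log marginal likelihood of a 2 x K
## family counts table under a symmetric Dirichlet prior with equivalent
## sample size `ess`: processes pseudo-observations one at a time and never
## touches the Gamma function, so it is an independent check of the
## closed-form BDe score.
dirichlet_multinomial_logml <- function(counts, ess) {
  K <- ncol(counts)
  zp_jk <- ess / (2 * K)
  zp_k <- ess / K
  total <- 0
  for (k in seq_len(K)) {
    for (j in 1:2) {
      z <- counts[j, k]
      if (z > 0) total <- total + sum(log(zp_jk + seq_len(z) - 1))
    }
    zk <- sum(counts[, k])
    if (zk > 0) total <- total - sum(log(zp_k + seq_len(zk) - 1))
  }
  total
}

## Random small family counts table (np parents -> 2^np configurations).
random_counts_table <- function(np, max_count = 20) {
  K <- 2^np
  matrix(sample(0:max_count, 2 * K, replace = TRUE), nrow = 2)
}

## Hand-built ensemble: spike times given per neuron as bin lists.
make_ensemble <- function(spike_bins, n_bins, trial_onsets, whiskers,
                          trial_window = 10, baseline_window = 10) {
  raster <- matrix(0L, length(spike_bins), n_bins)
  for (i in seq_along(spike_bins))
    raster[i, spike_bins[[i]]] <- 1L
  trial_ensemble(raster, trial_onsets, whiskers,
                 trial_window = trial_window,
                 baseline_window = baseline_window)
}

## Empirical cross-correlogram: counts of pre spikes at (t_post - lag).
ccg_argmax <- function(raster, pre, post, lags = -8:8) {
  counts <- vapply(lags, function(d) {
    t_post <- which(raster[post, ] == 1L)
    t_pre <- t_post - d
    ok <- t_pre >= 1 & t_pre <= ncol(raster)
    sum(raster[pre, t_pre[ok]])
  }, numeric(1))
  lags[which.max(counts)]
}

## Small simulated instance for search tests: n neurons, some planted lagged
## edges, short recording driven by background rate alone.
random_instance <- function(n, n_bins, lags, n_edges, seed,
                            weight = c(0.25, 0.5), rate = 40) {
  withr::with_seed(seed, {
    net <- generate_network(n, 0, background_rate = rate, barrels = "A",
                            seed = seed)
    if (n_edges > 0) {
      pairs <- expand.grid(pre = 1:n, post = 1:n)
      pairs <- pairs[pairs$pre != pairs$post, ]
      take <- sample(nrow(pairs), n_edges)
      net$edges <- data.frame(
        pre = pairs$pre[take], post = pairs$post[take],
        delay = sample(lags, n_edges, replace = TRUE),
        weight = runif(n_edges, weight[1], weight[2]),
        sign = "excitatory", stringsAsFactors = FALSE)
    }
    pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 1,
                             trial_window = 10, baseline_window = 10,
                             inter_trial_interval = n_bins, peak_gain = 0)
    ens <- simulate_session(net, pro, seed = seed + 1)
    ens$raster[, seq_len(min(n_bins, ncol(ens$raster))), drop = FALSE]
  })
}
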