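#' Lagged directed network (DBN structure)
#'
#' A set of directed edges `(pre, post, lag)` with lags in `1:max_lag`;
#' intra-slice (lag-0) edges are excluded, so the unrolled graph is acyclic
#' for any parent assignment and the BDe score decomposes over children.
#'
#' @param n_neurons number of nodes.
#' @param edges data frame with columns `pre`, `post`, `lag` (may have zero
#'   rows).
#' @param max_lag largest admissible Markov lag (default 5 bins).
#' @param max_parents cap on incoming `(pre, lag)` entries per child
#'   (default 10).
#' @return object of class `lagged_network`.
#' @export
lagged_network <- function(n_neurons, edges = NULL, max_lag = 5,
                           max_parents = 10) {
  if (is.null(edges))
    edges <- data.frame(pre = integer(), post = integer(), lag = integer())
  edges <- as.data.frame(edges)[, c("pre", "post", "lag")]
  stopifnot(all(edges$lag >= 1), all(edges$lag <= max_lag),
            all(edges$pre >= 1), all(edges$pre <= n_neurons),
            all(edges$post >= 1), all(edges$post <= n_neurons))
  if (anyDuplicated(edges[, c("pre", "post", "lag")]))
    stop("duplicate (pre, post, lag) edges")
  indeg <- table(edges$post)
  if (any(indeg > max_parents))
    stop("max_parents = ", max_parents, " exceeded for child(ren) ",
         paste(names(indeg)[indeg > max_parents], collapse = ", "))
  edges <- edges[order(edges$post, edges$pre, edges$lag), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_neurons = n_neurons, edges = edges, max_lag = max_lag,
                 max_parents = max_parents),
            class = "lagged_network")
}

#' @export
print.lagged_network <- function(x, ...) {
  cat("<lagged_network>", x$n_neurons, "neurons,", nrow(x$edges),
      "lagged edges (max lag", x$max_lag, ", max parents", x$max_parents,
      ")\n")
  invisible(x)
}

#' Family sufficient statistics for one child
#'
#' Counts `Z_jk`: the number of scored time bins in which the child is in
#' state `j` (0/1) while its lagged parents are in joint configuration `k`.
#' Bins run from `max(parent lags) + 1` to the end of the dataset, so every
#' lagged parent value lies inside the data; a dataset shorter than the
#' largest lag yields all-zero counts.  `k` indexes the binary tuple of
#' parent values in canonical parent order (sorted by `pre`, then `lag`).
#'
#' @param data an [analysis_dataset], [trial_ensemble] or binary matrix
#'   (neurons x bins).
#' @param child child neuron index.
#' @param parents data frame with columns `pre` and `lag` (or `NULL` for no
#'   parents); duplicate `(pre, lag)` entries are rejected.
#' @param exclude integer vector of bin indices never scored as child bins
#'   (e.g. [seam_mask()] bins after trial-concatenation seams).
#' @return object of class `family_statistics`: list with `counts`
#'   (2 x 2^np matrix, rows = child state 0/1), `n_parents`, `parents`,
#'   `child`, `t_effective`.
#' @export
family_statistics <- function(data, child, parents = NULL, exclude = NULL) {
  r <- as_raster(data)
  T_len <- ncol(r)
  if (is.null(parents) || !nrow(as.data.frame(parents))) {
    parents <- data.frame(pre = integer(), lag = integer())
  } else {
    parents <- as.data.frame(parents)[, c("pre", "lag")]
    if (anyDuplicated(parents)) stop("duplicate (parent, lag) entries")
    parents <- parents[order(parents$pre, parents$lag), , drop = FALSE]
  }
  np <- nrow(parents)
  lmax <- if (np) max(parents$lag) else 0L
  counts <- matrix(0, 2, 2^np,
                   dimnames = list(state = c("0", "1"), config = NULL))
  if (T_len > lmax) {
    ts <- (lmax + 1L):T_len
    if (!is.null(exclude)) ts <- setdiff(ts, as.integer(exclude))
    k <- integer(length(ts))
    for (m in seq_len(np))
      k <- k + bitwShiftL(r[parents$pre[m], ts - parents$lag[m]], m - 1L)
    j <- r[child, ts]
    tab <- tabulate(1L + 2L * k + j, nbins = 2L * 2L^np)
    counts[] <- matrix(tab, nrow = 2)
  }
  structure(list(counts = counts, n_parents = np, parents = parents,
                 child = child,
                 t_effective = if (T_len > lmax) length(ts) else 0L),
            class = "family_statistics")
}

#' Bins masked after trial-concatenation seams
#'
#' A dataset assembled by concatenating trial windows has seams at which the
#' lagged history of a bin belongs to a different trial.  By default the
#' analysis scores across seams (plain concatenation); this helper returns
#' the first `max_lag` bin indices after every seam so they can be excluded
#' (`exclude` of [family_statistics()], `mask_seams` of [anneal_search()]).
#'
#' @param n_bins total bins of the dataset.
#' @param segment_bins bins per concatenated segment (the trial window).
#' @param max_lag largest Markov lag considered.
#' @return integer vector of bin indices (1-based), possibly empty.
#' @export
seam_mask <- function(n_bins, segment_bins, max_lag = 5) {
  if (segment_bins + 1L > n_bins) return(integer(0))
  starts <- seq.int(segment_bins + 1L, n_bins, by = segment_bins)
  out <- as.vector(outer(0:(max_lag - 1L), starts, `+`))
  out[out <= n_bins]
}

#' BDe score of one family
#'
#' Log marginal likelihood of the child's conditional distribution under a
#' BDeu Dirichlet prior with equivalent sample size `ess` and a uniform
#' prior structure, so every pseudo-count is
#' `Z'_jk = ess / (2 * 2^n_parents)`.  Computed entirely in log-Gamma
#' arithmetic:
#' `sum_k [ lgamma(Z'_k) - lgamma(Z'_k + Z_k) +
#'          sum_j ( lgamma(Z'_jk + Z_jk) - lgamma(Z'_jk) ) ]`.
#' With no data the score is 0 (every Gamma ratio cancels).
#'
#' @param stats a [family_statistics()] object, or a bare 2 x K counts
#'   matrix (rows = child state).
#' @param ess equivalent sample size `a` (> 0).
#' @return log score (scalar).
#' @export
bde_family_score <- function(stats, ess = 1) {
  if (ess <= 0) stop("ess must be > 0 (all prior pseudo-counts positive)")
  counts <- if (inherits(stats, "family_statistics")) stats$counts
            else as.matrix(stats)
  K <- ncol(counts)
  zp_jk <- ess / (2 * K)
  zp_k <- ess / K
  zk <- colSums(counts)
  sum(lgamma(zp_k) - lgamma(zp_k + zk)) +
    sum(lgamma(zp_jk + counts) - lgamma(zp_jk))
}

## parent sets per child from a lagged_network
parent_sets <- function(network) {
  lapply(seq_len(network$n_neurons), function(j) {
    e <- network$edges[network$edges$post == j, , drop = FALSE]
    data.frame(pre = e$pre, lag = e$lag)
  })
}

#' Total BDe score of a structure
#'
#' Sum of [bde_family_score()] over all children; by decomposability, a
#' single-edge change alters only the affected child's family term.
#'
#' @param data raster-bearing object (see [as_raster()]).
#' @param network a [lagged_network()].
#' @param ess equivalent sample size.
#' @param exclude bins excluded from scoring (see [family_statistics()]).
#' @return object of class `scored_structure`: list with `network`,
#'   `log_score`, `family_scores` (one per child).
#' @export
total_score <- function(data, network, ess = 1, exclude = NULL) {
  r <- as_raster(data)
  fam <- vapply(seq_len(network$n_neurons), function(j) {
    ps <- network$edges[network$edges$post == j, c("pre", "lag"), drop = FALSE]
    bde_family_score(family_statistics(r, j, ps, exclude = exclude), ess)
  }, numeric(1))
  structure(list(network = network, log_score = sum(fam),
                 family_scores = fam),
            class = "scored_structure")
}

#' @export
print.scored_structure <- function(x, ...) {
  cat("<scored_structure> log score", format(x$log_score, digits = 10),
      "with", nrow(x$network$edges), "edges\n")
  invisible(x)
}

#' Simulated-annealing search for the best-scoring structure
#'
#' Stochastic search over lagged structures: each step proposes uniformly
#' among the legal moves -- adding an edge at one of the candidate lags,
#' deleting an existing edge, or reversing one (keeping its lag) -- and
#' accepts with probability `min(1, exp(delta/T))` under geometric cooling
#' `T <- T * cooling`.  The best structure ever visited is returned;
#' `max_parents` is never violated, and at most one lag is kept per ordered
#' neuron pair during the search (the largest-lag collapse of
#' [collapse_lags()] is therefore unambiguous).
#'
#' @param data raster-bearing object with more bins than `max(lags)`.
#' @param lags candidate Markov lags (default 1:5).
#' @param max_parents cap on parents per child (default 10).
#' @param iterations proposals per restart.
#' @param restarts independent restarts; the best structure across restarts
#'   is kept.
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor per proposal.
#' @param ess equivalent sample size of the BDeu prior.
#' @param init `"empty"` (default, reproducible) or `"random"`.
#' @param init_density edge probability for a random initial structure.
#' @param trace_every record the search trace every this many proposals
#'   (0 = off).
#' @param mask_seams for an [analysis_dataset], exclude the first
#'   `max(lags)` bins after every trial-concatenation seam from scoring
#'   (default `FALSE`: plain concatenation, lags cross seams).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return a `scored_structure`; the trace (if any) is in
#'   `attr(, "trace")` and the accepted-move count in
#'   `attr(, "n_accepted")`.
#' @export
anneal_search <- function(data, lags = 1:5, max_parents = 10,
                          iterations = 2e5, restarts = 3, t0 = 10,
                          cooling = 0.9999, ess = 1,
                          init = c("empty", "random"), init_density = 0.05,
                          trace_every = 0, mask_seams = FALSE, seed = 1) {
  init <- match.arg(init)
  r <- as_raster(data)
  if (ncol(r) <= max(lags))
    stop("data must have more bins than the largest lag")
  if (max_parents > 10)
    stop("max_parents above 10 is not supported by the search engine")
  mask <- integer(ncol(r))
  if (mask_seams) {
    if (!inherits(data, "analysis_dataset"))
      stop("mask_seams needs an analysis_dataset (known trial windows)")
    seg <- ncol(r) / length(data$trials)
    mask[seam_mask(ncol(r), seg, max(lags))] <- 1L
  }
  res <- withr::with_seed(seed,
    anneal_engine(t(r), as.integer(lags), as.integer(max_parents),
                  ess, t0, cooling, as.integer(iterations),
                  as.integer(restarts), init == "random", init_density,
                  as.integer(trace_every), mask))
  net <- lagged_network(nrow(r),
                        as.data.frame(res$edges),
                        max_lag = max(lags), max_parents = max_parents)
  out <- structure(list(network = net, log_score = res$log_score,
                        family_scores = NULL),
                   class = "scored_structure")
  attr(out, "n_accepted") <- res$n_accepted
  if (!is.null(res$trace)) attr(out, "trace") <- as.data.frame(res$trace)
  out
}

#' Exhaustive search over small structures
#'
#' Oracle for the annealing search: because only inter-slice edges exist,
#' families are independent and the global optimum is found by enumerating,
#' for each child, every assignment of at most one lag per candidate parent
#' (`(length(lags) + 1)^(n - 1)` combinations).  Restricted to `n <= 4` and
#' at most 1e5 combinations per child.
#'
#' @inheritParams anneal_search
#' @return a `scored_structure` holding the globally optimal network.
#' @export
exhaustive_search <- function(data, lags = 1:2, max_parents = 10, ess = 1) {
  r <- as_raster(data)
  n <- nrow(r)
  if (n > 4) stop("exhaustive search is limited to n <= 4 neurons")
  n_comb <- (length(lags) + 1)^(n - 1)
  if (n_comb > 1e5)
    stop("per-child enumeration too large: ", n_comb, " parent sets")
  opts <- c(0L, as.integer(lags))   # 0 = parent absent
  grid <- if (n == 1) matrix(integer(), 1, 0)
          else as.matrix(do.call(expand.grid, rep(list(opts), n - 1)))

  edges <- list(); fam_best <- numeric(n)
  for (child in seq_len(n)) {
    others <- setdiff(seq_len(n), child)
    best <- -Inf; best_ps <- NULL
    for (g in seq_len(nrow(grid))) {
      lag_of <- grid[g, ]
      act <- which(lag_of > 0L)
      if (length(act) > max_parents) next
      ps <- data.frame(pre = others[act], lag = lag_of[act])
      sc <- bde_family_score(family_statistics(r, child, ps), ess)
      if (sc > best + 1e-12) { best <- sc; best_ps <- ps }
    }
    fam_best[child] <- best
    if (nrow(best_ps))
      edges[[length(edges) + 1]] <-
        data.frame(pre = best_ps$pre, post = child, lag = best_ps$lag)
  }
  net <- lagged_network(
    n, if (length(edges)) do.call(rbind, edges) else NULL,
    max_lag = max(lags), max_parents = max_parents)
  structure(list(network = net, log_score = sum(fam_best),
                 family_scores = fam_best),
            class = "scored_structure")
}

#' Collapse Markov lags into a binary adjacency matrix
#'
#' `A[i, j] = 1` iff any lagged edge i -> j exists; when a pair is inferred
#' at several lags only the largest lag is retained as the annotation
#' (`attr(, "lags")`).  Self-edges are excluded from the adjacency by
#' default, matching the network feature space which reflects between-neuron
#' connectivity.
#'
#' @param network a [lagged_network()] or a `scored_structure`.
#' @param keep_self keep diagonal entries (default `FALSE`).
#' @return binary n x n matrix with the retained-lag matrix in
#'   `attr(, "lags")`.
#' @export
collapse_lags <- function(network, keep_self = FALSE) {
  if (inherits(network, "scored_structure")) network <- network$network
  stopifnot(inherits(network, "lagged_network"))
  n <- network$n_neurons
  A <- matrix(0L, n, n)
  L <- matrix(0L, n, n)
  e <- network$edges
  for (k in seq_len(nrow(e))) {
    i <- e$pre[k]; j <- e$post[k]
    if (!keep_self && i == j) next
    A[i, j] <- 1L
    L[i, j] <- max(L[i, j], e$lag[k])
  }
  attr(A, "lags") <- L
  A
}

#' Write a search trace as JSON lines
#'
#' @param structure a `scored_structure` produced by [anneal_search()] with
#'   `trace_every > 0`.
#' @param path output file; one JSON object per recorded step
#'   (`iteration`, `temperature`, `score`, `accepted`).
#' @return `path`, invisibly.
#' @export
write_search_trace <- function(structure, path) {
  tr <- attr(structure, "trace")
  if (is.null(tr)) stop("structure carries no trace; rerun with trace_every > 0")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tr)))
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}

#' Write a lagged network as GraphML and/or edge-list CSV
#'
#' @param network a [lagged_network()] or `scored_structure`.
#' @param edges_csv optional CSV path (`pre`, `post`, `lag`).
#' @param graphml optional GraphML path (edge attribute `lag`).
#' @return the network, invisibly.
#' @export
write_lagged_network <- function(network, edges_csv = NULL, graphml = NULL) {
  if (inherits(network, "scored_structure")) network <- network$network
  stopifnot(inherits(network, "lagged_network"))
  if (!is.null(edges_csv))
    write.csv(network$edges, edges_csv, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$edges$pre, to = network$edges$post,
                 lag = network$edges$lag),
      directed = TRUE,
      vertices = data.frame(name = seq_len(network$n_neurons)))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(network)
}
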