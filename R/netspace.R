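#' Build a PCA network feature space from adjacency matrices
#'
#' Vectorizes every binary adjacency matrix in a fixed row-major order
#' (excluding the diagonal, so the features reflect between-neuron
#' connectivity), stacks the vectors into a (number of networks) x
#' (n^2 - n) matrix, mean-centers the columns, and projects onto the top
#' `p` principal axes.  Distances between projections define the
#' network-similarity statistics ([network_distance()],
#' [average_pair_distance()], [similarity_report()]).
#'
#' @param adjacencies list of n x n binary matrices (identical n).
#' @param meta optional data frame of per-network labels (e.g. `whisker`,
#'   `session`, `dataset`, `subject`), one row per matrix.
#' @param p number of principal components (default 2).
#' @return object of class `network_feature_space`: list with `scores`
#'   (networks x p), `meta`, `rotation`, `center`, `sdev`,
#'   `var_explained`, `p`, `n`, `degenerate`.
#' @export
build_feature_space <- function(adjacencies, meta = NULL, p = 2) {
  if (length(adjacencies) < 2) stop("need at least 2 networks")
  n <- nrow(adjacencies[[1]])
  if (length(adjacencies) < p)
    stop("fewer networks (", length(adjacencies), ") than components (",
         p, ")")
  off <- which(t(diag(n) == 0))        # row-major off-diagonal positions
  X <- t(vapply(adjacencies, function(A) {
    stopifnot(nrow(A) == n, ncol(A) == n)
    as.numeric(t(A))[off]
  }, numeric(n * n - n)))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = p)
  tot <- sum(pc$sdev^2)
  degenerate <- tot < .Machine$double.eps
  scores <- pc$x
  if (ncol(scores) < p)   # fewer non-zero directions than requested
    scores <- cbind(scores, matrix(0, nrow(scores), p - ncol(scores)))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    stopifnot(nrow(meta) == length(adjacencies))
  }
  structure(list(scores = scores[, seq_len(p), drop = FALSE],
                 meta = meta,
                 rotation = pc$rotation, center = pc$center, sdev = pc$sdev,
                 var_explained = if (degenerate) rep(0, p)
                                 else (pc$sdev^2 / tot)[seq_len(p)],
                 p = p, n = n, degenerate = degenerate),
            class = "network_feature_space")
}

#' @export
print.network_feature_space <- function(x, ...) {
  cat("<network_feature_space>", nrow(x$scores), "networks of", x$n,
      "neurons in", x$p, "components (",
      sprintf("%.1f%%", 100 * sum(x$var_explained)), "variance )\n")
  invisible(x)
}

#' Euclidean distance between two network projections
#'
#' @param q_l,q_m projection vectors of equal dimension.
#' @return non-negative scalar distance.
#' @export
network_distance <- function(q_l, q_m) {
  if (length(q_l) != length(q_m)) stop("projection dimensions differ")
  sqrt(sum((q_l - q_m)^2))
}

select_rows <- function(space, whisker, session = NULL) {
  stopifnot(inherits(space, "network_feature_space"), !is.null(space$meta))
  sel <- space$meta$whisker == whisker
  if (!is.null(session) && !is.null(space$meta$session))
    sel <- sel & space$meta$session == session
  which(sel)
}

#' Average pairwise distance between two whiskers' networks
#'
#' `(2 / M^2) * sum_l sum_m D(q_l^w1, q_m^w2)` over the M networks of each
#' whisker -- the factor 2/M^2 applied literally, so equal pairwise
#' distances `d` give `2 d`.  `strict_mean = TRUE` uses `1/M^2` (the plain
#' mean) instead; the max-normalized similarities of [similarity_report()]
#' are identical under either convention.
#'
#' @param space a [build_feature_space()] result with `whisker` metadata.
#' @param w1,w2 whisker labels.
#' @param session optional session label to restrict both sets to.
#' @param strict_mean use `1/M^2` instead of the literal `2/M^2`.
#' @return scalar average distance.
#' @export
average_pair_distance <- function(space, w1, w2, session = NULL,
                                  strict_mean = FALSE) {
  i1 <- select_rows(space, w1, session)
  i2 <- select_rows(space, w2, session)
  if (!length(i1) || !length(i2)) stop("no networks for the given labels")
  if (length(i1) != length(i2))
    stop("unequal dataset counts: ", length(i1), " vs ", length(i2))
  M <- length(i1)
  D <- cross_dist(space$scores[i1, , drop = FALSE],
                  space$scores[i2, , drop = FALSE])
  (if (strict_mean) 1 else 2) * sum(D) / M^2
}

## Per-dataset distance samples between two whiskers' network sets, used as
## the t-test samples: dataset l of w1 is paired with dataset l of w2, so
## every sample involves two networks no other sample uses and the samples
## are exchangeable, independent replicates under a null of no session
## effect.  Scaled by 2 to sit on the scale of average_pair_distance()'s
## literal 2/M^2 factor, so mean(distance) estimates the same quantity.
dataset_distances <- function(space, w1, w2, session = NULL) {
  i1 <- select_rows(space, w1, session)
  i2 <- select_rows(space, w2, session)
  if (length(i1) != length(i2))
    stop("unequal dataset counts: ", length(i1), " vs ", length(i2))
  d <- sqrt(rowSums((space$scores[i1, , drop = FALSE] -
                       space$scores[i2, , drop = FALSE])^2))
  data.frame(dataset = seq_along(i1), distance = 2 * d)
}

#' Network-similarity report across whisker pairs and sessions
#'
#' For every whisker pair (within every session, when session labels are
#' present) computes the average pairwise distance and the similarity
#' `1 - D / max(D)`, normalized by the maximum average distance across all
#' pairs in the compared set, so the maximally distant pair scores 0.  When
#' all distances are 0 the report is flagged degenerate and all similarities
#' are 1.
#'
#' @param space a [build_feature_space()] result with `whisker` (and
#'   optionally `session`) metadata.
#' @param strict_mean passed to [average_pair_distance()].
#' @return data frame (`session`, `w1`, `w2`, `distance`,
#'   `norm_distance`, `similarity`) with the normalization constant in
#'   `attr(, "norm_const")` and a `degenerate` attribute.
#' @export
similarity_report <- function(space, strict_mean = FALSE) {
  stopifnot(!is.null(space$meta), !is.null(space$meta$whisker))
  whiskers <- unique(space$meta$whisker)
  if (length(whiskers) < 2) stop("need at least two whiskers")
  sessions <- if (is.null(space$meta$session)) NA_character_
              else unique(space$meta$session)
  pairs <- utils::combn(whiskers, 2)
  rows <- list()
  for (s in sessions)
    for (k in seq_len(ncol(pairs)))
      rows[[length(rows) + 1]] <- data.frame(
        session = s, w1 = pairs[1, k], w2 = pairs[2, k],
        distance = average_pair_distance(
          space, pairs[1, k], pairs[2, k],
          session = if (is.na(s)) NULL else s,
          strict_mean = strict_mean),
        stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  mx <- max(out$distance)
  degenerate <- mx == 0
  out$norm_distance <- if (degenerate) 0 else out$distance / mx
  out$similarity <- 1 - out$norm_distance
  structure(out, norm_const = mx, degenerate = degenerate)
}

#' Pre-synaptic convergence of inferred networks
#'
#' Mean in-degree over neurons of each network; with `normalize = TRUE`
#' (default) divided by `n - 1`, the number of possible parents, giving the
#' fraction of realized incoming connections per neuron.  With a `sessions`
#' label vector the per-session mean and SD across networks are returned.
#'
#' @param adjacencies list of binary adjacency matrices.
#' @param sessions optional label per network.
#' @param normalize divide by `n - 1`.
#' @return numeric vector (one value per network), or a data frame
#'   (`session`, `mean`, `sd`, `n`) when `sessions` is given.
#' @export
presynaptic_convergence <- function(adjacencies, sessions = NULL,
                                    normalize = TRUE) {
  vals <- vapply(adjacencies, function(A) {
    v <- mean(colSums(A))
    if (normalize) v / (nrow(A) - 1) else v
  }, numeric(1))
  if (is.null(sessions)) return(vals)
  stopifnot(length(sessions) == length(vals))
  out <- do.call(rbind, lapply(unique(sessions), function(s) {
    x <- vals[sessions == s]
    data.frame(session = s, mean = mean(x), sd = sd(x), n = length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Electrode-array geometry
#'
#' Silicon-probe layout: `n_shanks` shanks at `shank_pitch_um` horizontal
#' pitch, `sites_per_shank` sites per shank at `site_pitch_um` vertical
#' pitch (defaults: 8 x 4 at 200/100 um).  Site ids run down each shank.
#'
#' @param n_shanks,sites_per_shank array dimensions.
#' @param shank_pitch_um,site_pitch_um pitches in micrometers.
#' @return object of class `electrode_geometry`: data frame (`site_id`,
#'   `shank`, `depth`, `x_um`, `z_um`).
#' @export
electrode_geometry <- function(n_shanks = 8, sites_per_shank = 4,
                               shank_pitch_um = 200, site_pitch_um = 100) {
  g <- expand.grid(depth = seq_len(sites_per_shank),
                   shank = seq_len(n_shanks))
  out <- data.frame(site_id = seq_len(nrow(g)),
                    shank = g$shank, depth = g$depth,
                    x_um = (g$shank - 1) * shank_pitch_um,
                    z_um = (g$depth - 1) * site_pitch_um)
  class(out) <- c("electrode_geometry", "data.frame")
  out
}

#' Effective connection probability vs. electrode separation
#'
#' For every unordered unit pair, a connection is counted when either
#' direction is present in an adjacency matrix; the probability at a
#' horizontal/vertical separation is the count of connected pairs at that
#' separation, averaged over networks, divided by the number of pairs at
#' that separation.  Separations with no pairs are omitted.
#'
#' @param adjacencies list of binary adjacency matrices (identical n).
#' @param geometry an [electrode_geometry()].
#' @param site_ids electrode-site id per unit (every unit must be mapped).
#' @return data frame (`dh_um`, `dv_um`, `probability`, `n_pairs`).
#' @export
connection_probability_by_separation <- function(adjacencies, geometry,
                                                 site_ids) {
  n <- nrow(adjacencies[[1]])
  stopifnot(length(site_ids) == n)
  bad <- which(is.na(site_ids) | !(site_ids %in% geometry$site_id))
  if (length(bad))
    stop("unit(s) without a mapped electrode site: ",
         paste(bad, collapse = ", "))
  loc <- geometry[match(site_ids, geometry$site_id), ]
  pr <- Reduce(`+`, lapply(adjacencies, function(A)
    (A + t(A)) > 0)) / length(adjacencies)
  pairs <- which(upper.tri(pr), arr.ind = TRUE)
  dh <- abs(loc$x_um[pairs[, 1]] - loc$x_um[pairs[, 2]])
  dv <- abs(loc$z_um[pairs[, 1]] - loc$z_um[pairs[, 2]])
  agg <- aggregate(list(probability = pr[pairs]),
                   by = list(dh_um = dh, dv_um = dv), FUN = mean)
  cnt <- aggregate(list(n_pairs = rep(1L, nrow(pairs))),
                   by = list(dh_um = dh, dv_um = dv), FUN = sum)
  out <- merge(agg, cnt, by = c("dh_um", "dv_um"))
  out[order(out$dh_um, out$dv_um), ]
}

#' Two-sample t-test between session samples
#'
#' Pooled-variance two-sample t-test by default (Welch optional); the
#' degenerate case of two zero-variance samples with equal means returns
#' `t = 0, p = 1` (flagged), and zero-variance samples with different means
#' return `p = 0`.
#'
#' @param values_a,values_b numeric samples (each of length >= 2).
#' @param var_equal pooled variance (`TRUE`, default) or Welch.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `degenerate`.
#' @export
compare_sessions <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    eq <- mean(values_a) == mean(values_b)
    return(list(t = if (eq) 0 else Inf * sign(mean(values_a) - mean(values_b)),
                p = if (eq) 1 else 0,
                df = length(values_a) + length(values_b) - 2,
                mean_a = mean(values_a), mean_b = mean(values_b),
                degenerate = TRUE))
  }
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b), degenerate = FALSE)
}

#' Scatter plot of a network feature space
#'
#' Projections colored by whisker and shaped by session (when present).
#' Requires ggplot2.
#'
#' @param space a [build_feature_space()] result.
#' @return a ggplot object.
#' @export
plot_feature_space <- function(space) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(q1 = space$scores[, 1],
                   q2 = if (space$p >= 2) space$scores[, 2] else 0)
  if (!is.null(space$meta)) df <- cbind(df, space$meta)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = q1, y = q2))
  pt <- if (!is.null(df$whisker) && !is.null(df$session))
    ggplot2::geom_point(ggplot2::aes(colour = whisker, shape = session),
                        alpha = 0.7)
  else if (!is.null(df$whisker))
    ggplot2::geom_point(ggplot2::aes(colour = whisker), alpha = 0.7)
  else ggplot2::geom_point(alpha = 0.7)
  p + pt + ggplot2::labs(x = "PC1", y = "PC2")
}
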