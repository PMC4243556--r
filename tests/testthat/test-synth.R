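test_that("edge counts follow the connectivity ratio exactly", {
  expect_equal(nrow(generate_network(10, 0, seed = 1)$edges), 0)
  expect_equal(nrow(generate_network(10, 0.1, seed = 1)$edges),
               round(0.1 * 10 * 9))
  expect_equal(nrow(generate_network(23, 0.1, seed = 2)$edges),
               round(0.1 * 23 * 22))
  net <- generate_network(12, 0.15, seed = 9)
  expect_true(all(net$edges$delay %in% 1:5))
  expect_true(all(net$edges$pre != net$edges$post))
})

test_that("network generation is deterministic given the seed", {
  a <- generate_network(15, 0.1, seed = 42)
  b <- generate_network(15, 0.1, seed = 42)
  expect_identical(a$edges, b$edges)
  c <- generate_network(15, 0.1, seed = 43)
  expect_false(identical(a$edges, c$edges))
})

test_that("incompatible connectivity ratio and parent cap is rejected", {
  expect_error(generate_network(30, 0.5, max_parents = 10, seed = 1),
               "max_parents")
  expect_silent(generate_network(30, 0.1, max_parents = 10, seed = 1))
})

test_that("a silent network produces an all-zero raster", {
  net <- generate_network(3, 0, background_rate = 0, barrels = "A", seed = 1)
  pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 5,
                           peak_gain = 0)
  ens <- simulate_session(net, pro, seed = 1)
  expect_true(all(ens$raster == 0L))
})

test_that("background firing is calibrated: count within 3 binomial SDs", {
  net <- generate_network(2, 0, background_rate = 10, barrels = "A",
                          seed = 1)
  pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 100,
                           peak_gain = 0)
  ens <- simulate_session(net, pro, seed = 3)   # ~100 s at 10 Hz
  n_bins <- ncol(ens$raster)
  expected <- n_bins * 0.01
  tol <- 3 * sqrt(n_bins * 0.01 * 0.99)
  for (i in 1:2)
    expect_lt(abs(sum(ens$raster[i, ]) - expected), tol)
})

test_that("a strong planted edge leaves a cross-correlogram peak at its delay", {
  net <- generate_network(2, 0, background_rate = c(30, 2), barrels = "A",
                          seed = 1)
  net$edges <- data.frame(pre = 1L, post = 2L, delay = 3L, weight = 0.6,
                          sign = "excitatory")
  pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 100,
                           peak_gain = 0)
  ens <- simulate_session(net, pro, seed = 4)
  expect_equal(ccg_argmax(ens$raster, 1, 2), 3)
})

test_that("planted lags are recoverable as conditional-probability shifts", {
  for (d in c(1L, 5L)) {
    net <- generate_network(2, 0, background_rate = c(25, 5),
                            barrels = "A", seed = d)
    net$edges <- data.frame(pre = 1L, post = 2L, delay = d, weight = 0.4,
                            sign = "excitatory")
    pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 60,
                             peak_gain = 0)
    r <- simulate_session(net, pro, seed = d + 10)$raster
    tt <- (d + 1):ncol(r)
    p_cond <- mean(r[2, tt][r[1, tt - d] == 1])
    expect_gt(p_cond, mean(r[2, tt]))
  }
  # inhibition: conditional probability drops below baseline
  net <- generate_network(2, 0, background_rate = c(25, 15), barrels = "A",
                          seed = 7)
  net$edges <- data.frame(pre = 1L, post = 2L, delay = 2L, weight = 0.012,
                          sign = "inhibitory")
  pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 100,
                           peak_gain = 0)
  r <- simulate_session(net, pro, seed = 8)$raster
  tt <- 3:ncol(r)
  expect_lt(mean(r[2, tt][r[1, tt - 2] == 1]), mean(r[2, tt]))
})

test_that("simulation is bit-deterministic given the seed", {
  net <- generate_network(6, 0.2, barrels = c("D4", "D5"), seed = 2)
  pro <- stimulus_protocol(whiskers = c("D4", "D5"), trials_per_whisker = 10)
  a <- simulate_session(net, pro, seed = 5)
  b <- simulate_session(net, pro, seed = 5)
  expect_identical(a$raster, b$raster)
  c <- simulate_session(net, pro, seed = 6)
  expect_false(identical(a$raster, c$raster))
})

test_that("excess per-bin probability is clipped with a warning", {
  net <- generate_network(2, 0, background_rate = 2000, barrels = "A",
                          seed = 1)
  pro <- stimulus_protocol(whiskers = "A", trials_per_whisker = 2,
                           peak_gain = 0)
  expect_warning(ens <- simulate_session(net, pro, seed = 1),
                 "exceeded 1 before clipping")
  expect_gt(attr(ens, "n_clipped_high"), 0)
})

test_that("pairing with strength 0 reproduces the control network exactly", {
  net <- generate_network(12, 0.1, barrels = c("D4", "D5", "D6"), seed = 3)
  for (mode in c("strengthen_cross_edges", "add_cross_edges",
                 "correlate_inputs")) {
    eff <- pairing_effect(c("D4", "D5"), 0, mode = mode)
    expect_identical(apply_pairing(net, eff, seed = 1), net)
  }
})

test_that("add_cross_edges saturates at strength 1 and nests monotonically", {
  net <- generate_network(12, 0.1, barrels = c("D4", "D5", "D6"), seed = 3)
  b <- net$barrel
  eff1 <- pairing_effect(c("D4", "D5"), 1, mode = "add_cross_edges")
  full <- apply_pairing(net, eff1, seed = 9)
  cross <- with(full$edges,
                b[pre] %in% c("D4", "D5") & b[post] %in% c("D4", "D5") &
                  b[pre] != b[post])
  n_d4 <- sum(b == "D4"); n_d5 <- sum(b == "D5")
  expect_equal(sum(cross), 2 * n_d4 * n_d5)  # every candidate pair present

  key <- function(net) paste(net$edges$pre, net$edges$post)
  e3 <- key(apply_pairing(net, pairing_effect(c("D4", "D5"), 0.3,
                                              mode = "add_cross_edges"),
                          seed = 9))
  e6 <- key(apply_pairing(net, pairing_effect(c("D4", "D5"), 0.6,
                                              mode = "add_cross_edges"),
                          seed = 9))
  expect_true(all(e3 %in% e6))
  expect_gt(length(e6), length(e3))
})

test_that("strengthen_cross_edges boosts only cross-barrel weights", {
  net <- generate_network(14, 0.15, barrels = c("D4", "D5"), seed = 5)
  eff <- pairing_effect(c("D4", "D5"), 0.8, mode = "strengthen_cross_edges",
                        boost = 1.25)
  out <- apply_pairing(net, eff, seed = 1)
  b <- net$barrel
  cross <- with(net$edges, b[pre] != b[post])
  expect_equal(out$edges$weight[!cross], net$edges$weight[!cross])
  expect_true(all(out$edges$weight[cross] >= net$edges$weight[cross]))
  expect_gt(sum(out$edges$weight[cross]), sum(net$edges$weight[cross]))
})

test_that("convergence modifier adds or removes the stated edge fraction", {
  net <- generate_network(15, 0.2, barrels = c("D4", "D5"), seed = 6)
  n0 <- nrow(net$edges)
  up <- apply_pairing(net, pairing_effect(c("D4", "D5"), 0.5,
                                          convergence_modifier = 0.3),
                      seed = 2)
  expect_equal(nrow(up$edges), n0 + round(0.3 * n0))
  down <- apply_pairing(net, pairing_effect(c("D4", "D5"), 0.5,
                                            convergence_modifier = -0.1),
                        seed = 2)
  expect_equal(nrow(down$edges), n0 - round(0.1 * n0))
  # removal never touches cross-barrel edges between the paired barrels
  b <- net$barrel
  cross_key <- with(net$edges,
                    paste(pre, post)[b[pre] %in% c("D4", "D5") &
                                       b[post] %in% c("D4", "D5") &
                                       b[pre] != b[post]])
  expect_true(all(cross_key %in% paste(down$edges$pre, down$edges$post)))
})

test_that("unknown barrel labels are rejected", {
  net <- generate_network(6, 0.1, barrels = c("D4", "D5"), seed = 1)
  expect_error(apply_pairing(net, pairing_effect(c("D4", "C1"), 0.5),
                             seed = 1),
               "unknown barrel")
  pro <- stimulus_protocol(whiskers = c("D4", "C9"), trials_per_whisker = 2)
  expect_error(simulate_session(net, pro, seed = 1), "C9")
})

test_that("correlate_inputs drives the other paired barrel's responses", {
  net <- generate_network(8, 0, background_rate = 3,
                          barrels = c("D4", "D5"), seed = 4)
  eff <- pairing_effect(c("D4", "D5"), 0.8, mode = "correlate_inputs")
  paired <- apply_pairing(net, eff, seed = 1)
  pro <- stimulus_protocol(whiskers = c("D4", "D5"),
                           trials_per_whisker = 150)
  base <- response_summary(simulate_session(net, pro, seed = 2))
  corr <- response_summary(simulate_session(paired, pro, seed = 2))
  # D5-barrel neurons respond to D4 deflection only under the overlap
  d5 <- which(net$barrel == "D5")
  base_x <- mean(base$evoked_mean[base$whisker == "D4"][d5])
  corr_x <- mean(corr$evoked_mean[corr$whisker == "D4"][d5])
  expect_gt(corr_x, base_x + 1)
})

test_that("ensembles and networks round-trip through their text formats", {
  net <- generate_network(5, 0.2, barrels = c("D4", "D5"), seed = 8)
  d <- withr::local_tempdir()
  write_network(net, file.path(d, "edges.csv"), file.path(d, "net.graphml"))
  e <- read.csv(file.path(d, "edges.csv"))
  expect_equal(e$pre, net$edges$pre)
  expect_equal(e$delay_bins, net$edges$delay)
  g <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(igraph::vcount(g), net$n_neurons)
})
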