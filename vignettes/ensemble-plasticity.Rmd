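---
title: "Inferring effective connectivity and tracking ensemble plasticity with spikedbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring effective connectivity and tracking ensemble plasticity with spikedbn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sensory cortex reorganizes when its inputs change: pairing two whiskers of a
rat (sparing them while trimming the rest) changes how neurons in the
corresponding barrels of primary somatosensory cortex respond to whisker
deflection.  Classical single-neuron measures — evoked spike count and
first-spike latency — track this slowly and noisily.  An alternative is to
treat the simultaneously recorded ensemble as a network: infer the directed,
millisecond-scale *effective connectivity* between neurons from their spike
trains, embed the inferred networks in a common feature space, and measure
plasticity as movement of whole networks in that space.

`spikedbn` implements that analysis end to end, together with a synthetic
data generator that plants known connectivity so every stage can be
validated: simulator → dataset assembly → dynamic Bayesian network (DBN)
structure learning → network feature space → plasticity statistics.

## The spiking model

Spike trains are binned at Δ = 1 ms into binary indicators $r_i(t)$.  The
generator simulates an inhomogeneous Bernoulli (discrete-time Poisson)
process: neuron $i$ spikes in bin $t$ with probability

$$
p_i(t) = \mathrm{clip}\Big(p^{bg}_i \;+\; g_i(t) \;+\;
  \sum_{e: \, \mathrm{post}(e)=i} w_e \, s_e \, r_{\mathrm{pre}(e)}(t - d_e),
  \; 0, 1\Big)
$$

where $p^{bg}_i$ is the background rate converted to a per-bin probability,
$g_i(t)$ is the stimulus gain (nonzero while a whisker mapped to neuron
$i$'s barrel is deflected), and each edge $e$ contributes its weight $w_e$
(sign $s_e = \pm 1$ for excitation/inhibition) whenever its source spiked
$d_e$ bins earlier.  The additive-and-clip link is the simplest conditional
intensity consistent with an inhomogeneous Poisson description; bins whose
pre-clip probability exceeds 1 are counted and reported with a warning.
There is no refractory period by default — the process is pure Bernoulli
per bin.

Defaults (all configurable):

* **connectivity**: 10% of ordered neuron pairs carry an edge, delays
  uniform on 1–5 ms (the lag range the analysis scores), 20% of edges
  inhibitory — a typical cortical excitation/inhibition split;
* **weights**: 0.08–0.25 added spike probability per source spike, chosen so
  a single edge is reliably but not trivially detectable in an 18-s dataset;
* **rates**: 5 spikes/s background; evoked gain rising linearly to 0.08/bin
  at 8 ms and decaying with a 25-ms time constant — a typical deflection
  PSTH shape with tens-of-Hz transient peaks;
* **protocol**: 900 deflections per whisker, 100 ms each, at 1 Hz, one block
  per whisker; every trial retains a full 100-ms pre-stimulus baseline.

## The pairing manipulation

`apply_pairing()` plants experience-dependent plasticity between two paired
barrels.  Three modes are provided; the pipeline default is
`strengthen_cross_edges`, which scales the weights of existing cross-barrel
edges by $1 + \mathrm{strength} \times \mathrm{boost}$ (boost 1.25, weights
capped at 0.95).  `add_cross_edges` instead adds a `strength` fraction of
the absent cross-barrel edges, with the guarantee that the set added at a
smaller strength is a subset of the set added at a larger strength under the
same seed.  `correlate_inputs` leaves the network untouched and makes each
paired barrel respond to the other paired whisker with a fraction of the
evoked gain (receptive-field overlap).

A signed `convergence_modifier` changes the edge count by that fraction.
Added parents are placed preferentially as cross-barrel edges between the
paired barrels (then within them): the early rise in convergence this
emulates is potentiation of co-active inputs, so the new parents belong
where the co-activation is.  Removals never touch paired cross-barrel edges,
keeping the pairing effect monotone in strength.  Edge removal under a
negative modifier models later depression/pruning.

The three-session emulation uses strengths (0, 0.4, 0.8) for control,
early, and late sessions with convergence modifiers (0, +0.3, −0.1).  The
two nonzero strengths are the package's choice of a mid and a high level of
the same manipulation; the modifiers plant an early-rise/late-fall
convergence profile without asserting any particular magnitude.

## Dataset assembly

For each whisker, analysis datasets are built by concatenating the 100-ms
post-onset windows of 180 trials sampled uniformly *without* replacement
from the whisker's 900 trials — 18,000 bins (18 s) per dataset —
independently for each of $M$ datasets (so two datasets typically share
about 20% of their trials).  Concatenation creates seams at which a bin's
lagged history belongs to a different trial.  By default lags score across
seams, matching how concatenated datasets are normally analyzed;
`mask_seams = TRUE` (or the `exclude` argument of `family_statistics()`)
removes the first `max_lag` bins after every seam to expose how much the
artifact contributes.

## DBN structure learning

The ensemble's transition distribution factorizes over neurons given their
parent sets: each child depends only on its parents' spiking 1–5 bins back.
Because only such inter-slice (lagged) edges exist, the unrolled graph is
acyclic for *any* parent assignment, the marginal likelihood decomposes over
families, and structures can be scored family by family.

A structure is scored by the Bayesian Dirichlet equivalent (BDe) metric: for
child $i$ with parent configuration $k$ and child state $j \in \{0,1\}$,
with data counts $Z_{ijk}$ and prior pseudo-counts $Z'_{ijk}$,

$$
\log \Pr(D \mid G) = \sum_{i,k} \Big( \log
\frac{\Gamma(Z'_{ik})}{\Gamma(Z'_{ik} + Z_{ik})} + \sum_j \log
\frac{\Gamma(Z'_{ijk} + Z_{ijk})}{\Gamma(Z'_{ijk})} \Big)
$$

computed entirely in log-Gamma arithmetic.  The prior is BDeu with
equivalent sample size $a = 1$ and a uniform prior structure, i.e.
$Z'_{ijk} = a / (2 \cdot 2^{|\pi(i)|})$ — the standard uninformative choice
when no prior network is available.  Counts for a family run from
$\max(\text{parent lags}) + 1$ to the end of the dataset, so no lagged value
is ever fabricated before the data start; a family with no data scores
exactly 0.  The suite verifies the closed form against a sequential
Dirichlet-multinomial (Pólya-urn) oracle that never touches the Gamma
function.

**Search.**  Simulated annealing proposes uniformly among the legal moves —
add an edge at one of the candidate lags, delete an edge, or reverse one
(keeping its lag) — and accepts with probability
$\min(1, e^{\Delta/T})$ under geometric cooling.  At most one lag is kept
per ordered pair during the search, and the 10-parent cap is enforced at
proposal time, so no visited structure ever violates it.  The search starts
from the empty network by default (bit-reproducible; a random start is
available behind `init = "random"`), tracks the best structure ever visited,
and uses an iteration budget rather than wall-clock time so results are
hardware-independent.  Each proposal is evaluated in $O(T)$ by maintaining a
per-bin parent-configuration code per child.  For networks of up to 4
neurons `exhaustive_search()` enumerates every per-child parent assignment
and serves as the optimality oracle (ties resolved toward the first,
sparsest structure in enumeration order).

When a pair is inferred at several lags, `collapse_lags()` keeps the edge
with only its largest lag annotated and returns the binary adjacency matrix
used downstream (diagonal excluded).

## The network feature space and plasticity statistics

All adjacency matrices under comparison (every session, whisker and dataset
of a subject) are vectorized in fixed row-major order *excluding the
diagonal* — the feature should reflect between-neuron connectivity — and
stacked into a (networks × $n^2 - n$) matrix.  PCA is fitted **jointly on
all sessions**, so distances are comparable across sessions, and networks
are projected onto $p = 2$ components.  The distance between two networks
is the Euclidean distance between their projections, and the average
distance between two whiskers' network sets is

$$
\bar D(w_1, w_2) = \frac{2}{M^2} \sum_l \sum_m D(A_l^{w_1}, A_m^{w_2}),
$$

with the factor $2/M^2$ applied literally (equal pairwise distances $d$
give $\bar D = 2d$); `strict_mean = TRUE` switches to the plain mean
$1/M^2$.  Similarity is $1 - \bar D / \max \bar D$, normalized by the
largest average distance over all whisker pairs and sessions in the
compared set — mirroring the max-normalization of the single-neuron
metrics — so the factor convention cancels.  When every distance is zero
the report is flagged degenerate and similarities are 1.

Pre-synaptic convergence is the mean in-degree per network, divided by
$n - 1$ by default so it reads as the realized fraction of possible
parents; both scales are available.  Connection probability as a function
of electrode separation uses the 8-shank × 4-site geometry (200 µm / 100 µm
pitches) and counts an unordered pair connected when either direction is
present.

**Session comparisons.**  Sessions are compared with pooled-variance
two-sample t-tests (Welch optional).  For network similarity the samples
are per-dataset: dataset $l$ of one whisker is paired with dataset $l$ of
the other, so every sample involves two networks no other sample touches.
Averaging each dataset against the *whole* other set would make the samples
share that set and overlap in trials, correlating them and badly inflating
the test's false-positive rate — the matched pairing restores approximate
independence under the null (verified by Monte-Carlo replicates with the
pairing strength set to 0).  Convergence is compared on per-network
samples and the response metrics on per-neuron similarity samples, pooled
across subjects; the degenerate zero-variance case returns $p = 1$ when
means agree and is flagged.

## Single-neuron response metrics

The evoked count of a trial is the spike count in the 100-ms trial window
minus the count in the 100-ms window preceding onset; negative values are
kept, since the quantity is a difference, not a rectified rate.  First-spike
latency is the time from onset to the first spike inside the window, with
the onset bin counting as latency 0; trials without a spike are excluded
from the mean rather than imputed at the window length, and the number of
contributing trials is reported.  Windows are half-open,
$[\text{onset}, \text{onset}+100)$, so the accounting is bit-exact.  The
cross-whisker similarity of either metric is one minus the per-neuron
absolute difference normalized by the population maximum; per-neuron means
(not per-trial values) enter the latency similarity.

## Worked scales

The validation workloads are sized for a single CPU: the search-optimality
check uses 50 three-neuron, two-lag, 200-bin instances with 20 annealing
runs each; structure recovery uses a 10-neuron network at 10% density with
strong excitatory couplings (weights 0.25–0.35), 10 datasets of 18 s and
majority vote; the three-session emulation runs 4 subjects at $M = 20$
datasets per whisker with 2,500 proposals per search; and the null control
runs 20 replicates of a reduced two-whisker configuration.  The full-scale
defaults ($M = 100$, $2 \times 10^5$ proposals, 3 restarts) are what the
configuration object ships with.

```{r}
library(spikedbn)
cfg <- experiment_config(n_subjects = 4, n_datasets = 20,
                         anneal = list(iterations = 2500, restarts = 1,
                                       t0 = 10, cooling = 0.997),
                         seed = 1)
res <- run_experiment(cfg)
res$similarity_summary
res$convergence_summary
subset(res$tests, metric == "network_similarity")
```

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: binary 1-ms
rasters, stimulus-locked rate transients confined to one barrel per whisker,
sparse lagged causal interactions within the scored lag range, trial
structure with baselines, and a monotone planted pairing effect.  It does
not emulate biophysical membrane dynamics, spike waveforms or sorting
errors, behavioral state, whisking kinematics, adaptation across the
900-trial block, or oscillatory common input.  Passing tests therefore show
that the inference machinery recovers the kind of structure it models —
not that every feature of in-vivo recordings is captured.

## Known limitations

* Inhibitory edges onto low-rate neurons are nearly undetectable: with a
  5-Hz background, suppressing a 0.005/bin probability leaves few events to
  count.  Recovery benchmarks therefore use excitatory couplings.
* Datasets assembled from the same session share trials, so inferred
  networks within a session are correlated; the matched-pair test samples
  mitigate, but do not eliminate, this dependence.
* With $p = 2$ components the feature space keeps only the dominant
  variance directions; structure orthogonal to them does not influence the
  similarity statistic.
* Because the average pairwise distance mixes centroid separation with
  within-cluster dispersion, a session whose extra planted parents are only
  intermittently detected can see its distances inflated by detection
  variance.  At 4 subjects and $M = 20$, the late-vs-control similarity
  increase and the convergence mid-peak are robust across seeds, but the
  strict ordering of all three session means sits near the edge of the
  emulation's power.
* Effective connectivity is a statistical construct; an inferred edge is
  evidence of lagged predictive influence, not of an anatomical synapse.
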