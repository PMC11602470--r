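---
title: "Dynamic multilayer EEG networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multilayer EEG networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwnetdyn)
```

## The analysis in one paragraph

`mwnetdyn` treats a band-limited multichannel EEG recording as a sequence of
two-layer weighted multiplex networks. For every time segment, layer 1
carries amplitude envelope correlations (AEC, the absolute Pearson
correlation of Hilbert amplitude envelopes) and layer 2 carries imaginary
phase-locking values (IPLV, the magnitude of the imaginary part of the mean
phase-difference phasor). Segments are not fixed windows: the recording is
cut where the multiplex structure itself changes. Each segment is summarized
by its overlapping node closeness centrality vector; pooling these vectors
across trials and participants, a Louvain clustering of their
rank-correlation similarity graph defines a small catalog of recurring
network states. Each trial then becomes a categorical state sequence, whose
statistics (frequency, duration, coverage, transition structure) are
compared between a focused-learning (FL) and a mind-wandering (MW)
condition, and which feed a per-participant two-hidden-state discrete hidden
Markov model (HMM) classifier for mind-wandering detection.

## Connectivity layers

AEC and IPLV are deliberately complementary: AEC sees co-fluctuating signal
power, IPLV sees consistent non-zero phase lags. IPLV of a zero-lag linear
mixture is exactly zero, which is what makes it relatively insensitive to
volume conduction; the package's tests assert this identity directly. Both
estimators use the analytic signal from the FFT-based Hilbert construction,
computed on each segment as given (no padding, no trimming); the segmenter's
0.5 s minimum-length rule keeps segments long enough for the transform to be
meaningful.

Each layer is min-max normalized per segment (the smallest off-diagonal
edge maps to 0, the largest to 1) so the two layers live on a common scale.
If a layer is exactly flat, it maps to all ones rather than all zeros: a
zero weight means an absent edge and hence infinite shortest-path
distances, which would poison the centrality stage downstream.

## Centrality on the multiplex

Edge distance is the inverse of normalized weight; a node's within-layer
closeness is the inverse of its mean shortest-path distance to all other
nodes (0 if any node is unreachable). The overlapping closeness of a node
averages its per-layer closenesses. Two conventions exist for inter-layer
travel: the default keeps shortest paths inside each layer (matching the
per-layer structure of the centrality average); the `"coupled"` alternative
allows free hops between a node's replicas, which for two layers is
shortest paths on the element-wise-maximum graph. Both are implemented;
only the default is used by the rest of the pipeline.

A practical note: on an 8-node dense weighted graph, closeness is a
low-contrast statistic. One strong edge changes its endpoints' closeness by
only a few percent, because every mean distance is dominated by the other
six paths and because strong edges act as shortcuts for *all* nodes. This
observation shaped both the synthetic generator (below) and our reading of
the segmentation results.

## Segmentation by network-structure change

Two 2 s windows (`reference_window_s`, following the published parameter
choice) slide along the recording 0.25 s apart in steps of `step_s`. The
Euclidean distance between their layer-averaged closeness profiles is
monitored; a Gaussian kernel density (Scott's-rule bandwidth) is fitted to
the trailing pool of observed distances, and a step whose distance exceeds
the `p_kde = 0.96` quantile opens a candidate boundary. Three details
matter:

* boundaries are placed at the *peak* of a run of consecutive
  above-threshold steps, not at the first crossing, which otherwise lands
  about a second early;
* a distance joins the null pool only one window length after it is
  observed (a guard gap), so that the plateau of elevated distances around
  a genuine change cannot inflate the threshold used to detect it;
* segments are clamped to `[0.5, 10]` s, with a forced split at the
  maximum; any segment overlapping an artifact-masked stretch is dropped
  rather than stitched across the gap, so no spurious connectivity is
  computed across discontinuities.

Because the detector is a fixed-quantile outlier rule, it flags roughly
`1 - p_kde` of steps even on a perfectly stationary recording; conversely,
a genuine switch whose profile contrast sits inside the bulk of the
estimation-noise distribution will be missed. At 2 s windows the closeness
profiles of two planted coupling states differ by roughly one noise
standard deviation, and measured single-switch recovery (a boundary within
1 s of the truth) lands near half the seeds (30–65% across 20-seed batches) rather than near-certain, a
sensitivity limit of the statistic rather than of the detector: a
retrospective oracle that sees the full distance series does no better.
The segmentation-quality index `p_diff` — the fraction of adjacent segment
pairs whose between-segment structure distance strictly exceeds both
within-segment (half-vs-half) distances — nevertheless consistently ranks
the structure-driven segmentation above fixed 2 s windows, and that
ordering is what the acceptance checks pin.

## Network states

Per-segment overlapping-centrality vectors are min-max normalized per
participant and per component across all of that participant's segments and
trials, removing individual scale differences. The pooled vectors form a
complete graph weighted by Spearman correlations (negative values clamped
to zero, since modularity maximization assumes nonnegative weights), and
Louvain community detection at resolution 1 defines the states. The state
count is data-driven; communities holding under 1% of total time are merged
into the community with the most-correlated centroid, so the downstream HMM
observation alphabet is not polluted by near-empty symbols. States are
labeled A, B, C, ... by descending time coverage. Clustering is run per
band; cross-band correspondence is read off the Pearson correlation matrix
of state centroids.

## Sequence dynamics and the randomness test

Adjacent same-state segments are consolidated into runs; masked gaps break
runs without contributing transitions. Frequency (runs per second), mean
run duration, coverage (time fraction), and the observed transition matrix
`P(X -> Y)` (transition counts over total transitions; the diagonal is
structurally zero) summarize each sequence. Under the null hypothesis that
only state frequencies matter, the expected transition probability is
`P*(X -> Y) = P(Y) P(X) / (1 - P(X))`; its rows sum to `P(X)` and the whole
matrix to 1, identities the tests verify. Observed and expected matrices
are averaged over a condition's trials and compared by the chi-square
distance `d = sum (P - P*)^2 / P*`.

The null distribution of `d` is built by Monte-Carlo resampling: each
trial's run sequence is regenerated from the memoryless chain that draws
the next state from the pooled run frequencies excluding the current state
— exactly the process whose transition probabilities are `P*`. We adopted
this scheme after two rejected alternatives. Reassigning pooled matrix
cells between pseudo-observed and pseudo-expected matrices puts
near-zero cells into chi-square denominators, so null distances explode
and the test never rejects anything (measured size and power both 0.000).
Shuffling the run order is also miscalibrated, because consolidated
sequences cannot contain self-adjacent runs while shuffles can (measured
size 0.000, hence conservative with unquantified power loss). The
Monte-Carlo null measures size 0.050 at the nominal 0.05 and power 1.0
against a strongly cyclic chain (200 replicates). The p-value uses the
tie-inclusive `(m + 1) / (n + 1)` form, so identical observed and expected
matrices give p = 1 rather than the paradoxical 0 of the uncorrected
ratio.

## Group comparisons

Every metric contrast follows one fixed procedure: Tukey box-plot outlier
removal per group (quartiles by linear interpolation), Shapiro–Wilk
normality per group at 0.05, then either Levene's test deciding between
the pooled-variance and Welch t tests, or the two-sided rank-sum test if
normality fails. Raw p-values are reported without multiplicity
correction; the branching decisions are recorded on the result object so
the route taken is auditable.

## The HMM classifier

Per participant and band, trial sequences are concatenated per condition
and split into 8 contiguous blocks. Each fold trains one 2-hidden-state
discrete HMM per condition by Baum–Welch on the other 7 blocks (treated as
one concatenated sequence), selects the analysis band by an inner 4-fold
cross-validation on the training blocks only (ties break toward the lower
band), splits each held-out block into score windows, and scores each
window by the posterior probability of the FL model under equal priors.
AUC is computed over the fold's scored windows by the rank (Mann–Whitney)
formulation with half-credit ties; F1 (MW positive) uses the
Youden-optimal threshold of the training-window ROC. Band choice and
threshold never see test data.

Numerical choices: exactly uniform initialization is an EM fixed point
whose hidden states never differentiate (a property one test asserts), so
initialization is uniform plus a seeded perturbation. The perturbation
magnitude is 0.05 — at 0.01 the optimizer measurably stalls in the flat
symmetric saddle basin on length-2000 sequences (EM stops after ~3
iterations with identical emission rows). Because EM also has genuine
local optima, training uses 5 seeded restarts and keeps the best final
log-likelihood; this takes parameter recovery from 3/10 to 9/10 seeds in
the planted-HMM benchmark. Emission probabilities are floored at 1e-8
after training so a symbol absent from a training fold cannot annihilate a
test window's likelihood. Convergence is a log-likelihood gain below 1e-4
or 100 iterations. The forward/backward passes are implemented in C++;
they are exercised thousands of times per cross-validation.

## The synthetic generator

The generator exists so that every stage has a ground truth. A *planted
state* is a connectivity motif: one group of channels shares an
envelope-modulated narrowband source (raising within-group AEC at zero
lag, hence invisible to IPLV), and a disjoint group shares a second source
with progressive fractional-sample delays imposing pairwise phase lags of
multiples of pi/4 (raising within-group IPLV). Group coupling, rather than
isolated channel pairs, is essential: closeness centrality on a dense
normalized 8-node graph barely responds to one edge, and in early designs
with pair motifs the planted states were unrecoverable from 2 s windows
(adjusted Rand index near 0 against ground truth); with 4-channel group
motifs the same clustering recovers pure windows at ARI around 0.85.
Narrowband sources are white noise shaped by the same FIR band-pass
response the analysis pipeline uses (applied as a zero-phase
magnitude-squared response in the frequency domain), so the generator and
analyzer agree spectrally by construction.

A trial draws a hidden state path from a condition-specific Markov chain
with exponential dwell times (mean 2 s by default, the scale of the
published segment lengths), then mixes each channel's coupled sources at
amplitude `amp_strength * sqrt(snr)` against `sqrt(1 - amp_strength^2)` of
independent narrowband noise, renormalized to unit power.

The benchmark study conditions, fixed once: four planted states over the
8-channel montage; the FL condition's chain favors transitions within
states A and B (each favored transition receives probability 0.8) while MW
favors C and D — the two conditions share the same motifs and differ only
in their dynamics; `amp_strength = 0.9`, `snr = 2` (chosen so that the
within-state dispersion of normalized profiles is comparable to the 0.1
noise scale of the profile-level clustering benchmark); two trials per
condition of 240 s (the real task's trials are full lecture videos, i.e.
minutes of data; 240 s keeps the full benchmark tractable on one CPU);
theta and alpha offered to band selection; test blocks scored in 2 windows
each, since with roughly ten segments per block the default of 4 windows
leaves near-informationless 2-symbol scores. Measured at these conditions:
mean within-participant AUC about 0.91 over seeds, and about 0.5 when both
conditions use the same transition matrix.

What the generator does *not* emulate: volume conduction and reference
effects, 1/f broadband background, eye-blink and muscle artifacts,
non-exponential dwell distributions, and inter-participant variability in
motif topography. Passing the synthetic benchmarks therefore demonstrates
that the pipeline recovers what it is designed to recover under its own
assumptions, not that real mind-wandering EEG is classified at any
particular accuracy.

## Problem sizes used by the checks

The automated checks run the permutation-test calibration at 500
replicates with 999 Monte-Carlo draws; switch recovery on 20 single-switch
trials of 60 s; state recovery on 120 noisy profile vectors over 10 seeds;
HMM recovery on length-2000 sequences over 10 seeds; and the full
signal-to-classification benchmark on 10 structured and 20 null
participants. These sizes are the package's reference experiment; the
generator and pipeline scale linearly in duration, channels, and seeds for
users who want more.

## Known limitations

* Closeness centrality compresses structural differences on small dense
  graphs; the segmenter inherits this and localizes only prominent
  changes (see above). The mean segment length under the benchmark
  conditions is about 5–6 s, not the ~2 s scale reported on real data —
  with a fixed 4% outlier rate at a 0.25 s step, shorter segments would
  require a denser evaluation grid.
* Louvain's community count is data-driven; the merge rule stabilizes the
  alphabet but can absorb a genuinely small state into a correlated
  neighbor.
* The EDF reader supports the common 16-bit single-rate case only.
* The group-comparison procedure reports raw p-values by design; with the
  number of contrasts the pipeline produces, about 1 in 20 "significant"
  results is expected to be spurious.
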