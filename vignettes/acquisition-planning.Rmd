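---
title: "Planning targeted MS2 acquisition from a preliminary MS1 run"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning targeted MS2 acquisition from a preliminary MS1 run}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2plan)
```

## The problem

Untargeted LC-MS/MS experiments must decide, on the fly or in advance,
which precursor ions receive fragmentation (MS2) scans. The standard
data-dependent strategy (top-N DDA) picks the most intense ions of each
survey scan; because abundant ions stay abundant across their whole
elution peak and across replicate injections, DDA re-fragments the same
features repeatedly and misses much of the detectable feature space.

`ms2plan` takes the planned route: a preliminary MS1-only run is
processed into (a) the raw scan triplets (m/z, RT, intensity) and (b) a
table of detected feature apexes from an upstream feature finder. From
these the package computes, for one or more follow-up targeted
injections, the time-ordered set of acquisition windows that maximizes
the number of **distinct** features fragmented with adequate spectral
quality.

Formally, with N features, T scan times, and binary indicators
$X_{t,i}$ (feature $i$ acquired at time $t$), the planner maximizes
$\sum_i \mathbf{1}(\sum_t X_{t,i} > 0)$ subject to

* **quality** — the predicted MS2 total ion current of each acquisition,
  a function $f$ of the integrated MS1 intensity over the window, must
  reach a user threshold;
* **contiguity** — each feature is acquired in one contiguous RT
  interval only;
* **exclusivity** — at most one feature is acquired at any time.

## Pipeline and model

### Background filtering and clustering

Features whose apex is also present in the background/control channel
are removed first (`filter_background()`): a feature survives only if it
has no blank signal or its sample/blank intensity ratio reaches
`min_ratio` (default 3). Raw scan points are then assigned to the
nearest apex (`assign_signals()`) under a scaled Chebyshev distance
$d = \max(|\Delta mz|/\text{mz\_tol},\ |\Delta rt|/\text{rt\_tol})$ with
a hard cutoff at $d = 1$. The tolerances (defaults 0.01 Th, 5 s) are
deliberate choices: the nearest-neighbor rule needs a scale, and a hard
cutoff makes "this signal belongs to no feature" explicit rather than
silently attaching noise to the closest peak. Ties are broken by smaller
m/z difference, then feature id, so clustering is deterministic.

### The feature DAG

Within each cluster the signals are binned on RT (`bin_cluster()`,
half-open bins anchored at the cluster's first scan; default width = the
median inter-scan interval). Each non-empty bin becomes a node carrying
the summed intensity of its scans; windows run between bin
representative times (midpoints). For every ordered bin pair $(a, b)$
whose duration lies in `[min_duration, max_duration]` and whose
trapezoidal intensity integral over the padded window
$[rt_a - \Delta, rt_b + \Delta]$ predicts an MS2 TIC at or above
`tic_threshold`, the DAG gets a weight-1 edge — a feasible acquisition.
Weight-0 edges connect features to later features
($rt_{in} \ge rt_{out} + \text{transition\_gap}$), and each node is
split into an in-node and an out-node so that a path entering a cluster
must traverse exactly one of its weight-1 edges before leaving.

The RT padding $\Delta$ (default 0.2 s) absorbs small retention-time
shifts between the preliminary and the targeted run. Scan points outside
the padded window are excluded entirely — no partial-interval
interpolation — because instrument sampling is discrete and the simpler
rule is exactly additive across adjacent windows sharing a boundary
scan. Windows covering fewer than two scan points integrate to zero and
are therefore never feasible.

### The TIC quality model

MS2 TIC is modeled as linear in the integrated MS1 intensity:
`predict_tic()` returns $\max(0, \text{slope} \cdot \text{integral} +
\text{intercept})$. The fit (`fit_tic_model()`) is ordinary least
squares on training pairs measured in a conventional DDA run on the same
platform; the model file persists slope, intercept and $\Delta$. The
regression includes an intercept (electronic noise floors and transfer
losses shift the line away from the origin) and predictions are floored
at zero. When no training data exist the default identity model is used,
which turns the quality constraint into a threshold on the integral
itself — operationally equivalent, and free of platform assumptions.
The default threshold of $10^3$ TIC units suits the intensity scale of
the synthetic generator and of typical q-Orbitrap runs; it is exposed as
`planner_config(tic_threshold = )`.

### Path search

Sorting nodes by RT (out-nodes before in-nodes at equal times) is a
topological order of the DAG, and the planner's dynamic program runs
over it. Two structural observations shape the implementation:

* **Containment pruning.** A window strictly containing another window
  of the same cluster can always be replaced by the inner one without
  breaking feasibility, so only minimal windows are searched. This
  leaves the optimal score unchanged and keeps the search near-linear in
  the number of windows.
* **Global exclusivity is not free.** The split-node construction
  prevents a path from using two acquisition edges of a cluster *in a
  row*, but a path may legally leave cluster A, acquire B, and re-enter
  A later — the transition edges cannot see path history. Under heavy
  co-elution the relaxed "most weight-1 edges" path degenerates into
  ping-ponging between overlapping clusters and badly over-counts. The
  true objective counts distinct features, which makes the problem a
  job-interval-selection variant (NP-hard in general), and the solver
  treats it exactly where it matters:

  1. **Small instances** (≤ 13 clusters with feasible windows): an
     exact subset DP over clusters whose state is the minimal RT by
     which a subset can be completely acquired (earliest completion is
     the correct state by the usual exchange argument). Ties resolve
     toward earlier-finishing schedules, deterministically.
  2. **Large instances**: the relaxed sweep DP (prefix-best transition
     relaxation; ties toward larger accumulated intensity, then the
     lexicographically earliest window-start sequence). If the returned
     path revisits clusters, those clusters are masked exactly via a
     lazily grown bitmask and the sweep re-runs; a duplicate-free result
     is *certified* optimal because the relaxation only over-counts.
  3. **Fallback**: if the mask set outgrows its budget
     (windows × 2^masked > 2·10⁶), the planner takes the better of the
     repaired sweep path and an earliest-finish greedy and says so in a
     message — a feasible, deterministic schedule without an optimality
     certificate.

  Test ensembles exercise route 1 against an independent exhaustive
  oracle (`brute_force_optimum()`, which enumerates cluster orderings
  with greedy earliest-finish window selection — a different algorithm
  by construction).

### Iteration and outputs

`plan_paths()` removes every feature acquired by the current path and
replans until the requested number of paths is reached or a search
returns score 0 (remaining iterations are provably empty, so the loop
stops early rather than emitting empty paths). Exclusion is by whole
feature, not by used RT interval: the goal of follow-up injections is
breadth, and re-acquiring a feature in a different window adds no new
identification. Consequently per-iteration scores are nonincreasing and
the acquired feature sets are pairwise disjoint — properties the test
suite asserts on random ensembles.

`to_schedule_matrix()` bridges the continuous-time output back to the
binary $X_{t,i}$ formulation for validation: a bin belongs to a window
when the window covers the bin midpoint (so disjoint windows can never
collide in a discretization bin), and violations are reported naming the
broken constraint. Paths are separate injections, so the matrix is
validated per path while the objective counts distinct features across
all of them.

## Synthetic data: what it does and does not show

`generate_run()` emulates the preliminary MS1 experiment: Gaussian
elution profiles of configurable width on a regular scan grid, truncated
at $3\sigma$, apex heights log-uniform over a configurable range,
multiplicative log-normal intensity noise (intensities stay positive),
and optional background features flagged with blank-channel intensity.
Defaults — 0.5 s scan interval, $\sigma = 3$ s peaks, heights
$10^4$–$10^7$, 5% log-normal noise — are typical of reversed-phase
metabolomics gradients on a high-resolution instrument.

`simulate_dda()` is a deliberately minimal top-N simulator (per-scan
top-N selection with dynamic exclusion; no injection-time, charge-state
or isolation-purity modeling). It exists to measure *relative*
redundancy and coverage against the planner under identical synthetic
signals, not to emulate a specific instrument.

What passing tests show: the solver attains the true distinct-feature
optimum on small random instances, its schedules always satisfy the
acquisition constraints, iterative exclusion behaves as designed, and on
co-elution-heavy runs planned acquisition is dramatically less redundant
than replicated top-5 DDA. What they cannot show: behavior under
retention-time drift between injections beyond the $\Delta$ padding,
chimeric-spectrum effects, isotope/adduct redundancy, or real
instrument duty-cycle limits — all of which require instrument data.
The mzML ingestion of raw data is likewise out of scope; the package's
reference input is the tabular triplet/apex format.

## Problem sizes and numerics

The shipped validation uses 200 random oracle instances (≤ 6 clusters,
≤ 8 bins), 100-seed constraint and iteration ensembles, 50-seed
monotonicity and redundancy ensembles, and one 1000-feature run planned
into 5 paths (about 36 000 scan points; well under a minute on a single
core). Floating-point care: window boundary membership uses closed
padded intervals; binning nudges exact boundary points into the upper
half-open bin ($10^{-9}$ of a bin width); duration bounds carry a
$10^{-9}$ relative tolerance; path tables are written at full double
precision (`%.17g`) so write-then-read round-trips are exact.

## Known limitations

* Isolation-window overlap between co-eluting precursors is not
  modeled; apex-centered clustering only reduces, not eliminates,
  chimeric risk.
* The TIC model is global — no per-m/z stratification.
* On extremely interleaved instances the planner may return an
  uncertified (still feasible and deterministic) schedule; the message
  makes this visible.
* Vendor inclusion-list export is a fixed one-way column mapping
  (`format_inclusion_list()`); no vendor round-trip is attempted.
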