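---
title: "Models and methods behind meaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

`meaburst` turns per-unit spike-time recordings from cultured neuronal
networks on microelectrode arrays into a reproducible, multiparametric
activity phenotype, classifies phenotypes, and provides a ground-truthed
simulator to validate every stage. This vignette explains the underlying
models, the defaults and why they were chosen, the numerical conventions,
and what the validation suite does and does not establish.

## Time conventions and the analysis window

All times are real-valued milliseconds from recording start; every window
and bin is half-open, `[start, end)`, so each spike belongs to exactly one
bin. Spontaneous MEA recordings typically begin with a settling period, so
analysis is restricted to the *stable activity phase*, taken as the final
30 min of the recording (`select_stable_phase()`, configurable via
`analysis_window_policy()`). No stationarity test is applied — the tail is
taken as stable by convention; users with unstable recordings should
inspect rasters first. Per-bin statistics use 60 s bins; a trailing
partial bin is dropped everywhere, because rate estimates from partial
bins are biased (30 min divides evenly into 60 s bins, so nothing is lost
at the defaults). Units without spikes stay in the recording: they count
in network denominators such as participation fractions.

## Burst detection

Bursts are detected per unit by the classical two-threshold
(max-interval) reading of the interspike-interval method. The defaults —
maximum ISI to start a burst 40 ms, minimum ISI to end it 200 ms, minimum
interburst gap 100 ms, minimum duration 10 ms, minimum 2 spikes — are the
standard values for developing cortical cultures. Because the thresholds
alone do not fix an algorithm, the package pins these semantics:

- a burst is *seeded* by a spike pair with ISI ≤ 40 ms (hysteresis: an
  ISI in (40, 200) ms can extend an open burst but never opens one);
- once open, spikes are appended while ISI < 200 ms; an ISI ≥ 200 ms
  closes the burst at the last appended spike;
- consecutive bursts with gaps strictly below 100 ms are merged
  transitively *before* filtering, so a long burst split by one sparse
  gap is not discarded as two sub-threshold fragments;
- the duration and spike-count floors are applied last; burst start/end
  are the first/last member spikes, with no padding.

Boundary comparisons are `≤` for maxima, `≥` for minima, and strict `<`
for the merge gap. These choices are documented as the package's own, and
the test suite verifies them bit-exactly against an independent
brute-force scan-and-merge oracle on a thousand randomized trains. Note
that with the default thresholds the merge step is vacuous (any
inter-burst gap already exceeds the closing ISI); it matters when users
set `min_interburst_interval` above `min_isi_end`.

## The 204-feature registry

The descriptor engine computes 32 primary per-unit scalars — general
activity (spike counts and rates, ISI statistics, burst rate and period,
spike contrast, percent of spikes in bursts, tonic rate, burst duty) and
burst structure (duration, spikes per burst, spike density, the
profile-based amplitude/area/plateau/peak time, intra-burst ISI
statistics, and their within-unit CVs). Each primary is emitted in six
variants:

| variant | definition | category |
|---|---|---|
| (none) | mean over units of the per-unit value | the primary's own |
| `_sd` | SD across 60 s bins of the network-mean per-bin value | oscillation |
| `_cvtime` | mean over units of each unit's across-bin CV | oscillation |
| `_cvnet` | across-unit CV of the per-unit values | synchronization |
| `_binmax`, `_binmin` | extremes across bins of the network-mean per-bin value | oscillation |

plus 12 network-level synchronization features (Syn All and Syn share
with their CVs, event rate and count, population-burst duration, spikes,
period and period CV, hamming factor and its SD across pairs):
32 × 6 + 12 = 204. The composition of such commercial-scale feature sets
is conventionally proprietary; this registry is the package's explicit,
versioned choice (`feature_registry("v1")`), and feature tables are
comparable only within a registry version. Twelve canonical headline
parameters (three per category; `named_parameters()`) are guaranteed
present, and the suite checks they equal their standalone operations.

Network means of per-unit scalars average over the units that define the
value (e.g. only units with ≥ 2 bursts contribute an interburst interval;
the contributing count is reported by `general_activity()`). Degenerate
inputs yield `NA`, never silent zeros: a network without bursts has
missing burst structure, fewer than two complete bins make oscillation
metrics undefined, and fewer than two units make pairwise synchrony
undefined. One deliberate convention: all burst-structure network values
are unit means of per-unit means (not pooled over bursts), keeping every
"mean" variant consistent across the registry and invariant to which
units happen to burst most.

### Spike contrast

The spike contrast quantifies the alternation of spiking between
neighboring time segments. Each train is cut into consecutive 500 ms
segments; for adjacent pairs with `n_i + n_{i+1} > 0` the contrast is
`|n_i − n_{i+1}| / (n_i + n_{i+1})`, averaged over pairs and then units.
The absolute value is implementation-defined (it depends on the segment
length); only within-pipeline comparisons are meaningful.

### Burst profiles (amplitude, area, plateau)

Each burst's instantaneous rate is estimated by summing unit-mass
Gaussian kernels (bandwidth 10 ms, grid step half a bandwidth) over its
spike times, aligned at burst onset. The per-unit profile is the mean
over that unit's bursts; its peak is the *burst amplitude* (Hz), its
integral the *burst area* (the smoothed spike count), and the contiguous
region around the peak at ≥ 90 % of the peak the *burst plateau* (ms).
Per-bin variants average the per-burst profile features of bursts
starting in the bin. A 10 ms bandwidth resolves intra-burst structure at
the typical 10–20 ms intra-burst ISI without merging adjacent spikes into
a flat plateau.

### Population bursts, events, and the hamming factor

A sliding coincidence window of 300 ms counts units with a burst
overlapping the window; maximal regions where that count reaches 50 % of
all units (both configurable) become population bursts, overlapping
regions merged. The population-burst *center* is the spike-count-weighted
mean of member-burst midpoints; *Syn All* is the mean absolute distance
of member midpoints from the center (reported raw in ms — smaller means
tighter synchrony; the package does not invert it into a score), and
*Syn share* is the mean participating fraction. The same detector at the
50 %/300 ms setting defines *events*, so event rate, Syn All and Syn
share share one mechanism. The hamming factor reduces each unit to a
binary occupancy vector over 10 s bins (1 = some burst overlaps the bin)
and reports the mean pairwise agreement `1 − d_H / n_bins`; the pairwise
mean (rather than distance to a template train) makes the measure
symmetric in the units. It is exactly 1 iff all occupancy patterns are
identical.

## Classification

Feature vectors are standardized per fold by the training subset's mean
and SD; zero-variance features are dropped identically across folds and
missing values imputed by the training mean (with a logged count), so the
held-out sample never leaks into the transformation. The classifier is a
single-layer feed-forward perceptron — no hidden units, which is the
appropriate capacity for high-variance biological feature tables with
tens of samples — with one logistic output per group, one-hot targets,
summed cross-entropy loss, and arg-max prediction. Training uses
resilient propagation in its simplest canonical form (Rprop without
weight-backtracking): per-weight step sizes start at 0.1, grow by 1.2
while the gradient sign persists, shrink by 0.5 on a sign flip, clamped
to [1e−6, 50]; only the gradient sign enters the update. Weights
initialize uniformly in [−0.1, 0.1] from a seeded generator and the
whole train/validate path is bit-reproducible given the seed. Training
stops at a loss change below 1e−6 or 1000 epochs.

Cross-validation defaults to leave-one-out — the natural choice for
cohorts of a dozen networks per group — with label-balanced k-fold
available. Groups reduced to a single sample proceed with a warning; a
fold whose training set lacks a group keeps that output node with
all-zero targets rather than silently renumbering classes. The
recognition matrix is tested with a χ² goodness-of-fit against uniform
chance within each true-group row (50 % per cell for two groups), with
`df = rows × (cols − 1)`; group-size-proportional expectations are
available as an option. Two-group comparisons are run as separate
two-class problems by default; a single multi-class net over four groups
is supported by the same code path (`n_outputs` follows the labels).

## Group statistics and morphometry

`compare_groups()` reports mean ± SEM per group, treatment as percent of
control, and an unpaired Student's t-test — pooled variance by default
because that is what "Student's t-test" names, with Welch behind a flag.
No multiple-testing correction is applied by default, mirroring
per-parameter reporting practice in this field; a Benjamini–Hochberg
column is available and recommended whenever all 204 features are
screened. Normality is not re-tested per comparison; a Shapiro–Wilk
diagnostic report is optional output only. Morphometry ratios
(`morph_derive()`) validate the count hierarchy (neurons ≤ cells,
GABAergic neurons ≤ neurons) and return `NA` for zero denominators.

## The stimulus-envelope model

Exposure protocols of the pulse-modulated kind are represented by their
modulation envelope only: a carrier frequency (150 MHz by default) is
metadata, since synthesizing a 150 MHz waveform serves no analysis
purpose, while the on/off timing is the computable content. A modulation
frequency `f` with duty `d` gives cycles of `1000/f` ms with an on-phase
of `d·1000/f` ms — at 50 % duty: 100/50 ms at 10 Hz and 62.5/31.25 ms at
16 Hz — concatenated over sessions (default: 30 min at 10 Hz, then
30 min at 16 Hz). A final cycle cut by the session end is emitted
truncated rather than dropped, preserving total on-time at `duty ×
duration` up to one truncated cycle.

## The synthetic generator

`generate_network()` draws population events as a homogeneous Poisson
process; each unit joins an event with a participation probability, its
burst onset jittered by a Gaussian; burst spike counts are 2 plus a
Poisson draw (enforcing the 2-spike floor), intra-burst ISIs are
gamma-distributed; independent per-unit bursts and tonic Poisson
background complete the train. Exact duplicate spike times are dropped
(not jittered) to keep trains strictly ascending. Defaults portray an
active culture around two weeks in vitro: 24 units, 30 min, 0.1 Hz
events with 0.8 participation and 0.02 Hz independent bursts (≈ 6
bursts/min/unit), 12-spike bursts with 15 ms mean ISI (≈ 165 ms
duration), 0.3 Hz background (≈ 1.5 Hz unit spike rate), 50 ms onset
jitter. `maturation_profile(28)` doubles the event rate and roughly
triples the spike rate, emulating the maturation trajectory over which
bursting roughly doubles and spiking triples between two and four weeks
in vitro. Treatment effects are multiplicative on any driver;
`spike_driver_multipliers(1.5)` raises background rate and spikes per
burst by 50 %, which raises the expected unit spike rate by exactly 50 %.

The generator reproduces the *statistical shape* of developing-network
activity — burst-dominated firing, tunable synchrony, realistic rates —
but not several features of real data: no slow non-stationarity within a
recording, no electrode noise or sorting errors, no refractory structure
in the background process, no within-network heterogeneity of unit rates
beyond sampling noise, and no biophysics linking any stimulus to
activity. Validation against it therefore establishes that the pipeline
measures what the generative model plants, at realistic scales — not
that any specific biological effect size will be reproduced.

## Validation problem sizes

The test suite validates the detector against a brute-force oracle on
1,000 random 30 s trains; parameter recovery on 100 simulated cohorts of
12 + 12 networks (30 min, 24 units) with a ×1.5 spike-driver effect,
expecting significant recovery in ≥ 95 runs, plus 100 null cohorts
expecting a 5 % ± 3 pp rejection rate; classifier power on 24-sample,
204-feature cohorts with a 1-SD shift in 20 features against 20
label-permuted replicates; statistical oracles on 100 random cases at
1e−10; and byte-identity of repeated pipeline runs on 10-network
bundles. Smaller networks (4–12 units, 2–7 min) are used where the check
concerns contracts rather than statistical power.

## Known limitations

- The "stable phase" is positional, not tested; strongly drifting
  recordings will bias temporal-variability features.
- Spike contrast and the profile-based amplitude/area/plateau have
  implementation-defined absolute scales; compare them only within a
  registry version.
- Syn All is reported raw (ms); its direction is *inverse* to synchrony
  strength, which is easy to misread in heatmaps.
- The χ² construction assumes independent classification outcomes across
  cross-validation folds; leave-one-out folds share most training data,
  so p-values are approximate and best used comparatively.
- Hierarchical on-disk storage uses R's native serialization; it is
  compact and exact but not language-neutral — use the tabular layout
  for interchange.
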