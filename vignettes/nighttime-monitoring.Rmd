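---
title: "Nighttime monitoring with active rules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nighttime monitoring with active rules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightwatch)
```

`nightwatch` implements an event-driven pattern for home health
monitoring of a single older adult living alone: sensor streams are
inserted into in-memory tables, event-condition-action (ECA) triggers
react to each insert, and three services consume the resulting events —
bed presence/absence detection, transition mining, and early-night
behaviour classification. This vignette explains each model, its
assumptions and tunable parameters, the design choices where the design
was genuinely open, and what the bundled simulator does and does not
emulate.

## The active-rule engine

The engine (`eca_engine()`) models the substrate the services run on:
tables with AFTER-INSERT row triggers, bounded FIFO tables whose
engine-assigned `sample_id` wraps around in `1..capacity`, and named
publish/subscribe channels. Semantics are deliberately single-threaded
and synchronous — triggers fire inline in registration order and
notifications are delivered immediately in subscription order — so that
identical input streams always produce identical outputs. Whether
trigger actions should run inside or after the triggering insert is an
open design point in event systems; inline execution was chosen because
determinism matters more here than throughput, and a failing action
therefore does not undo the insert (remaining triggers still run, the
first error is re-raised afterwards).

The canonical use is the half-second presence rule: load-cell samples
arrive at 80 Hz into a FIFO table of capacity 40, a trigger with
condition `sample_id == 40` fires on every wrap-around — every 40th
insert, i.e. every half second — and its action evaluates the window
just completed.

## Bed presence from windowed load-cell statistics

A strain-gauge load cell under one bed leg reports a signed integer ADC
value; dividing by the calibration ratio (−41943 counts/kg for the
modelled hardware) gives kilograms. Body movements disturb the signal
while the bed is occupied, so over non-overlapping 40-sample windows
both the median weight $m_w$ and the (population) standard deviation
$\sigma_w$ form two clusters: occupied and empty. The presence rule is
the inclusive conjunction

$$\mathrm{Presence} = (\sigma_w \ge O_{\sigma_w}) \wedge (m_w \ge O_{m_w}),$$

with per-resident thresholds found by the Otsu algorithm, which places
the cut maximising the between-class variance
$\sigma_B^2 = \omega_0\,\omega_1\,(\mu_0-\mu_1)^2$.

Numerical choices worth knowing:

* **Location statistic.** The rule's location statistic is the window
  *median* (robust to short spikes); the mean is also computed and
  exposed. Descriptions of such rules sometimes conflate the two — the
  median is what `bed_presence()` tests.
* **Population standard deviation** (denominator $n$) is used: the
  window is a fixed-size signal block feeding a binarisation, not a
  sample from a larger population.
* **Otsu candidates and ties.** Values are binned into 256 uniform bins
  over `[min, max]`; every interior bin boundary is a candidate cut and
  ties break toward the smaller threshold. Class moments are computed
  from exact per-bin value sums, not bin centres, so the objective at
  each candidate equals a from-scratch recomputation on the raw values.
  When the two clusters are separated by an empty gap the objective is
  exactly flat across the gap and the returned threshold is the lowest
  boundary in it; any threshold in the gap induces the same
  classification, which is why the package's property tests compare
  induced partitions rather than raw thresholds.
* **Degenerate calibration.** Calibration refuses unimodal data: it
  requires Otsu's effectiveness measure (between-class over total
  variance) to reach 0.8 for both statistics. A unimodal Gaussian tops
  out near 0.64, clearly separated clusters approach 1, so 0.8 rejects
  single-cluster nights while tolerating the heavy right tail that
  movement bursts add to $\sigma_w$. The calibration period is
  configurable; the default used by `run_pipeline()` is the first full
  night, which must contain both occupied and unoccupied intervals.
* **Debounce.** `bed_detector()` accepts a confirmation count; the
  default is 1 (every half-second decision counts) because the modelled
  rule has no hysteresis. The first window of a night only initialises
  the state and emits nothing, since any convention for counting the
  initial assignment would be arbitrary. Nights are processed
  independently; no state crosses the 6 a.m. boundary.

## Mining nighttime transitions

The transition miner estimates, online, the first-order conditional
probabilities $P_{ij} = P(e_j \mid e_i)$ between consecutive events
over the alphabet {Ba, K, H, L, I, D, Bin, Bout}, together with the
mean and standard deviation of the inter-event time per ordered pair —
Welford's streaming algorithm, so a single pass equals a two-pass
recomputation to floating-point accuracy (the tests assert 1e−9
relative). Conventions chosen where none is canonical:

* repeated identical symbols closer than 30 s merge into one event
  (PIR sensors retrigger while a person stays in a room); the merged
  event keeps the first firing's timestamp. Self-transitions beyond the
  gap are real and are counted.
* $\sigma_t$ uses the sample ($n-1$) variance and is undefined (NA) for
  a single observation.
* transitions never cross night boundaries, matching the sensors' 10
  p.m.–6 a.m. duty cycle.
* the graph export keeps edges with $P_{ij} \ge 0.2$ by default — the
  threshold that leaves a resident's habitual routes visible — and
  orders nodes and edges by the fixed alphabet so output is
  deterministic. Per-edge time statistics label each edge.

Bed events fed to the miner should come from the load-cell detector
rather than the film-type bed sensor, whose miss rate (about 60% of
exits in the modelled deployment) badly distorts any row involving
`Bout`.

## Early-night behaviour classification

Each night is divided at midnight: windows starting before midnight are
labelled `TPI` (time period I, 10 p.m.–midnight), the rest `!TPI`. A
20-minute window stepping by its own width over the 8-hour night gives
24 windows per night — 6 of them TPI — and 336 observations over a
14-night study; the default grid is anchored at 10 p.m., so no window
straddles midnight. The step equalling the width is a choice: the
window is described as "sliding" in this family of methods but a
non-overlapping grid keeps observations disjoint and already yields the
intended dataset size.

The 15 features per window are: the symbols of the last four events
(most recent first, `N` when fewer are available), the elapsed times
$Et(t,t-k)$, $k = 1..3$, between the latest event and its three
predecessors, and the count of each of the eight event types. "No
events" is expressed by `N` slots plus all-zero counts rather than a
ninth count — the only composition that yields exactly 4 + 3 + 8 = 15.
A missing $Et$ (fewer than $k+1$ events) is coded as the window width
in seconds (1200), a "nothing earlier in this window" sentinel whose
missingness is already carried by the matching `N` slot; fractional
(missing-value) splits are deliberately not implemented.

The classifier is C4.5 grown from scratch: at each node every attribute
proposes its best candidate (numeric: the midpoint cut between sorted
distinct values with maximal information gain; categorical: one branch
per observed value), candidates below the mean gain of all candidates
are discarded, and the highest gain ratio wins. Ties break by attribute
declaration order, then toward the smaller threshold, making the tree
invariant to observation order. Growth stops on purity, depth 10, fewer
than `2 * min_leaf` cases, or no positive gain; `min_leaf` defaults
to 5. No post-pruning is applied. At prediction time an unseen or
missing categorical value routes to the majority child. Cross-validation
is stratified by class with an explicit seed; stratification is a
choice (it reduces fold-accuracy variance on the 25/75 label split) and
is not claimed to match any particular reference implementation.

## The night simulator

The simulator exists because the original study's data cannot be
shipped; it generates nights that are *structurally* faithful so every
service can be tested end to end against known ground truth.

A resident is a semi-Markov process over {Bed, bathroom, kitchen,
hallway, living room}: next states are drawn from a planted
row-stochastic matrix (the recovery target of the transition tests),
dwell times are truncated normals per state, and the gap between
leaving a state and the next room event is a truncated normal per
origin — 7 ± 7 min out of bed, the headline bathroom-transit statistic
of the modelled deployment, 30 ± 15 s between rooms. Because room
events fire at state entry, that out-of-bed gap — not the bathroom
dwell — is what the miner's `Bout → Ba` time statistic measures.

Two notes on the truncated normals. Dwells and gaps must be positive,
so samples are drawn from a normal truncated at zero with the
configured (μ, σ) as the *pre-truncation* parameters. For strongly
positive parameters the truncation is negligible, but for 7 ± 7 min it
is not: the realised mean is ≈ 9.0 min and the realised sd ≈ 5.4 min.
Re-parameterising so the realised moments equal (7, 7) is impossible —
a lower-truncated normal always has coefficient of variation below 1 —
so the package keeps the pre-truncation convention and its tests verify
empirical moments against the closed-form truncated moments.

Early-night behaviour (before midnight) differs from the rest of the
night only through dwell modulation: evening bed visits are short naps
(5 ± 2.5 min) while bed dwells after midnight are consolidated sleep
bouts (180 ± 60 min). This plants the TPI structure — elevated room
activity before midnight, stillness with occasional bathroom trips
after — without touching the transition matrix, so transition recovery
and classifier tests share one generative model. The wearable
inactivity sensor emits `I` every 5 min of uninterrupted bed stillness,
which is what makes sleep windows recognisable; evening naps are too
short to trigger it.

The load cell carries 25 kg on the instrumented leg when occupied with
2 kg movement noise plus one ~1 s burst per minute (amplitude 2 kg),
against a 0.4 kg tare and 0.02 kg noise when empty. These amplitudes
are nominal — the fraction of body weight resting on one leg is not
reported for the modelled hardware — but they reproduce the
characteristic bimodal window statistics; they are configuration, not
code. ADC values are `round(weight × ratio)`. The film-type bed sensor
is emulated by dropping each true `Bout` with probability 0.6
(configurable, plus optional spurious exits); its random stream is
seeded independently of the trajectory and load cell, so changing only
the Emfit parameters leaves the ground truth byte-identical.

What the simulator does **not** emulate: physiological signal structure
(breathing, sleep stages), sensor drift and recalibration, multiple
residents or pets, door traffic (night patrols are off by default), and
real behavioural nonstationarity across nights. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
assumptions, not field performance: in particular the near-perfect
detector F1 reflects the clean separation the generator plants, and the
reported cross-validated accuracy (~0.85–0.92 against a 0.75 majority
baseline at the default settings) measures recovery of the planted
early-night structure, not of any real resident's routine.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run
on a laptop in about a minute: bed-presence recovery uses 3 nights of
full 80 Hz signal (2,304,000 samples each), transition recovery uses
10,000 events from a planted 8-state chain plus ~250 nights of
trajectories, and the classifier checks use the default 14-night study
(336 windows). Every random quantity — trajectories, noise, bursts,
Emfit drops, CV folds — derives from one scenario seed through fixed
child streams, so any result in the pipeline's `metrics.json` is
reproducible byte for byte from the scenario and seed alone.
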