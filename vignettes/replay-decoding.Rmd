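---
title: "Decoding replay dynamics with a switching state-space model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding replay dynamics with a switching state-space model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replayssm)
```

## The model and its assumptions

Hippocampal replay is usually studied by decoding position from spikes in
20-ms-or-wider time bins and fitting a constant-speed line to the result.
That procedure presumes that a replay event *is* a constant-speed
trajectory. `replayssm` instead treats the represented position `x_k` and a
discrete movement dynamic `I_k` as joint latent states of a switching
state-space model evaluated every 2 ms, and estimates
`p(x_k, I_k | O_{1:T})` for an entire event by a forward (causal) filter and
a backward (acausal) smoother on a discretized track.

Three movement dynamics are modeled through their one-step position
kernels:

* **stationary** — the identity kernel: the position cannot change between
  2 ms steps;
* **continuous** — a Gaussian random walk with variance 6.0 cm² evaluated on
  pairwise *graph* distances between position bins, so mass propagates along
  the track, never across physical gaps. Two standard deviations are 4.90 cm
  per 2 ms step, i.e. latent speeds up to roughly 25 m/s are reachable —
  replay is known to run an order of magnitude faster than the animal;
* **fragmented** — a uniform kernel: the position may jump anywhere
  instantly, a well-specified null for spatially incoherent activity.

Transitions *between* dynamics use the kernel of the pair: entering
stationary uses the identity, entering continuous the random walk, and any
pair involving fragmented the uniform kernel (once coherence is lost,
nothing constrains where it resumes). The discrete chain keeps its dynamic
with probability 0.98 per step; with 2 ms steps that geometric dwell has a
100 ms mean, about the duration of a sharp-wave ripple. The data dominate
this weak prior: decoded transitions sharpen within ~10 ms, and the decoded
labels are unchanged for stay probabilities between 0.96 and 0.993 (checked
in the test suite). Initial conditions are uniform over dynamics and
position.

Both observation models assume the likelihood is dynamic-independent.
Sorted spikes use a Poisson likelihood whose rate maps come from a per-cell
GLM: log-link, cubic B-spline bases over linearized position with knots
every 5 cm (built per track arm, so bases never bridge the 15 cm layout gaps
between arms), and an L2 penalty of 0.5 on the spline coefficients,
maximized by Newton–Raphson. Clusterless decoding skips spike sorting: each
tetrode's spikes carry a 4-channel peak-amplitude mark m⃗, and Gaussian
product-kernel density estimates of the occupancy π(x), spike occupancy
p_i(x), and joint density p_i(x, m⃗) define the joint mark intensity
λ_i(x, m⃗) = µ_i p_i(x, m⃗)/π(x) and ground rate Λ_i(x) = µ_i p_i(x)/π(x).
Both encoders are fit on movement periods only (speed > 4 cm/s), when place
fields are expressed.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| time bin | 2 | ms | decoding resolution; silence between spikes is informative |
| position bin | 3 | cm | grid for Riemann sums; resolves the 6 cm² random walk |
| random-walk variance | 6.0 | cm² | "spatially close" for the continuous dynamic |
| stay probability | 0.98 | — | 100 ms expected dwell per dynamic |
| spline knot spacing | 5 | cm | place-field smoothness (sorted) |
| L2 penalty | 0.5 | — | stabilizes low-count GLM fits |
| position / mark bandwidth | 6.0 / 24.0 | cm / µV | KDE kernel SDs (clusterless) |
| classification threshold | 0.80 | — | "highly probable" cut for the five categories |
| movement threshold | 4 | cm/s | encoding-period selection and event gating |
| SWR detection | z = 2, 15 ms | — | permissive consensus-power threshold |

The classification threshold is read strictly ("above 0.80"): a bin is
stationary/continuous/fragmented when that dynamic's probability exceeds
0.80, a stationary-continuous or fragmented-continuous mixture when the pair
sum exceeds it (mixtures always include continuous; if both pairs qualify
the larger sum wins, ties to the stationary side), else unclassified. A
marginal of (0.5, 0.3, 0.2) — pair sum exactly 0.80 — is therefore
unclassified. Raising the threshold to 0.95 only ever removes
classifications (tested as a monotonicity property).

## What the synthetic data emulate

The simulation module generates every input the model consumes, under the
study's standard conditions:

* **Encoding runs** — 19 cells with Gaussian place fields (variance 36 cm²,
  i.e. SD 6 cm; 15 Hz peak; 10 cm spacing) on a 180 cm track, spiking as an
  inhomogeneous Poisson process along 15 constant-speed traversals. The
  traversal speed is not pinned down by the study conditions; the default is
  15 cm/s, a typical rat running speed (close to the 17 cm/s median reported
  for run periods on the W-track). Faster or slower traversals change the
  spike count per field, not the field shape.
* **The three-segment test sequence** — 60 ms of a single repeatedly firing
  cell (stationary; an interior cell by default, so its Gaussian field is
  fully expressed on the track), 190 ms of cells firing in spatial order as
  a trajectory sweeps the whole track (continuous), 30 ms of uniformly
  random cells (fragmented); one spike per 2 ms bin. Deterministic given
  the seed. Because the sweep starts at the track end, away from the
  stationary field, the stationary-to-continuous hand-off is identifiable
  to within a couple of time bins; a sweep emanating from the stationary
  position itself would be ambiguous ("switched already but barely moved"
  fits the same spikes) and the decoded switch point smears backward by
  10-20 ms.
* **Constant-speed sweeps** — one traversal per requested speed, each cell
  spiking exactly when the trajectory crosses its field peak; used to map
  dynamic probabilities against trajectory speed.
* **Marks** — isotropic Gaussian clusters in the 4-D amplitude space, means
  on a lattice separated by ≥ 3 mark bandwidths so the clusterless encoder
  can resolve them (synthetic; real marks come from recording hardware).
* **LFP** — broadband noise plus Hann-windowed ripple-band bursts, for
  testing the SWR detector against known injected intervals.

What these do **not** emulate: theta sequences, behavioral task structure,
realistic waveform shapes, interneurons, electrode drift, or correlated
noise across tetrodes. Passing tests on these data show the estimator
recovers known ground truth under its own generative assumptions — they do
not certify performance on real recordings, where encoding models are
misspecified and events are not cleanly segmented.

## Numerical choices

* All likelihoods are computed in log space; the filter subtracts the
  per-slice maximum before exponentiating and renormalizes every slice,
  accumulating the log normalizers into the event's log evidence
  (per-slice scaling rather than log-space matrix products, for speed with
  exactness).
* The backward pass uses the two-filter ratio form — acausal ∝ causal ×
  Σ ∫ kernel × discrete transition × acausal(k+1) / predictive(k+1) — with
  zero-predictive terms contributing zero; it reproduces brute-force path
  enumeration to 1e-10 on small instances and equals the causal estimate at
  the final bin by construction.
* Random-walk kernel rows are renormalized after evaluating the Gaussian on
  graph distances, so probability does not leak off the track ends;
  integration uses true bin widths (a track arm whose length is not a
  multiple of 3 cm gets one narrower final bin, anchored at the arm start).
* KDE bandwidths are Gaussian kernel SDs, with no boundary renormalization
  (plain product-kernel form); this leaves a mild density deficit within
  ~2 bandwidths of the track ends. Densities are floored at 1e-15 before
  division so intensities stay finite in never-visited bins.
* Newton–Raphson starts at the log mean rate, stops at gradient ∞-norm
  < 1e-6 or 100 iterations (documented defaults; the convergence tolerance
  is not externally prescribed), and halves the step on any penalized
  log-likelihood decrease.
* HPD regions use the descending-sort construction (smallest set of
  highest bins reaching 95% mass); exact ties break toward lower bin index.
  MAP ties likewise take the lowest bin index.
* The linearization HMM's transition matrix is only qualitatively
  specified upstream; this implementation uses a Gaussian penalty (SD =
  the 5 cm observation SD) on the mismatch between along-graph and
  Euclidean frame-to-frame displacement, plus the stated 0.1 diagonal
  bias, row-normalized — a documented substitute.
* The Radon significance shuffle circularly shifts each 20 ms bin's
  position distribution independently (the conventional column-cycle
  null); a common-offset variant is available via `shuffle = "common"`.
  The common-offset null preserves zero-slope structure exactly and
  therefore can never reject for stationary events, which contradicts
  their observed detectability, so it is not the default.
* The filter/smoother recursion is compiled (RcppArmadillo): a 1 cm/s
  constant-speed traversal spans 90,000 two-ms bins, and the sweep
  analysis decodes dozens of such events.

## Problem sizes used by the tests and acceptance script

Encoding fits use 15 traversals (~90,000 two-ms samples); the three-segment
decode is averaged over 10 independent simulations and the place-field
recovery over 20; the speed sweep decodes 50 constant-speed sequences
logarithmically spaced from 1 to 10,000 cm/s; the shuffle contrast uses a
5-seed resampling ensemble against the matched unshuffled run. These sizes
were chosen so each analysis stabilizes its reported quantity (Monte-Carlo
SE well inside the assertion tolerances) while the whole suite remains
quick to run.

## Design choices where the design was open

* **Speed sweep construction**: the sweep takes the speed list as an
  argument rather than fixing one of the two plausible published readings
  (10,000 trajectories from 1 cm/s vs 20,000 from 0.5 cm/s); tests use 50
  log-spaced speeds spanning the same 1–10,000 cm/s range.
* **Fragmented segment generation**: active cells are drawn uniformly per
  2 ms step, the minimal reading of "random, out of spatial order".
* **Mean HPD size per event** averages over all event bins; a
  classified-bins-only variant is available through the per-category
  field of `summarize_event`.
* **Replay speed** uses the absolute value of the Gaussian-smoothed MAP
  gradient (replays may reverse direction; only magnitude is reported),
  and only classified periods longer than 20 ms are summarized — with 3 cm
  bins and 2 ms steps, slower speeds are not resolvable within a shorter
  window, and below ~38 cm/s a within-segment MAP track does not move at
  all, so estimated segment speeds tie at zero there.

## Known limitations

* Real-data ingestion (multi-session recording formats, spike sorting,
  video tracking) is out of scope; positions, spikes, marks, and LFP arrive
  as arrays/CSV.
* The clusterless encoder stores its training samples (it is a kernel
  method); very long encoding sessions cost memory proportional to spike
  count.
* 2D decoding is supported structurally (occupancy-masked grids with
  BFS distances) but the spline encoder demonstrates 1D fits; tensor-spline
  2D fields are not exposed.
* The classification threshold partitions a continuous quantity; boundary
  cases (pair sums near 0.80) are sensitive to encoder bandwidths, which is
  why the threshold is configurable and the 0.95 check exists.
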