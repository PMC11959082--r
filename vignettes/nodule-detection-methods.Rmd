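---
title: "Methods: swarm-tuned recurrent detection of pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swarm-tuned recurrent detection of pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulekit)
```

nodulekit is a desk-scale CAD pipeline for pulmonary nodules in 2-D CT
slices. This vignette records the models, the tunable parameters with
their defaults and units, the numerical choices, and the places where the
design was genuinely open — in enough detail that a reader can predict
what the code does without reading it.

## Morphological lung-field segmentation

`segment_lobes()` isolates the two lung fields by a fixed six-step
morphological chain: Otsu binarization with the lung taken as the dark
class (air is radiolucent, so lung fields are dark against soft tissue);
removal of blobs connected to the image border; 8-connected component
labelling; retention of the two largest components; erosion with a
Euclidean disk of radius 2 px (detaches vessel-linked structures);
closing with a disk of radius 10 px followed by hole filling
(re-attaches wall-adherent nodules and recovers the bright nodule
"holes" punched into the dark field by binarization). The chain has no
randomness. Connectivity, the disk definition (distance ≤ radius) and
the dark-class convention are pinned and tested rather than left to the
backing library's defaults. Slices with fewer than two surviving
components keep what they have with a warning (single-lung slices are a
real occurrence); a slice with none is an error, not an empty mask.

`extract_roi()` is element-wise masking: pixels outside the lobe mask
are exactly zero, pixels inside are unchanged. The rest of the pipeline
only ever sees this product image.

## Fuzzy C-means segmentation

`fcm_cluster()` minimizes the weighted squared error
$D(W,C)=\sum_{i=1}^{c}\sum_{k=1}^{n} w_{ik}^{x}\,\lVert h_k-d_i\rVert^2$
by alternating the membership update
$w_{ik}=1\big/\sum_{j}\left(\lVert h_k-d_i\rVert/\lVert h_k-d_j\rVert\right)^{2/(x-1)}$
with the fuzzified weighted-mean center update. Defaults: fuzzifier
`x = 2` (dimensionless; `x = 1` is rejected because the update
degenerates to hard assignment), convergence when the maximum center
displacement drops below `1e-5` in feature units, at most 300
iterations. The objective is recorded each iteration and is non-increasing
(the classical alternating-optimization argument); the test suite asserts
this on every seeded run it performs. A point coinciding with a center
receives full membership there (the limit of the update), ties toward
the lowest cluster index; a cluster that loses all membership weight is
re-seeded at a random data point with a warning. Generic clustering
initializes centers at `c` distinct random data points under the
configured seed.

`segment_nodules()` clusters per-pixel feature vectors of the in-mask
region — intensity alone by default, optionally augmented with
per-pixel backbone channels (Gaussian-smoothed intensity and gradient
magnitude at scales 1 and 2 px) — and takes the argmax-membership
cluster with the highest mean intensity as the nodule candidate, since
nodules are bright against parenchyma. Two deliberate choices here:

* **Initialization.** Nodules occupy a fraction of a percent of the
  lung, and fuzzy C-means started from two random points of such an
  imbalanced sample almost always splits the dominant parenchyma noise
  mode instead of isolating the bright minority. Starting centers are
  therefore the data points nearest to intensity targets spread from the
  in-mask *median* (the parenchyma mode) to the in-mask maximum.
  Anchoring the dark center at the minimum instead of the median is not
  safe: the first update then leaves part of the noise attached to the
  bright center and drags it inward.
* **Detection guard.** Selecting the brightest cluster must not
  manufacture a nodule out of pure noise. Under a noise-only null the
  two fuzzy centers of a Gaussian intensity field settle roughly 1.5–1.7
  standard deviations apart (the fuzzy analogue of the 2-means split of
  a Gaussian at ±0.8σ); a genuine nodule separates the centers by the
  lung–nodule contrast, an order of magnitude more. The bright cluster
  is therefore accepted only when the center gap exceeds
  `min_gap_factor = 2.5` robust standard deviations (1.4826 × MAD) of
  the in-mask intensities; otherwise the slice is declared nodule-free
  and the mask is empty. MAD rather than SD keeps the estimate anchored
  to the parenchyma mode even when a large nodule inflates the spread.
  The threshold comes from this null analysis, sits between the two
  regimes with wide margins on both sides, and is exposed in the
  configuration.

Accepted masks are split into 8-connected candidate regions (specks
under 9 px dropped) which are the pipeline's detection unit; vessel-like
clutter that legitimately joins the bright cluster separates from the
nodule at this step.

## Descriptors

All descriptors share one pinned neighbourhood convention: neighbour
`n = 0` sits east of the centre and the index runs counterclockwise
(E, NE, N, NW, W, SW, S, SE). Any fixed convention works; this one is
asserted against brute-force oracles in the tests.

**Statistical moments.** `statistical_features()` returns population
(biased) moments in the fixed order mean, kurtosis, skewness, standard
deviation, variance; kurtosis is non-excess (`m4/m2²`, so a Gaussian
scores 3 and the three-point sample `{1,2,3}` scores 1.5). A
zero-variance region defines skewness and kurtosis as 0. Population
rather than sample moments is a reproducibility pin, not a statistical
claim — regions are hundreds of pixels, where the distinction is
negligible.

**LTP.** Each neighbour difference `A = J_n − J_c` maps to a ternary
digit: +1 for `A ≥ τ`, 0 inside the open dead zone `(−τ, τ)`, −1 for
`A ≤ −τ`; assigning the boundary `A = −τ` to −1 makes the three cases
partition the line. The usable representation is the conventional
upper/lower split into two binary codes (`Σ 2^n` over +1 digits and over
−1 digits); the literal signed ternary sum `Σ b·3^n` is also returned,
but it is not a base-3 code (digits are negative) and is not
histogrammed. The threshold τ is in the image's intensity units; the
default 0.05 is sized for [0, 1] images with noise σ ≈ 0.03, i.e. the
dead zone absorbs ~1.7σ of noise.

**LOOP.** The eight Kirsch directional kernels (+5 on the three border
cells toward the neighbour, −3 elsewhere, zero centre — coefficients sum
to zero, hence invariance to global intensity offsets) are evaluated on
the 3×3 window. Each neighbour's bit weight is `2^(u_N)` with `u_N` the
rank of its Kirsch response magnitude (0 = smallest … 7 = largest, ties
broken by neighbour index), and the bit itself is `1` when the neighbour
is at least as bright as the centre. The sum runs over all eight
neighbours, so a constant window scores exactly 255. Rank-based weight
assignment is what gives the descriptor its rotation robustness.

**Histograms.** Codes are computed at every in-mask pixel whose full
3×3 window lies inside the image, histogrammed over 0..255, rebinned to
`histogram_bins = 32` equal-width bins and normalized to sum 1 (an empty
region yields an all-zero histogram with a warning). Histograms are
computed over the candidate region only, not the whole ROI: the
boundary-to-interior code mix is exactly the size/irregularity signal
the classifier needs, and whole-ROI pooling would dilute it.

**Backbone.** Deep pretrained feature extractors are out of scope; the
backbone is a pluggable interface with a handcrafted default,
`backbone_filter_bank()`: mean and population SD of the image smoothed
at Gaussian scales 1 and 2 px and of the gradient magnitude at the same
scales — 8 numbers, deterministic, near-invariant to small spatial
shifts (pinned in a test at `1e-3` L2 for a 6-px shift of a clean disc).
In the pipeline it is applied to the candidate's bounding box padded by
2 px. The final classifier input is the fixed-order concatenation
`E = [backbone, moments, LTP-upper ‖ LTP-lower ‖ LOOP]`, reversible by
`split_features()`.

## The swarm optimizer

`cho_optimize()` maximizes a box-bounded objective with a population of
`pop_size = 30` members over `t_max = 200` iterations (minimization is
wrapped by negation). Each iteration draws the time-control value
$\zeta(t) = \lvert(1 - t/t_{\max})(2r_2 - 1)\rvert$ once; each member
then explores when a fresh uniform draw exceeds $1-\zeta$ and exploits
otherwise, so exploration fades linearly in expectation and
$\zeta(t_{\max}) = 0$ exactly.

*Exploration* (ocean-current foraging):
$B' = V_F\,\alpha_i + \varpi_F B + \tfrac{1}{2}\big(B + r_3 (B_G - a\mu)\big)$
with differential fitness $\alpha_i = F(B) - F(B_G) \le 0$, foraging
speed $V_F = 0.02$, recursive factor $r_3 \sim U(0.1, 1)$, trial factor
$a = 3\,U(0,1)$ and $\mu$ the swarm mean.

*Exploitation* (induced movement):
$B' = B + \gamma r_4 (U_{up}-U_{low})(1 - t/t_{\max})^2 +
\tfrac{1}{2}\big(B_G \odot \varphi_B + \varpi_n (B - B_{prev})\big)$
with sensitivity $\gamma = 0.1$, $r_4 \sim U(0,1)$ per dimension, and
$\varphi_B$ the sum of a local effect (every member's normalized fitness
change times its normalized displacement, both denominators guarded by
$\varepsilon = 10^{-10}$) and a target effect (the same construction
with the global best standing in for the neighbour; switchable to zero).
A flat swarm — worst fitness equal to best — defines the normalized
fitness as 0, so degenerate populations produce no division by zero and
no spurious drift.

*Boundary repair*: out-of-box coordinates wrap to the opposite face with
a diffusion perturbation `D_max · U(−1, 1)`, `D_max = 0.005` box units,
then a final clamp guarantees containment even for proposals more than a
box-width out. The global best is elitist, so the best-fitness history
is monotone non-decreasing by construction.

Three stability decisions deserve their reasoning on record, because the
obvious transplants from the parent algorithms fail:

* **The adaptive weight must stay below 1/2.** In this formulation the
  weight multiplies the *position* directly, and the exploration map's
  total position coefficient is $\varpi_F + 1/2$. The PSO/krill
  convention of annealing 0.9 → 0.1 is contractive only when the weight
  rides on a velocity; applied to the position it makes every
  exploration step expansive for half the run. nodulekit anneals
  $\varpi_F = \varpi_n$ linearly 0.45 → 0.05 (one shared schedule),
  keeping the per-event map contractive throughout.
* **The inertia term rides on the difference velocity.** The
  exploitation move uses $\varpi_n (B - B_{prev})$, the member's
  velocity-by-difference, not the raw previous position: a raw-position
  term gives the late-stage map a coefficient $1 + \varpi_n/2 > 1$ and
  forbids refinement, while the velocity reading (which is also the
  krill parent's, where inertia weights the old induced *motion*)
  vanishes as the swarm settles.
* **The random walk must anneal faster than exploration decays.**
  Exploration events arrive at rate $\propto (1 - t/t_{\max})$; the
  exploitation random walk accumulates between consecutive events, so
  its accumulated displacement scales as amplitude/rate. A linear
  amplitude anneal therefore leaves a scale-invariant O(1) perturbation
  floor no matter how long the run is; the quadratic anneal
  $(1 - t/t_{\max})^2$ makes the product vanish and lets the schedule
  hand the swarm over to pure refinement. The acceptance suite verifies
  the consequence: on the 5-D sphere with bounds ±5, the 20-seed median
  final best must reach −10⁻² and beat equal-budget uniform random
  search.

A candidate with non-finite fitness is rejected (the member keeps its
position) with a warning; the run, not the member, owns the RNG, so the
full trajectory is bit-reproducible from the config seed.

## The classifier and its training

The flat feature vector is zero-padded and chunked row-wise into
`timesteps = 8` steps (`step_dim = ceiling(length/8)`). One forward and
one backward LSTM pass (hidden size 8 per direction) run from zero
states; per step, three sigmoid gates and a tanh candidate are computed
from `[h_prev, x_t]`, the cell state updates as
`c_t = Q ⊙ c_prev + I ⊙ X̃` and the hidden state as
`h_t = P ⊙ tanh(c_t)`. `Q` is the forget gate — the naming follows its
role as the multiplier of the previous cell state — `I` the input gate,
`P` the output gate. The final representation concatenates the forward
state at the last step with the backward state at the first step; a
single linear unit plus sigmoid yields the malignancy probability, and
`p ≥ 0.5` (ties included) is called malignant. One BiLSTM layer is
implemented; stacking is not.

Training is gradient-free: all 1489 parameters (at the default
geometry; four gate blocks per direction plus the output unit) are
flattened in a fixed, versioned layout and handed to the swarm optimizer
over the box `[−2, 2]^P`. The objective is classification accuracy on
the *training* portion of a seeded stratified 80/20 split, with features
z-scored on training statistics; the held-out portion is scored once, on
the returned best parameters. Optimizing held-out accuracy directly
would make the final evaluation circular, so the package deliberately
does not, even though accuracy-as-fitness invites it. Bounded weights
plus standardized inputs keep pre-activations in the gates' responsive
range, which is what makes a 1000-evaluation search viable at all.

## The phantom generator

`generate_phantom()` emulates exactly the structure the pipeline's
assumptions rely on: a bright soft-tissue background (mean 0.85 on
[0, 1]), two dark elliptical lung fields (mean 0.25, jittered geometry,
clear of the border), thin vessel-like bright curves (0.50) inside the
lungs, bright quasi-circular nodules (0.70), and additive Gaussian noise
(σ = 0.03; ground truth recorded pre-noise). Benign nodules are smooth
discs of radius 3–6 px; malignant nodules draw 9–14 px and perturb the
boundary sinusoidally with relative amplitude 0.25 — at the 256-px
default slice size these radii correspond to the few-millimetre nodules
of clinical screening data. Malignancy is therefore encoded as size plus
boundary irregularity, both visible to the implemented descriptors
through the boundary-to-interior code mix and gradient content; real
radiologist labels correlate with subtler cues no phantom reproduces.
Dataset labels are assigned as a deterministic balanced draw
(`round(n·ratio)` malignant, shuffled), so the realized class balance
matches the configured ratio up to rounding.

What the phantoms do *not* emulate — Hounsfield calibration, anatomy
beyond two ellipses, texture inside nodules, 3-D continuity, scanner
artefacts — bounds what green tests mean: they certify the algorithms
against their own stated assumptions, not clinical performance.

## Problem sizes and reproducibility

The package's reference experiment (`run_experiment()`) uses 100
phantom slices at 256 px, single nodule per slice, swarm training with
population 20 for 50 iterations, and a stratified 80/20 split; the
acceptance script adds 20-seed optimizer benchmarks, 50-slice
preprocessing sweeps and 20-slice segmentation sweeps. These sizes are
the package's chosen reference conditions: large enough that every
claimed property is exercised end to end, small enough to run routinely
on one CPU. Every stochastic stage (phantom rendering, clustering
initialization, swarm trajectory, data splits) draws from seeds derived
from a single configured seed, and the test suite asserts bit-identical
reruns of the full experiment.

## Known limitations

The pipeline is 2-D and slice-wise by design. Nodule candidates are
intensity-defined, so a nodule darker than parenchyma or overlapping the
mediastinum is outside the model. The separation guard assumes unimodal
parenchyma noise; pathologies that bimodalize the lung field (severe
consolidation) would defeat it. The classifier's feature budget is a
deliberate desk-scale stand-in for deep backbones, and its accuracy on
phantoms should not be read as a clinical claim.
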