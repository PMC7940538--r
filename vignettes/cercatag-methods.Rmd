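---
title: "Modelling the cricket cercal escape response: methods and design notes"
author: "cercatag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cricket cercal escape response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cercatag)
```

This vignette is the package's own account of the science it implements:
the statistical model of cercal filiform-hair spiking, the leaky-integrator
feature map, the sparse bio-inspired TAG network and its training, and the
evaluation metrics.  It also records every numerical choice that the
underlying physiology does not pin down, and what the synthetic data do —
and do not — establish.

## 1. The hair simulator

Each 1-second trial draws five stimulus variables uniformly within bounds
(`stimulus_bounds()`): background intensity and direction describe ambient
air drift; attack angle, speed and attacker size describe one simulated
predator strike whose air-current peak falls at either 350 or 700 ms.
Sixteen hair sub-populations (2 cerci × 2 length classes × 4 socket
orientations) of `n_hairs = 60` hairs each fire:

* **baseline**: per hair, `round(intensity × length_factor ×
  direction_factor)` spike times drawn uniformly on [0, 1] s.  Short
  (fast-tuned) hairs fire at half the long-hair rate; hairs aligned with
  the prevailing drift fire `1 + γ` times more and opposite hairs `1 − γ`
  times less (γ = 0.5).  Counts are deterministic products by default — the
  spike *times* remain random — with a Poisson option
  (`hair_config(poisson_baseline = TRUE)`) for users who prefer count
  noise.
* **attack**: per hair one Bernoulli trial with `p = p_θ · p_side · s`.
  The directional tuning is a raised cosine floored at β₁; the cosine is
  clamped at zero *before* the floor so β₁ is a true minimum and `p` can
  never go negative.  The cercus ipsilateral to the attack responds fully
  (`p_side = 1`, side of attack = left for θ < 180°); the contralateral
  side decays as `exp(−α·|π − θ|)` with floor β₂, so a strike from exactly
  behind excites both cerci equally and `p` is bounded in
  [0.75·β₁·β₂, 1].  A success contributes exactly one extra spike at
  `N(t_attack, 1/attack_speed)` — short hairs lead by 10 ms, reproducing
  the reduced response latency of short hairs under accelerating air
  bursts.  The 10 ms lead is fixed, not scaled with attack speed.

Angles are degrees externally and radians inside the cosine/exponential.

### Free constants and their calibration

The electrophysiological literature that fixes the response floors, the
contralateral decay and the ambient firing ranges is not reproduced in
numbers anywhere we could copy them from, so these are package constants:
β₁ = β₂ = 0.1, α = 2 rad⁻¹, γ = 0.5, N = 60.  Two further constants are
not published at all and had to be calibrated against the *reported
behaviour* of the system — the full model holds a ~0.07 tolerated FPR,
ablating components degrades it in a specific order, and mid-sized generic
networks do not beat the bio-inspired wiring:

* **background intensity ∈ [15, 30]** (per-hair baseline spikes/s for long
  hairs).  Much wider ranges (e.g. [5, 40]) make the ambient level so
  variable that separating "strong background" from "attack" becomes a
  strongly non-linear problem that no 63-synapse network can express — the
  architecture's representational ceiling degrades to a tolerated FPR an
  order of magnitude above the reported regime while wide perceptrons still
  solve the task, contradicting the reported ablation structure.
* **attack speed ∈ [100, 500] s⁻¹**, i.e. attack-spike jitter σ between 2
  and 10 ms: the time scale of a fast looming strike, and sharp enough
  that the attack transient survives the RC integration window.

These were fixed once, by scanning a coarse grid for the regime that
reproduces the *qualitative* structure above, and are not touched by any
test or script thereafter; all headline numbers in the README are computed
under exactly these defaults.

## 2. The feature map

Each input neuron integrates one sub-population through a parallel RC
circuit, `C dV/dt = i(t) − V/R` (0.1 pF, 200 GΩ), receiving a 1 pA pulse
for one integration step per spike — charge `i·dt`, i.e. +10 mV, per spike,
with coincident spikes summing linearly.  Forward Euler at `dt = 1` ms is
exact for this piecewise-linear input (the recursion is a first-order
recursive filter); the tests verify first-order convergence to the analytic
exponential as `dt → 0`.  `dt` must stay below `RC = 20` ms for stability;
the validator enforces this.

Activations are `tanh(Vc − ⟨Vc⟩_train)` after scaling voltages by
`voltage_scale = 10` (one spike ⇒ +0.1).  The scale is a numerical choice:
it places typical baseline-subtracted voltages in roughly [−3, 3], the
informative range of tanh.  A ×100 scale (one spike ⇒ +1) drives the
ensemble voltage of 60-hair populations tens of units into saturation and
collapses the features to their signs; we measured an order-of-magnitude
loss in achievable tolerated FPR under it.  The per-neuron baseline means
are computed on the training split only and frozen, so no information leaks
from the test rows.

Snapshots are read `snapshot_lag = 10` ms after each candidate attack peak
(350 and 700 ms): half an RC time constant, late enough that most
attack-locked spikes (σ ≤ 10 ms) have arrived, early enough that the
transient has only decayed by ~40%.  The snapshot at the true attack slot
is labelled 1, the other 0, so every simulation yields one attack and one
ambient row and the 2·n_sims dataset is balanced by construction.  Rows are
shuffled with the run seed and split 50/50 into train/test.

## 3. The TAG network

Seven interneurons read the 16 features through a fixed mask: four
directional cells (two same-angle slow inputs each), `slow` (four rear
long-hair inputs), `fast` (four rear short-hair inputs) and `glob` (all
eight long-hair inputs).  Lateral connections are all-to-all among the
directional cells *including self-connections* — the reading under which
the wiring totals exactly 63 synapses (24 feed-forward + 26 lateral + 6
regulatory + 7 jump); without self-loops the count is 59 —, mutual between
`slow` and `fast`, and uni-directional from the speed cells onto the
directional cells.  `glob` sends one regulatory synapse to each other
interneuron and receives none laterally.

The lateral loop is unrolled one step so gradients cannot cycle: step 1
applies tanh to the feed-forward drive plus the glob input; step 2 applies
tanh to the step-1 activation plus the lateral drive *computed from step-1
activations* plus the bias.  `glob` itself, having no lateral inputs,
reduces to `tanh(tanh(ff) + b)`; its bias enters in the second step,
mirroring the other cells.  The jump neuron is a sigmoid over the
interneuron activations.  Ablation variants keep or drop whole groups:
`I` (22 weights), `I+L` (48), `I+G` (37), `I+L+G` (63); variant `I`
excludes the glob cell entirely, so six interneurons feed the jump neuron.

Initialization is deterministic — +1 for all masked feed-forward weights,
−1 for the glob regulatory synapses and for the lateral weights between
opposite directional pairs (45↔225, 135↔315), −1/+1 for the jump weights
from `slow`/`fast`, 0 elsewhere — encoding the expected signs of the
circuit before any data are seen.  Only the glob sign is directly dictated
by the background-subtraction hypothesis; the remaining entries follow the
same logic (opponent inhibition; attack = fast−slow divergence) and are
validated by the convergence of training within its 50-epoch budget.

## 4. Training

The loss is the equal-weight sum of the binary cross-entropy of the jump
output against the attack label and the categorical cross-entropy of the
four directional activations against the background direction, plus
`(λ/2)Σw²` weight decay (λ = 10⁻⁴, weights only).  tanh activations are
not probabilities, so the directional loss applies a normalized exponential
(softmax) first; every row carries a direction label, so this term is
computed on all rows.  Probabilities are clipped at 10⁻⁷ inside the logs.

Optimization is mini-batch (8) RMSprop (decay 0.99, ε = 10⁻⁸) for 50
epochs from the deterministic init; gradients are analytic (hand-derived
backpropagation through the one-step unrolling, verified against central
finite differences at 10⁻⁵ relative tolerance) and masked, so weights
outside the connectivity pattern stay exactly zero forever.  The learning
rate is not published; we use 10⁻² because at 10⁻³ the training loss is
still visibly descending at epoch 50 — i.e. the model has not converged
within its stated budget — while at 10⁻² the trace is flat over the last
ten epochs and pushing further (Adam, 20× the epochs) improves the training
loss only marginally.  Mini-batches are reshuffled every epoch from the run
seed; two models trained with the same seed and config see identical
batches, which is how the comparators share the TAG's batch stream.

Comparators: logistic regression (17 parameters; trained with the same
RMSprop/50-epoch recipe as the TAG family, which its convex objective
converges well within) and fully connected tanh MLPs with 1 or 3 equal
hidden layers, Adam (β = 0.9/0.999, lr 10⁻³), 1,000 epochs, binary
cross-entropy only, fan-in-scaled uniform random init.  The width sweeps
default to 2…1024 (one layer) and 2…256 (three layers).  Optional L1
training (`l1 = 10⁻³` by default when enabled) produces the sparsified
variants; magnitude pruning pools *all* weight matrices into one ranking
(biases exempt) and zeroes the lowest percentile.

## 5. Evaluation

ROC curves rectify the jump probability at 1,001 regular thresholds on
[0, 1]; the tolerated FPR is the minimum FPR among thresholds with TPR ≥
0.95.  If no threshold attains the floor the trivial all-positive operating
point (FPR 1) is reported with a warning — also the convention for
constant-score models (e.g. a 100%-pruned network).  AIC is `2k + 2·NLL`
with `k` the trainable parameter count *including biases* and NLL the
summed Bernoulli negative log-likelihood of the jump output on the held-out
split.  Ablation conclusions are asserted on medians over ≥ 5 seeds, since
each seed regenerates the dataset and the batch stream; the AIC comparison
is made on the standard (first-seed) run.  The prune sweep reports the
first grid percentile whose tolerated FPR strictly exceeds the TAG
reference; the robustness sweep perturbs trained weights with
multiplicative (default) or additive Gaussian noise and re-evaluates
without retraining, ≥ 10 draws per level.

## 6. Problem sizes

The standard study uses 1,000 simulations (2,000 rows), five seeds for the
ablation medians, and two comparator configurations at the published
crossover widths (1×256 and 3×32) for the headline sweep; the full
logarithmic sweep is available through `run_mlp_sweep()` /
`run_paper_pipeline()`.  These sizes reproduce the reported structure while
keeping a complete run in the minutes range on one CPU.

## 7. What the synthetic data do and do not show

The generator emulates direction/speed-tuned ensemble spiking with
uniform ambient drift, one attack transient per trial, and the
short-hair latency lead.  It does **not** emulate hair-to-hair tuning
heterogeneity beyond the long/short dichotomy, socket biomechanics,
boundary-layer aerodynamics, frequency-dependent tuning curves, adaptation,
or correlated noise between hairs; ambient intensity is constant within a
trial.  Passing tests therefore establish that the implementation is
faithful to the stated statistical model and that the architectural
comparison holds *under that model* — not that the trained weights would
transfer to real cercal recordings.  Degenerate inputs are handled
explicitly: zero background intensity yields empty baseline rasters;
single-simulation datasets carry one row per class; empty datasets,
invalid bounds, non-positive `dt` and unknown variants raise errors.
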