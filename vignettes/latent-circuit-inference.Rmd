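---
title: "Latent circuit inference: model, fitting procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent circuit inference: model, fitting procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(latentcircuit)
```

## The model

Heterogeneous neural population responses during cognitive tasks often
occupy a low-dimensional subspace, but standard dimensionality reduction
describes that subspace without saying how dynamics within it are
generated. The latent circuit model closes this gap: it fits an
$N$-dimensional response trajectory $y(t)$ with the trajectories of a small
$n$-node recurrent circuit, embedded through a tall orthonormal matrix
$Q \in \mathbb{R}^{N \times n}$,

$$y = Qx, \qquad \dot x = -x + f(w_{\mathrm{rec}} x + w_{\mathrm{in}} u), \qquad
z = w_{\mathrm{out}} x,$$

with $f$ a rectified-linear activation, $u(t)$ the task inputs and $z(t)$
the behavioral outputs the circuit must reproduce. Because $Q^\top Q = I$,
the columns of $Q$ are population activity patterns whose projections
correlate one-to-one with latent nodes, and the latent connectivity can be
interpreted as a connectivity structure of the large network: if the model
fits well, then $Q^\top W_{\mathrm{rec}} Q \approx w_{\mathrm{rec}}$ and
$Q^\top W_{\mathrm{in}} \approx w_{\mathrm{in}}$, and a change
$\delta$ of a single latent connection $(i,j)$ maps onto the rank-one
ambient perturbation $\delta\, q_i q_j^\top$. These relations are what
make the method falsifiable: inferred mechanisms can be checked against
the network's connectivity (`conjugate_connectivity()`) and validated
behaviorally by patterned perturbations (`map_perturbation()`,
`apply_perturbation()`) or activity stimulation (`stimulate_along_axis()`).

## Orthonormal embeddings without constrained optimization

Optimizing over orthonormal $Q$ directly is a manifold problem. We instead
parameterize $Q$ by an arbitrary square matrix $B$ through the Cayley
transform: $A = B - B^\top$ is skew-symmetric, $C = (I+A)(I-A)^{-1}$ is
orthogonal for every such $A$ ($I - A$ is always invertible), and $Q$ is
the first $n$ columns of $C$. Gradients flow through this map analytically
(`cayley_embed()` and its backward pass use
$dC = (I + C)\, dA\, (I-A)^{-1}$). The parameterization is degenerate --
$A$ has $N(N-1)/2$ free entries while $B$ has $N^2$ -- but the degeneracy
lives entirely in $B$ and never surfaces in $Q$, so we leave it alone.
Orthonormality of $Q$ therefore holds *exactly at every optimizer step*,
not just at convergence.

## The task testbed

The context-dependent decision-making task (`ctx_dm_task()`) presents a
context cue (320--1,000 ms, amplitude 1.2 cued / 0.2 uncued), then after a
delay a compound stimulus from 1,200 ms whose motion and color evidence
channels carry $(1 \mp c)/2$ for signed coherence
$c \in \{\pm 0.04, \pm 0.12, \pm 0.2\}$; a baseline drive $u_0 = 0.2$ is
added to all six channels at every step, and independent Gaussian noise
$\sqrt{2/\alpha}\,\sigma_{\mathrm{in}}\,\eta_t$ with
$\sigma_{\mathrm{in}} = 0.01$ is added per channel and step. Output
targets are 0.2/0.2 during the cue and 1.2/0.2 (right) or 0.2/1.2 (left)
from 2,250 ms; the squared output error is penalized only during the cue
epoch and the final 750 ms. The trial end is not pinned down by the
timing parameters alone; we fix the trial at 3,000 ms (75 steps of 40 ms),
which makes the target onset coincide with the start of the penalized
response window. Whether the cue amplitude 1.2 already includes the
baseline is equally underdetermined; we add the baseline on top of all
channels uniformly (a flag in `ctx_dm_task()` changes this). Time steps
live on a grid closed at the left edge; epoch boundaries snap to the
nearest grid point, so the 2,250 ms target onset lands on the step at
2,240 ms.

The RNN testbed (`rnn_init()`, `rnn_train()`) is a 50-unit
rectified-linear network, 80% excitatory / 20% inhibitory, with
$\tau = 200$ ms, $\Delta t = 40$ ms, $\sigma_{\mathrm{rec}} = 0.15$, and
nonnegative input/output weights, trained with Adam (learning rate 0.01,
weight decay 0.001, minibatch 128, 1,800 trials) on the masked squared
error plus a firing-rate penalty $\lambda_r \sum y^2$
($\lambda_r = 0.05$) and an orthogonality penalty
$\lambda_{\mathrm{orth}} \lVert B_{io}^\top B_{io} -
\mathrm{diag}(B_{io}^\top B_{io}) \rVert^2$ on the column-normalized
concatenation $B_{io} = [W_{\mathrm{in}}, W_{\mathrm{out}}^\top]$
($\lambda_{\mathrm{orth}} = 1$). Excitatory recurrent weights are
initialized from a Gaussian with mean $1/\sqrt N$ and variance $1/N$,
inhibitory from mean $4/\sqrt N$; draws whose sign would violate Dale's
law at initialization are clipped to zero, and the matrix is rescaled to
spectral radius 1.5. After every Adam step, recurrent weights that changed
sign are clipped to zero (Dale's law), and $W_{\mathrm{in}}$,
$W_{\mathrm{out}}$ are clamped nonnegative.

## Numerical choices

* **Gradients.** There is no automatic differentiation here: the
  backpropagation-through-time passes for the RNN loss, the latent
  reconstruction loss and the neural-data loss, and the backward pass of
  the Cayley transform, are derived analytically and implemented in
  compiled code. Each is verified against central finite differences in
  the test suite (relative error below $10^{-5}$ away from rectifier
  kinks; exactly at a kink the subgradient convention makes a
  finite-difference comparison meaningless on a measure-zero set).
* **Loss reduction.** Adam is invariant to the overall loss scale, so
  what matters is the *relative* weighting of the task error, the rate
  penalty and the orthogonality penalty. The RNN loss averages the task
  error over the penalized entries and takes
  $\lambda_r \cdot \mathrm{mean}(y^2)$ for the rate term (the
  orthogonality penalty is added unscaled). We also tried weighting the
  terms as raw sums; because a trial has ~50x more rate entries than
  penalized output entries, that weighting prices persistent activity out
  entirely (mean rates collapse to ~0.03) and the context-memory solution
  never forms -- the network settles permanently into an
  "integrate both streams" optimum. Mean reduction keeps the rate penalty
  gentle and trains reliably. Early stopping is relative: optimization
  stops when the epoch loss has not improved by 0.1% over a patience of
  25 epochs.
* **Input-weight initialization.** The scale of the (nonnegative) input
  weights decides whether context gating can be learned at all. At
  $U[0, 1/\sqrt N]$ the cue-driven input (~0.1) is buried under the
  per-step recurrent noise (sd ~0.47), no usable context trace survives
  to the stimulus epoch, and the gradient for exploiting context vanishes
  -- runs stay at chance on incongruent trials for thousands of epochs.
  At $U[0,1]$ the cue reaches the population robustly and the same
  optimizer finds the gating solution within a few hundred epochs. The
  default is $U[0,1]$.
* **Stochastic trajectories during fitting.** Latent trajectories are
  re-simulated with fresh recurrent noise
  ($\sigma_{\mathrm{rec}} = 0.15$, the value used for the fitted network)
  on every minibatch; the noise enters inside the rectifier and its
  gradient path is carried by the stored rectifier gates.
* **Evaluation convention.** Held-out fit quality compares the model's
  *mean* prediction -- latent trajectories simulated without recurrent
  noise -- to the held-out data, and the headline $r^2$ is computed on
  condition-averaged responses (the two disjoint trial halves of the
  split are compared as per-condition averages, as in cross-validated
  analyses of recorded firing rates). Scoring a single stochastic model
  realization against single noisy trials instead would impose a
  double-noise floor on $r^2$ that no model, including the generating
  network itself, could exceed.
* **Node identity.** `w_in` is structurally diagonal (input $i$ drives
  node $i$ only) and `w_out` reads out only the two choice nodes; the
  structural zeros are re-imposed and the active entries clamped
  nonnegative after every update. This pins node identities, removes the
  permutation symmetry, and makes recurrent weights directly comparable
  across fits -- which is what allows plain correlations to measure
  solution uniqueness. We read the diagonal constraint on the
  input/output concatenation this way deliberately: constraining the
  *Cayley auxiliary* $B$ to be diagonal instead would freeze $Q$ at the
  identity and remove the embedding altogether.
* **Ties and degenerate cases.** Exactly tied outputs at the decision
  step are resolved by a seeded fair coin and flagged. Ensembles rank by
  held-out $r^2$ with ties broken by lower final training loss. A
  constant connectivity matrix has no defined correlation; uniqueness
  statistics report it as missing rather than failing.
* **Train/test splits.** Trials are split 50/50 within each condition
  (the convention the cross-validated firing-rate protocol uses: two
  equal disjoint trial sets); all fit-quality metrics are computed on the
  held-out half only. An ensemble shares one split so its members are
  ranked on the same test set.

## Fitting condition-averaged recordings

For condition-averaged firing-rate data, responses are centered, so the
model gains an intercept, $y = Qx + b$, and the loss becomes the
normalized three-term tradeoff

$$L = \lambda\, r_Q^2 + r_x^2 + r_z^2,$$

with $r_Q^2$ the relative residual of projecting the data onto the
embedding subspace, $r_x^2$ the relative mismatch between projected data
and latent trajectories, and $r_z^2$ the relative output error on the
final 250 ms. The subspace weight $\lambda$ matters precisely because
task-relevant variance is a small fraction of total variance in cortical
recordings; $\lambda = 0.5$ is the default and `lambda_grid()` replicates
the grid-search selection over $[0, 1.5]$. The data terms are evaluated
only on the timesteps with observed responses (the final 15 steps of a
150-step, 10-ms grid in the standard layout: contextual input 0--1,500 ms,
stimulus 750--1,500 ms); sliding-window bin centers are aligned to the
nearest grid step. Inputs to the latent circuit are noiseless here --
each "trial" is a condition average -- while the recurrent noise is kept.

`preprocess_rates()` implements the standard pipeline (50-ms binned
counts, within-split trial averaging per condition, per-unit z-scoring,
Gaussian smoothing with $\sigma = 40$ ms, subtraction of the
condition-independent mean, PCA denoising to 50% cumulative variance), and
drops conditions with fewer than 4 trials and constant-rate units.

## What the synthetic surrogate emulates -- and what it does not

`generate_synthetic_population()` builds populations with known ground
truth: a planted circuit (by default the handcrafted suppression circuit,
`example_suppression_circuit()`) is simulated over the 72 task conditions,
embedded through a random orthonormal map, mixed with smooth task-irrelevant
components scaled so the task subspace holds a chosen fraction of total
variance (defaults emulate the low task-relevant variance of prefrontal
data), and observed through two independently noisy splits. It reproduces
the *statistical layout* of preprocessed recordings -- condition structure,
observation window, centering, low task variance -- but not spiking
statistics, rate nonstationarities, session-to-session drift, or neuron
dropout. Recovery results on these surrogates therefore demonstrate that
the fitting pipeline is sound within its model class, not that any given
cortical dataset satisfies the model's assumptions.

## Problem sizes

The worked analyses in this package run at desk scale, chosen once: one
50-unit network trained on 1,800 trials (early stopping typically ends
training after 150--250 epochs); latent ensembles of 20--64 random
initializations with the top 10 kept; behavioral tables from 10--20
trials per condition; solution-space analyses across a handful of
independently trained networks rather than hundreds. The reference-scale
study behind these procedures uses hundreds of networks with 100 fits
each; statistics that rest on screening a large ensemble down to its best
tenth -- the uniqueness correlation and the across- versus within-network
variance ratio -- are systematically attenuated at desk scale, because a
top-10-of-20 set necessarily retains fits outside the dominant
optimization basin. Fits that do converge to the dominant basin agree
with each other at correlations of 0.9 and above.

## Known limitations

* The activation is fixed to rectified-linear on both sides (an
  activation hook exists internally, but smooth-saturating variants are
  not implemented).
* The latent dimensionality is user-set (default $n = 8$, the number of
  inputs plus outputs); no model-selection over $n$ is provided.
* Perturbation probes deliberately do not re-impose Dale's law -- they
  are probes of a trained network, not retraining.
* The permutation test's shuffle operates on whole trials (responses are
  permuted across trials relative to their conditions); within-trial
  temporal shuffles are out of scope.
* Converters for any specific external electrophysiology dataset layout
  are not included; `preprocess_rates()` defines the expected long-form
  layout instead.
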