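# latentcircuit

Circuit mechanisms behind heterogeneous neural population activity are hard
to read off from correlation-based dimensionality reduction: a
low-dimensional projection describes *where* activity lives, not *how* it
is generated. `latentcircuit` fits a **latent circuit model** -- a small
recurrent circuit whose trajectories, embedded through an orthonormal map,
reproduce both the high-dimensional responses and the behavioral outputs:

$$y = Qx, \qquad \dot x = -x + f(w_{\mathrm{rec}}x + w_{\mathrm{in}}u), \qquad z = w_{\mathrm{out}}x,$$

with $Q^\top Q = I$ parameterized through the Cayley transform of a
skew-symmetric matrix, $f$ rectified-linear, $u$ the task inputs and $z$
the outputs. Because the embedding is orthonormal, latent connectivity is
interpretable as connectivity of the large network
($Q^\top W_{\mathrm{rec}} Q \approx w_{\mathrm{rec}}$), and perturbing one
latent connection maps onto a rank-one perturbation
$\delta\,q_i q_j^\top$ of the network's weights -- so inferred mechanisms
can be *validated* in connectivity and behavior, not just in fit quality.

The package is aimed at systems/computational neuroscientists studying
cognitive tasks. It provides:

* a context-dependent decision-making task generator
  (`ctx_dm_task()`, `make_batch()`),
* a Dale-constrained rectified-linear RNN testbed trained by
  backpropagation-through-time with Adam (`rnn_init()`, `rnn_train()`,
  `psychometric()`),
* the latent circuit fitter with Cayley-parameterized orthonormal
  embeddings (`fit_latent()`, `fit_ensemble()`), plus a variant for
  condition-averaged firing-rate recordings with an intercept and a
  normalized three-term loss (`fit_neural()`, `preprocess_rates()`),
* connectivity conjugation, rank-one perturbation mapping and activity
  stimulation probes (`conjugate_connectivity()`, `map_perturbation()`,
  `stimulate_along_axis()`),
* solution-space analyses: ensemble uniqueness, PCA + Gaussian-mixture
  clustering of fitted circuits, across- vs within-network variance
  ratios, linear decoding, axis projections and a permutation test for
  whether inferred connectivity depends on the neural responses
  (`uniqueness()`, `cluster_solutions()`, `variance_ratio()`,
  `train_decoder()`, `shuffle_test()`),
* synthetic surrogate populations with planted ground-truth circuits
  (`generate_synthetic_population()`, `example_suppression_circuit()`).

## Worked example

Train a 50-unit excitatory/inhibitory RNN on the context-dependent
decision-making task, fit an ensemble of 8-node latent circuits to its
responses, and check the inferred mechanism against the network's own
connectivity:

```r
library(latentcircuit)

p <- rnn_init(N = 50, seed = 2024)
trained <- rnn_train(p, rnn_train_config(seed = 2024, max_epochs = 800))
trained$epochs   # early stopping ended training here
#> [1] 237

batch <- make_batch(ctx_dm_conditions(), 8, seed = 4242,
                    alpha = trained$params$alpha)
sim <- rnn_simulate(trained$params, batch, seed = 4243)

fits <- fit_ensemble(sim$y, sim$z, batch, n_inits = 20, top_k = 10,
                     latent_fit_config(seed = 91, max_epochs = 2500,
                                       patience = 100, tol = 1e-4))
best <- fits[[1]]
best
#> latent_fit: n = 8, 607 epochs, held-out r2 = 0.943 (task r2 = 0.834)

# the fitted embedding exposes the circuit inside the RNN's weights
conj <- conjugate_connectivity(trained$params$W_rec, best$circuit$Q)
cor(as.numeric(conj$w_rec), as.numeric(best$circuit$w_rec))
#> [1] 0.7772381

# agreement of the other converged fits with the best one
round(uniqueness(fits)$correlations, 2)
#> [1] 0.58 0.63 0.95 0.72 0.52 0.91 0.58 0.58 0.69
```

The held-out `r2` is the coefficient of determination between the embedded
latent trajectories `Q x` and the condition-averaged RNN responses on
trials never seen in fitting -- the 8-node circuit explains ~94% of the
held-out response variance of the 50-unit network. The conjugation
correlation (~0.78) says the same connectivity structure is present in the
RNN's weight matrix when viewed in the fitted basis. Several independent
fits recover essentially the same circuit (correlations above 0.9 with the
best fit); larger ensembles make the converged subset dominate. The
recovered `w_rec` shows the suppression mechanism: inhibitory weights from
each context node onto the sensory nodes of the *irrelevant* stream, and
excitatory sensory-to-choice weights implementing the two
stimulus-response mappings.

A command-line wrapper over the same functions is installed at
`inst/cli/lcirc.R` (`train-rnn`, `psychometric`, `fit-ensemble`,
`conjugate`, `perturb`, `make-synthetic`).

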