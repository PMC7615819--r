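---
title: "Temporal predictive coding for sequential memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal predictive coding for sequential memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmem)
```

## The problem

A sequential memory stores an ordered list of patterns
$x^\mu \in \mathbb{R}^N$, $\mu = 1, \dots, P+1$, and, cued with one
pattern, recalls the *next* one — recursively, the whole sequence. Two
model families are implemented here:

* **Temporal predictive coding (tPC)** networks, which learn the
  transition structure by minimizing squared temporal prediction errors
  with local, Hebbian-shaped updates, and recall by relaxing value
  neurons against the learned prediction;
* the **Asymmetric Hopfield Network (AHN)** family, which stores the
  cross-step outer-product sum
  $W_{\mathrm{AHN}} = \sum_\mu x^{\mu+1} (x^\mu)^\top$ and retrieves in a
  single shot. Under the Universal-Hopfield view a retrieval is
  $\sum_\mu x^{\mu+1}\,\mathrm{sep}(\mathrm{sim}(x^\mu, q))$: a
  similarity between the query and each stored pattern (here always a
  dot product), sharpened by a separation function (identity, a
  polynomial of degree $d$, or a softmax at temperature $\beta$ — the
  latter called MCAHN).

Recall comes in two protocols. **Online** recall cues every step with
the ground-truth previous pattern; **offline** recall cues only the
first step and feeds each recall forward as the next query, so errors
can accumulate.

## Single-layer tPC

At step $\mu$ the error neurons carry
$\varepsilon^\mu = x^\mu - W f(x^{\mu-1})$ and the single weight matrix
follows $\Delta W \propto \varepsilon^\mu f(x^{\mu-1})^\top$, updated at
every step, over as many sequence presentations as needed. Recall
relaxes the value neurons by $\dot{\hat{x}} \propto -\varepsilon$, whose
fixed point for the identity nonlinearity is $\hat{x} = W f(q)$.

Two facts organize everything the package does with this model:

1. **The linear fixed point of training is least squares.** From a zero
   start, the updates stay in the span of the stored patterns, and the
   trained $W$ converges to $A C^{+}$ with
   $A = \sum_\mu x^{\mu+1}(x^\mu)^\top$ and
   $C = \sum_\mu x^{\mu}(x^\mu)^\top$. `closed_form_weights()` computes
   this map directly and is the analytical oracle for the trained
   network.
2. **Least-squares retrieval is whitened Hopfield retrieval.** With
   $M = (C/P)^{-1/2}$ (symmetric ZCA square root;
   `whitening_matrix()`), the retrieval can be written as the
   Universal-Hopfield form with a *whitened* dot-product similarity,
   averaged over the stored transitions:
   $R(q) = \frac{1}{P}\sum_\mu x^{\mu+1} (M x^\mu)^\top (M q) = A C^{+} q.$
   The whitened patterns have identity second moment on their span,
   $\langle Mx^\mu (Mx^\mu)^\top\rangle_\mu = I$. So linear tPC is the
   classical AHN with an implicit statistical-whitening step — which is
   why its capacity survives feature correlation that collapses raw
   dot-product retrieval.

Three conventions are worth stating because the algebra silently
depends on them. First, the equivalence assumes zero-mean memories;
`center_sequence()` removes the mean over all $P+1$ patterns once, and
the `center = TRUE` flags are idempotent on centered data. Second, the
whitener is built from the *mean* second moment $C/P$, so the identity
above carries the $1/P$ averaging factor; written as a bare sum over
transitions the expression would be off by exactly $P$. We fix the
mean convention because it makes both printed statements — the
identity second moment and the equality with $A C^+ q$ —
simultaneously true. Third, both `closed_form_weights()` and
`whitening_matrix()` truncate eigenvalues below $10^{-8}$ of the
largest (the same spectral cutoff), so the two routes agree to machine
precision even on rank-deficient input, where the pseudoinverse
handles degeneracy without error and the whitening identity holds on
the span only.

### Verifying the equivalence against the iterative network

`verify_property1()` checks three discrepancies at documented
tolerances: trained-vs-closed-form recall ($<10^{-3}$),
closed-form-vs-whitened retrieval ($<10^{-6}$), and the whitened
second moment against the identity on the span ($<10^{-4}$).

The first check hides a numerical subtlety. Per-step gradient updates
with a *constant* learning rate converge to the least-squares solution
only when the stored patterns are linearly independent, so that every
per-step error can reach zero. Small correlated binary draws are very
often exactly linearly dependent (two features collide with
probability $((1+b)/2)^P$ per pair), the system becomes inconsistent,
and constant-rate training settles into a limit cycle displaced from
least squares by a distance proportional to the learning rate. The
verification therefore trains with an *annealed* rate: stages of
constant-rate training run to the stage's fixed point, each stage
shrinking the rate fivefold, with per-stage epoch budgets scaled by
the smallest nonzero eigenvalue of $C$ (the slowest learnable
direction), until consecutive stage solutions agree on recall. This is
a statement about the optimizer, not the model: the model's fixed
point is least squares; the annealing merely removes the
finite-step-size bias.

```{r property1}
verify_property1(n_features = 20, length = 10, corr_b = 0.6, seed = 1)$errors
```

## Two-layer tPC

The two-layer model adds hidden value neurons $z^\mu$ that make a
temporal prediction of their own next state through $W_H$ and a
top-down prediction of the sensory input through $W_F$; inference and
learning minimize
$\|z^\mu - W_H f(\hat z^{\mu-1})\|^2 + \|x^\mu - W_F f(z^\mu)\|^2$.
The hidden state carries *temporal context*: two identical sensory
inputs at different positions (aliased inputs) receive different
hidden representations because their temporal priors differ, which is
what lets the model recall different successors for them. The model is
a hidden-Markov-style latent chain trained by alternating inference
(relax $z^\mu$ with the input clamped) and Hebbian weight updates.

### Numerical choices that matter

These were the genuinely open design decisions; each default was forced
by reproducible optimization failures at desk scale, and each
alternative remains available as an argument.

* **Batched weight updates.** Gradients are accumulated over the steps
  of a sequence and applied once per presentation. The first step has
  no preceding hidden estimate, so its decode error never vanishes;
  with per-step updates that irreducible gradient sustains a limit
  cycle that never settles. Batching makes good solutions actual
  stationary points.
* **The first pattern initializes the chain but contributes no weight
  update.** Its role is to set $\hat z^1$ (it is also the recall cue);
  forcing $W_F$ to decode it from a cold start pollutes the objective
  with an unsatisfiable term.
* **Adaptive (Adam) scaling of the updates** is the default
  (`optimizer = "sgd"` restores plain gradient steps). The update is
  the same prediction-error outer product, rescaled per synapse; plain
  SGD plateaus far above the attainable energy floor on every task we
  ship.
* **Recognition initialization of inference.** Hidden relaxations start
  from the feedforward guess $W_F^\top x$ (`inference_init = "prior"`
  starts from the temporal prediction instead). Early in training the
  prior is near zero, $f(z) \approx 0$ kills the learning signal, and
  training crawls; the recognition guess breaks that degeneracy.
* **Energy backtracking in the relaxations.** The explicit Euler step
  is stable only below $2/(1+\sigma_{\max}(W_F)^2)$, which training
  crosses as $W_F$ grows. Each relaxation step is accepted only if the
  energy does not increase, halving the step until it does not (and
  re-growing it after clean steps). The energy is therefore
  non-increasing along every relaxation by construction; the test
  suite asserts it at a step size of 0.01 on random instances.
* **Deterministic reset state.** The hidden chain starts from the zero
  vector during *both* memorization and recall, so the recall rollout
  reproduces the memorized chain exactly. Drawing the reset from a
  Gaussian (`reset = "gaussian"`, scale `hidden_init_scale`) perturbs
  the cue's inferred context, and the learned latent dynamics —
  which are expansive for interesting sequences — amplify that
  perturbation along the rollout.
* **Multi-start training** (`n_starts`). The objective is non-convex
  and has a well-characterized bad optimum for aliased sequences: the
  two occurrences collapse onto one context and the model recalls the
  average of their successors. Restarts re-draw the weight
  initialization deterministically from `seed + start - 1`, and the fit
  with the lowest final memorization energy is kept; the collapsed
  optimum is easily rejected because its energy floor is the distance
  between the conflicting successors.

During recall, online mode re-infers the hidden state from the
ground-truth query at every step, while offline mode carries the
converged hidden estimate forward directly — so offline recall of a
well-trained model is an open-loop rollout of the learned latent
dynamics from the cue's inferred context.

## The synthetic stimuli

All inputs come from seeded generators; nothing is downloaded.

* `generate_binary_sequence()`: i.i.d. uniform $\pm 1$ patterns, the
  classical capacity benchmark.
* `generate_correlated_binary_sequence()`: each pattern draws a latent
  sign $g$; every feature takes $g$ with probability
  $p = (1+\sqrt b)/2$ and $-g$ otherwise, giving pairwise feature
  correlation exactly $(2p-1)^2 = b$ with uniform marginals. This is
  the simplest construction matching the parameterization
  "$b = |$correlation$|$"; other constructions with the same second
  moments could differ in higher moments.
* `generate_onehot_word()`: words as sequences of one-hot letter
  vectors, distinct letters by default.
* `generate_moving_bar()`: the deterministic 5×5 movie whose bar
  visits rows 1,2,3,2,1 — steps 2 and 4 are aliased with *different*
  successors (and, necessarily for a down-then-up path, steps 1 and 5
  coincide too, harmlessly: step 1 is the cue and step 5 has no
  successor).
* `generate_rotating_shape_set()`: parametric shapes rotated by a fixed
  angle per frame (default 8 steps of 45°, 16×16 frames, bilinear
  resampling). The `train` family is filled regular polygons, the
  `heldout` family is line crosses — disjoint shape classes, so
  generalization is always measured on a class never seen in training.
  These movies emulate "identical dynamics, varying content"; they do
  not emulate the stroke statistics of handwritten characters, so
  passing results show transfer of the learned *rotation*, not
  robustness to natural image structure.

## Experiment drivers and the regimes they run in

Problem sizes below are the package defaults, chosen as desk-scale
versions of the phenomena.

**Capacity** (`estimate_pmax()`): $P_{\max}$ is the largest number of
transitions recalled with mean bit-error at most 0.01, scanned
incrementally with early stop after three consecutive failing lengths,
five fresh (model, sequence) pairs per length, online recall. Linear
tPC capacity sits near $N$ (exact recall while the stored patterns are
independent); the classical AHN's sits near $N / (2\ln N)$ and
collapses under feature correlation, because correlated cross-terms
scale like $bN$ — the same order as the signal. Uncorrelated scans use
the default schedule (100 epochs); correlated scans at $N = 100$ use
2000 epochs at tolerance $10^{-7}$, since correlation makes the
transition problem ill-conditioned and an under-trained network would
understate the model's capacity.

**Serial recall** (`serial_recall_experiment()`): a fresh two-layer
model per word, offline recall cued by the first letter, letters
decoded by argmax (ties to the lowest index), the cued position never
scored. The default recipe (hidden width 13 for a 26-letter alphabet,
50 presentations) deliberately operates the model in a
capacity-limited regime where its accuracy is comparable to human
serial recall — at saturation there are no errors and hence no
positional structure to study. Accuracy falls sigmoidally with word
length; the positional accuracy profile is U-shaped (primacy and
recency), and misrecalls concentrate on neighboring positions.
`primacy_recency_scores()` summarizes the profile relative to the
middle-position minimum; the underlying bar matrix is the
`positional_matrix` field.

**Aliasing** (`aliasing_experiment()`): random binary sequences
($N = 50$) with 20% of positions (rounded up) replaced by one repeated
pattern; online-recall MSE of fresh single- and two-layer models on the
plain and aliased versions. The single-layer model can only recall the
average of an aliased frame's successors, so its MSE jumps; the
two-layer model's hidden context keeps its MSE essentially unchanged.
`hidden_context_separation()` quantifies the mechanism as one minus
the cosine similarity between the hidden states at the aliased steps
(minimum over aliased pairs, zero-guarded for degenerate states).

**Generalization** (`generalization_experiment()`): one two-layer model
per training size on rotating-shape movies, offline recall cued by the
first frame, scored on seen movies and on held-out crosses. The
rotation is a fixed linear map of the frame, so the driver defaults to
the identity nonlinearity and one hidden unit per pixel; five
presentations suffice for the trend. Held-out MSE falls as training
size grows — the model extracts the shared rotational dynamics rather
than memorizing movies.

## Known limitations

* The whitening equivalence is exact only for the identity
  nonlinearity and zero-mean data; with `tanh` the correspondence is
  qualitative.
* Two-layer training is non-convex: the shipped defaults are tuned for
  the desk-scale tasks above, and new tasks may need their own
  learning rate, hidden width, or `n_starts`.
* The generators emulate the *statistical structure* of the stimuli
  (correlation level, aliasing, shared dynamics), not natural-image
  content; conclusions about natural movies require real data.
* Models with three or more layers, Kalman-filter formulations, and
  spiking implementations are out of scope.
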