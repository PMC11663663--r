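---
title: "Models and methods: DIVA, BR-DIVA and the six-problems simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DIVA, BR-DIVA and the six-problems simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brdiva)
```

## The benchmark

Eight stimuli, each a triple of binary features, can be split into two
equal categories in 35 unordered ways, and those fall into exactly six
structural equivalence classes under permutation of the three dimensions and
relabelling of feature values. Type 1 is a one-dimensional rule, Type 2 an
exclusive-or on two dimensions, Types 3-5 are rule-plus-exception
structures (three of each category's four members obey a one-dimensional
rule, one violates it), and Type 6 is the parity problem with no
within-category similarity at all. Human difficulty classically orders them
1 < 2 < 3-5 < 6.

The package fixes one canonical representative per class
(`shj_assignment()`); any member of a class is behaviourally equivalent for
a model whose random initialisation is symmetric across dimensions, and a
fixed representative keeps every simulation deterministic given its seeds.
Features are coded 0/1 rather than -1/+1 so that the sigmoid output units
can actually attain the reconstruction targets. The exception stimulus of
Types 3-5 is always *computed* as the unique category member misclassified
by the best one-dimensional rule (ties between equally good rules broken by
lowest dimension index), never hard-coded. In input space the mean Hamming
distance from the exception to its three rule-following category mates
orders the structures Type 4 (5/3) < Type 3 (2) < Type 5 (7/3), which is
the geometric basis for the Type 5 predictions discussed below.

## The two models

**DIVA** is a 3-2-(3 x 2) divergent autoencoder: a shared sigmoid hidden
layer of two units and one three-unit sigmoid decoder "channel" per
category. A stimulus is classified into the category whose channel
reconstructs it with the least sensitivity-scaled summed squared error;
exact ties are broken uniformly at random. Learning is one online
backpropagation step per trial on the true category's channel only (the
other channel's weights are untouched), which is what lets channels become
category-specific. Biases are included on the hidden and output layers and
are initialised like every other weight, uniformly on plus/minus
`weight_range`.

**BR-DIVA** replaces the deterministic hidden layer with a variational
bottleneck. The encoder produces two Gaussian posteriors per stimulus:
means by an affine map (`W_mu`), standard deviations by
`sigma = exp(logvar/2)` from an affine log-variance map (`W_logvar`), so
`sigma` is positive by construction. One latent sample
`z = mu + sigma * epsilon`, with `epsilon` standard normal, serves -- raw,
without squashing -- as the hidden activation for every decoder channel, and
the same single draw is used for the trial's response and its learning
update. The per-trial loss is

```
L = sum_j (r_j - x_j)^2  +  beta * KL( N(mu, diag sigma^2) || N(0, I) )
```

with the reconstruction term taken on the true channel only and
`KL = 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` computed once from the
shared encoder. Gradients flow through `z` to both encoder weight matrices
via the reparameterisation; the KL gradient touches only the encoder. The
capacity parameter `beta` (unitless, nonnegative) sets the price of
deviating from the standard-normal prior: it is the model's bounded
rationality, trading representational precision against coding cost.

Tunable parameters and their defaults, which are the study conditions
throughout: `learning_rate = 1`, `sensitivity = 1` (scale on squared feature
errors), `attention_breadth = 1` (a uniform feature-weighting hook, a no-op
at 1), `weight_range = 0.5`, `n_hidden = 2`. For single-model work the
constructor default is `beta = 0.1`; the grid simulations sweep
`beta_grid(50)` over 0.01-100 (log-spaced).

## Stability of the optimisation, and the divergent regime

Plain per-trial gradient descent on the KL term is *conditionally* stable.
Along the mean path the objective contributes curvature
`beta * ||x_tilde||^2` (with the bias appended, `||x_tilde||^2` is up to 4
for these stimuli), so the classical step-size condition requires roughly
`learning_rate * beta * ||x_tilde||^2 < 2`. At the conventional learning
rate of 1 this bounds stable optimisation to `beta` below about 0.5: above
it the encoder weights oscillate with growing amplitude and, a little
higher, overflow within a block. This is a property of the model plus
optimiser, not an implementation artifact -- the analytic gradients are
verified against central finite differences to 1e-5 relative error in the
test suite.

Three design choices follow:

* A participant whose weights overflow keeps running: non-finite channel
  errors are treated as infinitely bad, and when every channel is
  non-finite the response is a uniform random guess. Such runs respond at
  chance and learn nothing further. Aborting instead would make any sweep
  of the full 0.01-100 grid unrunnable.
* Properties that presuppose a convergent optimiser are tested inside the
  stability region. The KL-domination limit (posterior collapse to the
  prior at very large `beta`) is exercised at a step size satisfying the
  bound above; the monotone decrease of trained-encoder KL with `beta` is
  checked over 0.01-0.4. On the full grid neither can hold: diverged runs
  have astronomically large KL, and aggregate accuracy is *not* stable
  across the grid -- every structured problem falls to chance once `beta`
  crosses the stability boundary, which the grid simulations themselves
  show.
* The constructor default `beta = 0.1` is the largest decade-scale grid
  value safely inside the stability region.

## Simulation protocol

`run_experiment()` crosses simulated participants x problem types (x the
capacity grid for BR-DIVA). Each participant starts from fresh uniform
random weights and runs 20 blocks; a block presents all eight stimuli once
in an independent uniform random order; the response is scored *before* the
learning update on every trial. Defaults: 100 participants, 20 blocks, all
six types, 50 grid values.

Every random quantity derives from `base_seed` via `participant_seeds()`,
with two separate streams per participant. The stimulus-order stream
depends only on (base seed, type, participant), so DIVA and BR-DIVA -- and
every `beta` -- see identical trial orders for matched participants, which
is what makes the paired model comparisons paired. The
initialisation/latent-noise stream additionally depends on model and grid
position, so weights are re-drawn per `beta` (the protocol leaves this
open; re-drawing avoids sharing one initialisation's quirks across the
whole grid while trial orders stay matched). Any design cell is
independently re-runnable from its two seeds, and full tables are
bit-identical across runs with equal base seeds.

## Analyses

All analyses are pure functions of the tidy trial table (re-running on a
saved CSV reproduces them to numerical precision).

* **Order of difficulty**: accuracy aggregated to one cell mean per
  (type, beta), then OLS `accuracy ~ type + beta` with Type 1 as reference
  (`fit_difficulty()`), so type coefficients are aggregate deficits
  relative to the one-dimensional rule problem.
* **Model comparisons**: where BR-DIVA is compared with DIVA without naming
  a `beta` (paired t-tests, the block x model regressions), BR-DIVA
  per-participant accuracy is first averaged within each `beta` and then
  across the grid (`subject_accuracy()`), treating capacity as a secondary
  within-participant manipulation. Per-`beta` tables remain available.
* **Rule-plus-exception regression**: per-(type, beta, block) means of
  Types 3-5, OLS `accuracy ~ block * type * beta` with Type 5 as reference.
  Block enters as an uncentered numeric 1-20 covariate, so type main
  effects are block-0 extrapolations; centering would change them but not
  the interactions, and the uncentered coding matches the single-slope
  interpretation of the block effect.
* **t-tests**: classical paired (`df = n - 1`) and pooled-variance
  two-sample (`df = n1 + n2 - 2`) tests. Zero-variance differences are an
  explicit error rather than a silent 0/0: the statistic is undefined
  there, even though equal inputs are sometimes loosely described as
  "t = 0".
* **Representation geometry**: `hidden_geometry()` maps the eight stimuli
  to hidden coordinates (sigmoid activations for DIVA, deterministic
  posterior means for BR-DIVA) and, for Types 3-5, the mean Euclidean
  distance from each category's exception to its rule-followers.
  `rule_exception_curves()` splits per-block error rates into
  rule-following and exception stimuli.

## What the simulations do and do not show

The generator emulates exactly the benchmark's study conditions: binary
three-feature stimuli, balanced two-way categorisation, blocked random
presentation with supervised feedback, and participant-level variability
coming only from initial weights, trial orders and latent noise. It does
not emulate real human data: no stopping criteria or criterion runs, no
per-subject parameter variation, no perceptual noise on the stimulus side,
no session or dataset effects. Passing tests therefore validate the models
and protocol, not any claim about people.

Two behaviours of the faithful implementation are worth flagging for
anyone comparing against published divergent-autoencoder results obtained
with other codebases or tuned hyperparameters. First, at these fixed
hyperparameters DIVA masters Types 1-4 but retains exception errors on
Type 5 (its mean accuracy plateaus near the 6/8 rule ceiling) and shows no
net learning on Type 6, where channel-specific training actively
anti-generalises across the parity structure's category boundary. Second,
as described above, BR-DIVA's useful dynamic range of `beta` at
`learning_rate = 1` ends near 0.5; the upper decades of the conventional
grid produce degenerate chance-level runs. Both follow from the exact
gradients and fixed step size, and both are visible directly in the
package's own learning-curve output.

## Problem sizes

The unit suite runs on small deterministic cases (single participants, 100
finite-difference gradient checks per model, exhaustive 35-grouping x
48-symmetry combinatorics). The end-to-end reproduction checks in the test
suite use 25 participants and a 10-value grid; `scripts/acceptance.R` and
`run_benchmark()` run the full protocol, 100 participants and the 50-value
grid, which takes a few minutes on one CPU.

```{r example, eval = FALSE}
trials <- shj_experiment(model = "BRDIVA", types = 1:6,
                         n_participants = 100, betas = beta_grid(50),
                         base_seed = 1)
fit_difficulty(trials)
```
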