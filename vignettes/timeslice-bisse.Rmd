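---
title: "Time-sliced BiSSE: model, inference and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-sliced BiSSE: model, inference and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epochsse)
```

## The model

`epochsse` fits binary-state speciation and extinction (BiSSE) models in
which all six rates are piecewise constant in time.  A lineage in state
$i \in \{0, 1\}$ (here: 0 = small-fruited, 1 = megafaunal-fruited)
speciates at rate $\lambda_i$, goes extinct at rate $\mu_i$, and switches
state at rate $q_{ij}$; each rate may change value at fixed ages
("epoch breakpoints"), such as the Quaternary onset at 2.6 Ma.  Ages are
measured in Ma before present, tips at age 0, so the most recent epoch is
$[0, 2.6)$ and an age exactly at a breakpoint belongs to the older epoch.

Along a branch, writing $E_i(s)$ for the probability that a lineage alive
at age $s$ in state $i$ leaves no sampled descendant and $D_i(s)$ for the
density of the observed subtree given state $i$, the standard BiSSE
equations hold per epoch:

$$\frac{dE_i}{ds} = \mu_i - (\lambda_i + \mu_i + q_{ij}) E_i
  + q_{ij} E_j + \lambda_i E_i^2$$
$$\frac{dD_i}{ds} = -(\lambda_i + \mu_i + q_{ij}) D_i
  + q_{ij} D_j + 2 \lambda_i E_i D_i$$

Incomplete sampling enters only through the tip conditions
($D_i = f_i \cdot [\text{state} = i]$, $E_i = 1 - f_i$), the skeletal-tree
correction with per-state sampling fractions $f_0, f_1 \in (0, 1]$.  At
internal nodes $D_i \leftarrow \lambda_i(\text{node age}) D_i^{L}
D_i^{R}$; at the root the state contributions are combined with
state-proportional ("FitzJohn") weights by default, and divided by
$\lambda_i (1 - E_i(T))^2$ to condition on both crown lineages surviving
to be sampled.  Both conventions follow the defaults of the standard
BiSSE software and are exposed through `lik_condition()` so their
sensitivity can be checked.

## Numerics

Branch segments are integrated with an adaptive Dormand–Prince 5(4)
stepper (compiled; relative tolerance $10^{-8}$, absolute $10^{-10}$),
switching rate sets exactly at breakpoints.  $D$ is rescaled to unit
maximum at every node with the log-factor accumulated — without this the
likelihood underflows on trees with thousands of tips.  $E$ is clamped to
$[0,1]$ against round-off.  Zero-length branches (present in posterior
tree samples) pass values through unchanged.  Tips are snapped to age 0
after an ultrametricity check at a relative tolerance of $10^{-6}$ of
tree height, absorbing the dating noise posterior samples carry.  The
test suite cross-checks the compiled integrator against an independent
fixed-step RK4 implementation, against closed forms (pure death, pure
Markov, Yule), and against the exact factorization
"equal-rates BiSSE = birth–death $\times$ Mk".

## The constrained model space

A two-epoch model is a mapping from the 12 rate slots
$\{\lambda_0, \lambda_1, \mu_0, \mu_1, q_{01}, q_{10}\} \times
\{\text{recent}, \text{old}\}$ onto shared free parameters
(`constraint_spec()`).  Per rate family the canonical generator crosses
four patterns — shared–constant, state-dependent, time-dependent,
state-and-time-dependent — giving 64 combinations, keeps those with at
most 7 free parameters, and adds the fully free 12-parameter model:
exactly 43 uniquely named models.  There is no single canonical
enumeration of such constrained sets, so the generator is deterministic,
documented, and replaceable: any list of
`constraint_spec`s (including asymmetric one-state-shift patterns
`"s0"`/`"s1"`) can be passed wherever a model set is accepted.

Model selection follows the dual criterion: likelihood-ratio tests for
structurally nested pairs (nesting is checked on the slot partitions) and
AIC globally.  `stepwise_search()` starts from the fully free model,
repeatedly accepts the immediate coarsening with the highest LRT p-value
above $\alpha$ (0.05 by default, configurable), and arbitrates
everything fitted by
the $\Delta\mathrm{AIC} < 2$ / fewest-parameters rule, with ties broken
by lower AIC and then model name.

## Inference

`fit_mle()` maximizes the likelihood over log-rates in the box
$[10^{-8}, 10^3]$ Myr$^{-1}$ — a derivative-free simplex pass polished by
L-BFGS-B, from several perturbed heuristic starts (SSE surfaces under
constraints are multimodal).  A smooth penalty outside the box keeps the
simplex from wandering into very-high-rate regions where the ODEs become
stiff and slow; this is purely a performance guard.  One-parameter
problems use Brent's method.

`run_mcmc()` is a univariate slice sampler (one coordinate sweep per
generation) on the natural rate scale with independent exponential priors
of rate $1/(2\hat r)$, where $\hat r = \log(n_{\text{tips}}/2)/T$ is the
character-independent net-diversification heuristic — the convention of
the standard BiSSE software.  Chains start at the MLE; slice widths are tuned during a 500-generation
warm-up that is not recorded; the default burn-in is 10% (both are
configurable and logged with each chain).  The
sampler is validated against the tractable pure-birth posterior, which is
Gamma in closed form.

## Simulators

Three designs mirror the validation studies the analysis calls for:

* `sim_mk_trait()` — exact CTMC simulation of a neutral binary trait down
  a fixed tree, with the full history recorded.
* `sim_bd_tree()` — constant-rate birth–death trees conditioned *jointly*
  on tip count and crown age.  The $n-2$ interior speciation times are
  drawn by inverse CDF from their known conditional density given
  survival (for rate difference $r = \lambda - \mu$:
  $F(t) \propto (1 - e^{-rt})/(\lambda - \mu e^{-rt})$), and the topology
  is assembled by splitting a uniformly chosen extant lineage at each
  time.  Rejection sampling is infeasible at 1774 tips near
  $\lambda \approx \mu$; this construction is exact and O(n).  The
  branching-time law is verified by KS tests against the analytic CDF.
* `sim_bisse_timeslice()` — forward Gillespie simulation of the joint
  tree + trait process with epoch-switching rates, starting from two
  crown lineages at the requested root age (the crown convention keeps
  the reconstructed root age exact and matches the pure-birth expectation
  $E[\text{tips}] = 2 e^{\lambda T}$).  Extinct lineages are pruned;
  draws are rejected until the surviving tip count falls in a window —
  exact-count conditioning has no tractable construction under
  state dependence.

`apply_sampling()` implements the skeletal-tree process the likelihood's
sampling-fraction correction assumes: each tip of state $i$ is retained
independently with probability $f_i$.

## Ancestral states

`marginal_ancestral_states()` combines the post-order partial likelihoods
below each node with a pre-order pass that transports the likelihood of
the rest of the tree down each branch, using the linear propagator of the
$D$ system (two extra unit-vector integrations per branch).
`stochastic_maps()` samples joint histories conditional on tips under the
Mk reduction: node states root-to-tips from their conditional
distributions, then each branch bridge exactly by uniformization (closed
form for two states; retry cap $10^4$ per branch).  Maps use the
trait-only process while marginals use the full fitted model —
deliberately, so the cheap and the model-complete route can be compared
as a consistency check.  The root prior for maps defaults to the stationary
distribution and is configurable; the agreement of map frequencies with
marginal reconstructions (within $2/\sqrt{n_{\text{maps}}}$) is asserted
in the test suite.

## The synthetic data generator

`generate_dataset()` emulates the statistical structure of a large palm
radiation with no external data: a birth–death tree conditioned on
species count and age (defaults 2539 species, 105 Ma, $\lambda = 0.2$,
$\mu = 0.19$); two clade-clustered regions painted by a slow symmetric
character (a handful of expected region changes, mimicking strong
regional endemism); a binary fruit-size state evolved with
region-specific $0 \to 1$ rates calibrated so the *measured* prevalences
hit the targets (12% globally, ~16% NW / ~10% OW) after per-state
missingness of 32% (small) / 18% (megafaunal) — the underlying true
prevalence is correspondingly lower ($p = m f_0 / (f_1(1-m) + f_0 m)$);
fruit lengths drawn from two lognormal components truncated to the
correct side of the 4 cm threshold, so the 3.5/4.5 cm sensitivity path is
exercisable end to end; one tagged clade (default 98 tips); and jittered
node-age replicates standing in for a posterior tree sample.  The desk
profile (300 species, 10 trees) keeps tests fast; the full profile is one
argument away.  What passing tests on these data do *not* show: real
posterior samples vary in topology, real missingness is not independent
across tips, and real fruit-length distributions are not lognormal — the
generator reproduces the calibration targets, not palm biology.

## Validation study design choices

The two epoch-shift studies state only the shifted values (extinction
$0.02 \to 0.3$; transition $0.005 \to 0.34$, both at 2.6 Ma).  The
remaining settings used here: speciation 0.2 Myr$^{-1}$ for both states
(the value of the companion birth–death study), baseline extinction 0.02
and transition 0.005 (the stated pre-shift values, applied
symmetrically), crown age 30 Ma with draws conditioned on 300–500
surviving tips (the desk-scale analogue of the full-size design), and a
megafaunal root state — the reconstructed ancestral condition of the
study system, and a necessary one: rates of a state that is absent from
a simulated tree are unidentifiable.  Refits use the generating
constraint structure (shared speciation; the shifted family free per
state and epoch, k = 6) with the fitting box capped at 20 Myr$^{-1}$ so
unidentified nuisance rates cannot drift into the stiff-ODE regime.

The pipeline's defaults are the full-scale settings (cut-off grid
25/20/15/10/5/2.6/1/0.5 Ma, 100 trees, 10 000 generations); tests and the
null-behaviour study run deliberately smaller configurations (stated in
each test) to keep the whole suite inside a desk-scale run.  The
per-cut-off quantity plotted through time is the *recent-epoch* rate of
the two-epoch model refitted with its breakpoint at that cut-off — the
reading of "rates per time slice" this package adopts; the model
structure is selected once at 2.6 Ma and held fixed across the grid.

## Known limitations

* Two states only; no hidden-state, multi-state, quantitative or
  geographic extensions, and no fossil tips.
* The 43-model set is one documented canonical construction; analyses
  committed to a different enumeration should pass their own list of
  `constraint_spec`s.
* Wald intervals on log-rates (used in the no-shift checks) are
  asymptotic; rates estimated at a bound have no meaningful interval.
* The slice sampler reports effective sample sizes but no further
  convergence diagnostics.
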