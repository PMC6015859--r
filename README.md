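# epochsse

Time-sliced binary-state speciation and extinction (BiSSE) models for R:
diversification analysis when a binary trait's macroevolutionary rates may
have shifted at known ages — for example, whether lineages bearing large
"megafaunal" fruits (≥ 4 cm) suffered elevated extinction or elevated
trait loss after the onset of the Quaternary (2.6 Ma), when their large
animal dispersers declined.

The package is aimed at phylogenetic comparative biologists who have an
ultrametric tree (or a posterior sample of trees), a binary tip trait, and
per-state sampling fractions, and who want to fit, select among, and
validate epoch-shift diversification models.

## The model

A lineage in state *i* ∈ {0, 1} speciates at rate λᵢ, goes extinct at
rate μᵢ, and switches state at rate q₀₁ or q₁₀ (all in Myr⁻¹); every rate
is piecewise constant in age, changing at user-chosen breakpoints (ages in
Ma before present; tips at 0). The likelihood is computed by post-order
ODE pruning of the standard BiSSE equations

    dEi/ds = μi − (λi + μi + qij) Ei + qij Ej + λi Ei²
    dDi/ds = −(λi + μi + qij) Di + qij Dj + 2 λi Ei Di

with per-state sampling fractions at the tips, FitzJohn root weighting,
and survival conditioning (both configurable). Around the likelihood sit:

* a constrained model space of up to 43 two-epoch models with
  likelihood-ratio / ΔAIC < 2 stepwise selection;
* maximum-likelihood fitting and slice-sampling MCMC across posterior
  tree samples, with pooled rate-through-time quantile summaries over a
  cut-off grid (25/20/15/10/5/2.6/1/0.5 Ma by default);
* marginal ancestral-state reconstruction and stochastic character maps;
* exact simulators: birth–death trees conditioned jointly on tip count
  and age, neutral-trait CTMC evolution, and forward Gillespie simulation
  of the joint tree + trait process with epoch shifts;
* a synthetic data generator emulating a palm-scale radiation (rare
  clustered trait, per-state missingness, two regions, posterior-like
  tree replicates) so every stage is testable offline.

## Worked example

Fit and compare a constant model against a Quaternary extinction-shift
model on simulated data:

```r
library(epochsse)

## simulate a tree + trait history with a true extinction shift for the
## megafaunal state (0.02 -> 0.3 Myr^-1 at 2.6 Ma)
truth <- shift_scenario_params("extinction")
h <- sim_bisse_timeslice(truth, root_age = 30, root_state = 1,
                         min_tips = 300, max_tips = 500, seed = 5)

## fit: shared speciation, state+epoch extinction, shared transition
spec <- spec_from_patterns(lambda = "c", mu = "st", q = "c")
fit  <- fit_mle(h$tree, h$tip_states, spec, breakpoint = 2.6,
                starts = 3, seed = 1)
fit
#> fit_result 'L:c_M:st_Q:c': logL = -866.081, k = 6, AIC = 1744.162
#>   lambda    mu0.r    mu1.r        q    mu0.o    mu1.o
#> 0.217668 0.000004 0.590011 0.011103 0.049264 0.050619
```

`mu1.r` (the megafaunal extinction rate in the recent epoch) comes back
far above `mu1.o`, recovering the built-in shift; speciation (`lambda`)
is estimated near its generating value 0.2. Averaged over 10 replicate
simulations the recent-epoch MLE is within ~10% of the generating 0.3
(single replicates are noisy — the recent epoch is only 2.6 Myr long):

```r
ext <- shift_recovery_study("extinction", n_rep = 10, seed = 1)
mean(ext$shift_recent)
#> [1] 0.3278427
sum(ext$shift_recent > ext$shift_old)
#> [1] 10
```

Model selection and the full time-window analysis:

```r
sel <- stepwise_search(h$tree, h$tip_states, breakpoint = 2.6, seed = 1)
attr(sel, "report")          # AIC table with the Delta-AIC < 2 choice
res <- run_timeslice_analysis(trees, traits, analysis_config(f = c(0.68, 0.82)))
res$rtt                      # recent-epoch rate quantiles per cut-off
```

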