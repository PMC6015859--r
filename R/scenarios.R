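## Canned validation study designs: the two epoch-shift scenarios (an
## extinction-rate shift 0.02 -> 0.3 and a transition-rate shift
## 0.005 -> 0.34 for the megafaunal state at the Quaternary onset), and
## the neutral-trait designs on large conditioned birth-death trees.

#' Rate parameters of the epoch-shift validation scenarios
#'
#' Both scenarios share speciation 0.2 Myr^-1 for the two states and a
#' Quaternary-onset breakpoint.  In the extinction scenario the megafaunal
#' state's extinction rate rises from 0.02 to 0.3 Myr^-1 in the recent
#' epoch (the other state keeps 0.02); in the transition scenario the
#' megafaunal-to-small rate rises from 0.005 to 0.34 Myr^-1 (the reverse
#' rate keeps 0.005).
#'
#' @param shift `"extinction"` or `"transition"`.
#' @param breakpoint shift age in Ma (default 2.6).
#' @return a [time_slice_params()] with two epochs.
#' @export
shift_scenario_params <- function(shift = c("extinction", "transition"),
                                  breakpoint = 2.6) {
  shift <- match.arg(shift)
  if (shift == "extinction") {
    time_slice_params(breakpoint, rbind(
      epoch_rates(0.2, 0.2, 0.02, 0.3, 0.005, 0.005),
      epoch_rates(0.2, 0.2, 0.02, 0.02, 0.005, 0.005)))
  } else {
    time_slice_params(breakpoint, rbind(
      epoch_rates(0.2, 0.2, 0.02, 0.02, 0.005, 0.34),
      epoch_rates(0.2, 0.2, 0.02, 0.02, 0.005, 0.005)))
  }
}

#' Epoch-shift recovery study
#'
#' Simulates replicate joint tree+trait histories under an epoch-shift
#' scenario (see [shift_scenario_params()]), conditioning each draw on a
#' surviving tip-count window, then refits the matching two-epoch model by
#' maximum likelihood (shared speciation; the shifted rate family free per
#' state and epoch) and collects the per-replicate estimates.
#'
#' The default crown age of 30 Ma yields a few hundred surviving tips under
#' the scenario rates — a desk-scale analogue of the full-size design.
#' The root state defaults to megafaunal (state 1), the reconstructed
#' ancestral condition of the study system.
#'
#' @param shift `"extinction"` or `"transition"`.
#' @param n_rep number of replicate histories (default 10).
#' @param root_age crown age of each simulation (Ma).
#' @param min_tips,max_tips surviving tip-count window (default 300-500).
#' @param seed master seed; replicate seeds derive from it by counter.
#' @param starts optimizer starts per fit.
#' @param root_state root state for the simulations.
#' @param breakpoint shift age (Ma).
#' @param upper fitting upper bound on rates (Myr^-1); 20 by default, far
#'   above any biologically plausible value for this design, which keeps
#'   unidentified nuisance rates from drifting into the stiff-ODE regime.
#' @return a data frame with one row per replicate: `n_tips`,
#'   `state1_frac`, `shift_recent`, `shift_old` (the shifted rate's
#'   recent/old-epoch MLEs), `other_recent`, `other_old` (the non-shifted
#'   state's rates from the same family), `logL`.  The generating recent
#'   value is in attribute `"truth"`.
#' @export
shift_recovery_study <- function(shift = c("extinction", "transition"),
                                 n_rep = 10, root_age = 30,
                                 min_tips = 300, max_tips = 500, seed = 1,
                                 starts = 2, root_state = 1,
                                 breakpoint = 2.6, upper = 20) {
  shift <- match.arg(shift)
  params <- shift_scenario_params(shift, breakpoint)
  fitspec <- if (shift == "extinction")
    spec_from_patterns("c", "st", "c") else spec_from_patterns("c", "c", "st")
  slot <- if (shift == "extinction")
    c("mu1.r", "mu1.o", "mu0.r", "mu0.o") else
      c("q1.r", "q1.o", "q0.r", "q0.o")
  truth <- if (shift == "extinction") 0.3 else 0.34
  rows <- lapply(seq_len(n_rep), function(i) {
    h <- sim_bisse_timeslice(params, root_age, root_state = root_state,
                             min_tips = min_tips, max_tips = max_tips,
                             seed = seed * 1000L + i)
    fit <- fit_mle(h$tree, h$tip_states, fitspec, breakpoint,
                   starts = starts, seed = seed * 1000L + i, upper = upper)
    ## the "c" pattern collapses the non-shifted family to one identifier,
    ## so look up slots defensively
    get_id <- function(id) if (id %in% names(fit$par)) fit$par[[id]] else NA_real_
    data.frame(n_tips = ape::Ntip(h$tree),
               state1_frac = mean(h$tip_states),
               shift_recent = get_id(slot[1]), shift_old = get_id(slot[2]),
               other_recent = get_id(slot[3]), other_old = get_id(slot[4]),
               logL = fit$logL)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  attr(out, "shift") <- shift
  out
}

#' Maximum-likelihood fit of the two-state Markov model
#'
#' @param tree,traits data as in [mk_loglik()].
#' @param symmetric fit one shared rate (`TRUE`) or two rates (`FALSE`).
#' @param cond root handling as in [mk_loglik()].
#' @param lower,upper rate bounds (Myr^-1).
#' @return list with `q01`, `q10` and `logL`.
#' @export
fit_mk <- function(tree, traits, symmetric = FALSE,
                   cond = lik_condition(), lower = 1e-8, upper = 1e3) {
  st <- .tip_states(tree, traits)
  lo <- log(lower); hi <- log(upper)
  if (symmetric) {
    o <- optimize(function(lq) -mk_loglik(tree, st, exp(lq), exp(lq), cond),
                  c(lo, hi), tol = 1e-8)
    list(q01 = exp(o$minimum), q10 = exp(o$minimum), logL = -o$objective)
  } else {
    nll <- function(lq) {
      v <- tryCatch(-mk_loglik(tree, st, exp(lq[1]), exp(lq[2]), cond),
                    error = function(e) NA_real_)
      if (!is.finite(v)) 1e10 else v
    }
    o <- optim(c(log(0.05), log(0.05)), nll, method = "L-BFGS-B",
               lower = lo, upper = hi)
    list(q01 = exp(o$par[1]), q10 = exp(o$par[2]), logL = -o$value)
  }
}

#' Neutral-trait study on conditioned birth-death trees
#'
#' Simulates replicate birth-death trees conditioned on tip count and age,
#' evolves a neutral binary trait on each, and refits the Mk transition
#' rate(s) by maximum likelihood.
#'
#' @param n_rep number of trees (default 10).
#' @param n_tips,age,lambda,mu tree simulation settings (defaults 1774
#'   tips, 105 Ma, speciation 0.2, extinction 0.19).
#' @param q01,q10 generating transition rates (defaults 0.02 symmetric).
#' @param symmetric_fit fit a shared rate (`TRUE`) or two rates.
#' @param seed master seed.
#' @return data frame with one row per tree: `q01_hat`, `q10_hat`,
#'   `state1_frac`, `logL`; generating rates in attribute `"truth"`.
#' @export
neutral_trait_study <- function(n_rep = 10, n_tips = 1774, age = 105,
                                lambda = 0.2, mu = 0.19, q01 = 0.02,
                                q10 = q01, symmetric_fit = q01 == q10,
                                seed = 1) {
  rows <- lapply(seq_len(n_rep), function(i) {
    tr <- sim_bd_tree(n_tips, age, lambda, mu, seed = seed * 1000L + i)
    h <- sim_mk_trait(tr, q01, q10, seed = seed * 1000L + 500L + i)
    st <- h$tip_states
    if (length(unique(st)) == 1)  # monomorphic draws carry no signal
      return(data.frame(q01_hat = NA_real_, q10_hat = NA_real_,
                        state1_frac = mean(st), logL = NA_real_))
    fit <- fit_mk(tr, st, symmetric = symmetric_fit)
    data.frame(q01_hat = fit$q01, q10_hat = fit$q10,
               state1_frac = mean(st), logL = fit$logL)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- c(q01 = q01, q10 = q10)
  out
}
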