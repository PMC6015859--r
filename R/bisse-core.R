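## Time-sliced BiSSE likelihood machinery.
##
## The model: a lineage in state i (0 small, 1 megafaunal) speciates at rate
## lambda_i, goes extinct at rate mu_i, and switches state at rate q_ij; all
## six rates are piecewise constant in age, changing at fixed breakpoints.
## Along a branch the usual BiSSE ODEs hold, integrated in age s (backwards
## in time):
##   dEi/ds = mu_i - (lambda_i + mu_i + q_ij) Ei + q_ij Ej + lambda_i Ei^2
##   dDi/ds = -(lambda_i + mu_i + q_ij) Di + q_ij Dj + 2 lambda_i Ei Di
## Ei is the probability that a lineage alive at age s in state i leaves no
## sampled descendant; Di the density of the observed subtree given state i.

RATE_NAMES <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

#' Per-epoch rate set
#'
#' @param lambda0,lambda1 speciation rates (Myr^-1) for states 0 and 1.
#' @param mu0,mu1 extinction rates (Myr^-1).
#' @param q01,q10 transition rates (Myr^-1), 0->1 and 1->0.
#' @return named numeric vector of class `epoch_rates`.
#' @export
epoch_rates <- function(lambda0, lambda1 = lambda0, mu0 = 0, mu1 = mu0,
                        q01 = 0, q10 = q01) {
  r <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all rates must be finite and non-negative")
  structure(r, class = "epoch_rates")
}

#' Time-sliced rate parameters
#'
#' Bundles breakpoint ages with one [epoch_rates()] set per epoch.  Epoch 0
#' is the most recent (youngest) interval.  With no breakpoints this is the
#' constant-rate BiSSE model.
#'
#' @param breakpoints strictly increasing ages (Ma); may be empty.
#' @param epochs a list of [epoch_rates()] (length `length(breakpoints)+1`,
#'   most recent first) or a numeric matrix with columns
#'   `lambda0, lambda1, mu0, mu1, q01, q10`.
#' @return an object of class `timeslice_params`.
#' @export
time_slice_params <- function(breakpoints, epochs) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) && is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (is.list(epochs)) epochs <- do.call(rbind, epochs)
  epochs <- matrix(as.numeric(epochs), ncol = 6,
                   dimnames = list(NULL, RATE_NAMES))
  if (nrow(epochs) != length(breakpoints) + 1)
    stop("need exactly length(breakpoints) + 1 epochs (most recent first)")
  if (any(!is.finite(epochs)) || any(epochs < 0))
    stop("all rates must be finite and non-negative")
  structure(list(breakpoints = breakpoints, epochs = epochs),
            class = "timeslice_params")
}

#' Likelihood conventions at the root
#'
#' @param root_mode `"fitzjohn"` (state weights proportional to the root
#'   partial likelihoods, the default), `"equal"`, or `"prior"` (supply
#'   `root_prior`).
#' @param root_prior numeric length-2 prior summing to 1 (used with
#'   `root_mode = "prior"`).
#' @param condition_on_survival divide each root state's contribution by
#'   `lambda_i (1 - Ei(T))^2`, conditioning on both root lineages leaving
#'   sampled descendants (default `TRUE`).
#' @return an object of class `lik_condition`.
#' @export
lik_condition <- function(root_mode = c("fitzjohn", "equal", "prior"),
                          root_prior = NULL, condition_on_survival = TRUE) {
  root_mode <- match.arg(root_mode)
  if (root_mode == "prior") {
    if (is.null(root_prior) || length(root_prior) != 2 ||
        abs(sum(root_prior) - 1) > 1e-8 || any(root_prior < 0))
      stop("root_prior must be a length-2 non-negative vector summing to 1")
  } else root_prior <- c(0.5, 0.5)
  structure(list(root_mode = root_mode, root_prior = as.numeric(root_prior),
                 condition_on_survival = isTRUE(condition_on_survival)),
            class = "lik_condition")
}

.root_mode_code <- function(cond)
  switch(cond$root_mode, fitzjohn = 0L, equal = 1L, prior = 2L)

#' BiSSE ODE right-hand side
#'
#' Pure-R statement of the derivatives, mainly for testing and
#' documentation; the tree likelihood uses a compiled integrator with the
#' identical right-hand side.
#'
#' @param age age (Ma); unused for constant rates but kept for the general
#'   signature.
#' @param y numeric length-4 state `(E0, E1, D0, D1)`.
#' @param rates an [epoch_rates()] vector.
#' @return numeric length-4 derivative with respect to age.
#' @export
ode_rhs <- function(age, y, rates) {
  if (any(!is.finite(y))) stop("NaN/Inf in ODE state")
  E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
  r <- unclass(rates)
  c(r["mu0"] - (r["lambda0"] + r["mu0"] + r["q01"]) * E0 + r["q01"] * E1 +
      r["lambda0"] * E0^2,
    r["mu1"] - (r["lambda1"] + r["mu1"] + r["q10"]) * E1 + r["q10"] * E0 +
      r["lambda1"] * E1^2,
    -(r["lambda0"] + r["mu0"] + r["q01"]) * D0 + r["q01"] * D1 +
      2 * r["lambda0"] * E0 * D0,
    -(r["lambda1"] + r["mu1"] + r["q10"]) * D1 + r["q10"] * D0 +
      2 * r["lambda1"] * E1 * D1) |> unname()
}

#' Integrate the BiSSE ODEs along a branch interval
#'
#' Integrates `(E, D)` from the younger age to the older age, switching
#' epoch rates exactly at breakpoints.  On return `D` is rescaled to unit
#' maximum, with the factor accumulated in `log_scale` (underflow
#' protection on large trees); `E` is unaffected by the rescaling.
#'
#' @param E_init,D_init numeric length-2 initial values at `age_lo`.
#' @param age_lo,age_hi interval in Ma, `age_lo < age_hi`.
#' @param params a [time_slice_params()].
#' @param rtol,atol integrator tolerances.
#' @return list with `E`, `D` (max-1 rescaled) and `log_scale`.
#' @export
integrate_branch <- function(E_init, D_init, age_lo, age_hi, params,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(age_lo < age_hi, length(E_init) == 2, length(D_init) == 2)
  if (any(E_init < 0 | E_init > 1)) stop("E must start within [0, 1]")
  if (any(D_init < 0)) stop("D must be non-negative")
  y <- .bisse_ode_cpp(c(E_init, D_init), age_lo, age_hi, params$epochs,
                      params$breakpoints, rtol, atol)
  if (any(!is.finite(y))) stop("branch integration failed (non-finite state)")
  D <- y[3:4]
  mx <- max(D)
  if (mx > 0) D <- D / mx
  list(E = y[1:2], D = D, log_scale = if (mx > 0) log(mx) else -Inf)
}

## internal: states as a named 0/1 vector aligned to tree tips
.tip_states <- function(tree, traits) {
  if (inherits(traits, "trait_dataset")) align_traits(traits, tree)
  else {
    st <- traits[tree$tip.label]
    if (anyNA(st))
      stop("missing tip states for: ",
           paste(head(tree$tip.label[is.na(st)], 5), collapse = ", "),
           "; prune these tips or impute states before fitting")
    st
  }
}

#' Time-sliced BiSSE log-likelihood
#'
#' Post-order ODE pruning with per-state sampling fractions applied at the
#' tips (`Di = f_i` for the observed state, `Ei = 1 - f_i`), speciation
#' combination at internal nodes, and root aggregation per
#' [lik_condition()].
#'
#' @param tree a validated ultrametric `phylo`.
#' @param traits a `trait_dataset` or named 0/1 vector; all tips must have
#'   non-missing states.
#' @param params a [time_slice_params()].
#' @param f length-2 per-state sampling fractions in `(0, 1]`
#'   (state 0, state 1).
#' @param cond a [lik_condition()].
#' @param rtol,atol integrator tolerances.
#' @return the log-likelihood (scalar).
#' @export
tree_loglik <- function(tree, traits, params, f = c(1, 1),
                        cond = lik_condition(), rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "timeslice_params"))
  if (length(f) != 2 || any(f <= 0) || any(f > 1))
    stop("sampling fractions must lie in (0, 1]")
  st <- .tip_states(tree, traits)
  tr <- ape::reorder.phylo(tree, "postorder")
  age <- node_ages(tr)
  res <- .bisse_loglik_cpp(tr$edge, age, as.integer(st), ape::Ntip(tr),
                           params$epochs, params$breakpoints, f[1], f[2],
                           .root_mode_code(cond), cond$root_prior,
                           cond$condition_on_survival, rtol, atol)
  ll <- res$loglik
  if (!is.finite(ll))
    stop("non-finite log-likelihood (degenerate parameters?)")
  ll
}

#' Constant-rate birth-death log-likelihood (closed form)
#'
#' Likelihood of a reconstructed ultrametric tree under a constant-rate
#' birth-death process with sampling fraction `rho`, evaluated from the
#' closed-form branch solutions (no ODE solver).  Conventions match
#' [tree_loglik()]: conditioning on survival of both root lineages divides
#' by `lambda (1 - E(T))^2`.  Serves as an independent oracle for the
#' equal-rates reduction of the BiSSE likelihood.
#'
#' @param tree a validated `phylo`.
#' @param lambda speciation rate (> 0 when the tree has internal nodes).
#' @param mu extinction rate (>= 0).
#' @param rho sampling fraction in `(0, 1]`.
#' @param condition_on_survival as in [lik_condition()].
#' @return log-likelihood.
#' @export
bd_loglik <- function(tree, lambda, mu = 0, rho = 1,
                      condition_on_survival = TRUE) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (mu < 0) stop("mu must be non-negative")
  if (lambda <= 0 && ape::Nnode(tree) >= 1)
    stop("lambda must be positive for a tree with internal nodes")
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  r <- lambda - mu
  ## y(a) = 1 - E(a) solves dy/da = y (r - lambda y), y(0) = rho:
  ##   y(a) = r rho e^{ra} / (r + lambda rho (e^{ra} - 1))        (r != 0)
  ##   y(a) = rho / (1 + lambda rho a)                            (r == 0)
  ## and D(a)/D(0) = e^{ra} [r / (r + lambda rho (e^{ra} - 1))]^2.
  near_crit <- abs(r) < 1e-12 * max(lambda, 1)
  logDfac <- function(a) {
    if (near_crit) -2 * log1p(lambda * rho * a)
    else r * a - 2 * log1p(lambda * rho * (exp(r * a) - 1) / r)
  }
  surv <- function(a) {
    if (near_crit) rho / (1 + lambda * rho * a)
    else r * rho * exp(r * a) / (r + lambda * rho * (exp(r * a) - 1))
  }
  ll <- ntip * log(rho)
  for (e in seq_len(nrow(tree$edge))) {
    a0 <- age[tree$edge[e, 2]]; a1 <- age[tree$edge[e, 1]]
    ll <- ll + logDfac(a1) - logDfac(a0)
  }
  ## one lambda per internal node (root included, as in the pruning pass)
  ll <- ll + (ntip - 1) * log(lambda)
  if (condition_on_survival) {
    Eroot <- 1 - surv(max(age))
    ll <- ll - log(lambda) - 2 * log(1 - Eroot)
  }
  ll
}

## 2-state CTMC transition probability matrix, closed form
.mk_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  p1 <- q01 / s; p0 <- q10 / s
  e <- exp(-s * t)
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e), 2, 2)
  ## rows: from-state 0, 1 (column-major fill above keeps [i, j] = P(i-1 -> j-1))
}

#' Two-state Markov (Mk) log-likelihood
#'
#' Standard pruning likelihood of a binary character under a continuous-time
#' Markov chain, using the closed-form 2x2 transition probabilities.  Root
#' weighting follows `cond$root_mode` (survival conditioning does not apply
#' to a pure character model and is ignored).
#'
#' @param tree a validated `phylo`.
#' @param traits a `trait_dataset` or named 0/1 vector.
#' @param q01,q10 transition rates (Myr^-1).
#' @param cond a [lik_condition()]; only the root mode is used.
#' @return log-likelihood.
#' @export
mk_loglik <- function(tree, traits, q01, q10, cond = lik_condition()) {
  if (q01 < 0 || q10 < 0) stop("transition rates must be non-negative")
  st <- .tip_states(tree, traits)
  if (q01 == 0 && q10 == 0 && length(unique(st)) > 1)
    stop("zero transition rates cannot produce mixed tip states")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + ape::Nnode(tr)
  L <- matrix(NA_real_, nnode, 2)
  L[cbind(seq_len(ntip), st + 1)] <- 1
  L[cbind(seq_len(ntip), 2 - st)] <- 0
  logcomp <- 0
  el <- tr$edge.length
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- .mk_pmat(q01, q10, el[e])
    v <- as.vector(P %*% L[ch, ])
    if (is.na(L[par, 1])) L[par, ] <- v
    else {
      L[par, ] <- L[par, ] * v
      mx <- max(L[par, ])
      if (mx <= 0) stop("Mk likelihood underflow")
      L[par, ] <- L[par, ] / mx
      logcomp <- logcomp + log(mx)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  w <- switch(cond$root_mode,
              fitzjohn = L[root, ] / sum(L[root, ]),
              equal = c(0.5, 0.5),
              prior = cond$root_prior)
  log(sum(w * L[root, ])) + logcomp
}
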