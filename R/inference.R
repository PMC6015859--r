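## Maximum-likelihood fitting under a constraint spec, and Bayesian MCMC
## by univariate slice sampling across posterior tree samples.

## run expr with a temporary RNG state seeded by `seed` (NULL = leave RNG
## alone), restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## character-independent net-diversification heuristic from tip count and
## tree age; floor keeps degenerate inputs usable as optimizer starts
.rhat <- function(tree) max(log(ape::Ntip(tree) / 2) / tree_height(tree), 1e-3)

## heuristic starting value per free-parameter identifier
.start_values <- function(spec, tree) {
  ids <- free_params(spec)
  rh <- .rhat(tree)
  v <- vapply(ids, function(id) {
    if (startsWith(id, "lambda")) 2 * rh
    else if (startsWith(id, "mu")) 0.5 * rh
    else 0.2 * rh
  }, 0)
  setNames(v, ids)
}

#' Maximum-likelihood fit of a constrained two-epoch BiSSE model
#'
#' Box-constrained maximization of [tree_loglik()] over the free parameters
#' of a [constraint_spec()], on the log-rate scale (bounds `[1e-8, 1e3]`
#' Myr^-1).  Optimization runs a derivative-free simplex pass followed by
#' L-BFGS-B, from `starts` perturbed heuristic starting points, and returns
#' the best converged optimum.
#'
#' @param tree,traits,f,cond data and conventions as in [tree_loglik()].
#' @param spec a [constraint_spec()].
#' @param breakpoint epoch boundary age (Ma); with a constant-rate spec the
#'   slicing is inert.
#' @param starts number of optimizer starts (>= 1).
#' @param seed integer seed for the start perturbations (NULL = use the
#'   current RNG stream).
#' @param lower,upper rate bounds (Myr^-1).
#' @param nm_maxit,bfgs_maxit iteration caps for the simplex and L-BFGS-B
#'   passes.
#' @return an object of class `fit_result`: `spec`, `par` (named MLE vector,
#'   natural scale), `logL`, `k`, `AIC`, `converged`, and a per-start
#'   `trace` data frame.
#' @export
fit_mle <- function(tree, traits, spec, breakpoint, f = c(1, 1),
                    cond = lik_condition(), starts = 5, seed = NULL,
                    lower = 1e-8, upper = 1e3, nm_maxit = 400,
                    bfgs_maxit = 200) {
  stopifnot(starts >= 1)
  st <- .tip_states(tree, traits)
  ids <- free_params(spec)
  lo <- log(lower); hi <- log(upper)
  nll <- function(lp) {
    ## smooth penalty outside the box: keeps the simplex pass from wandering
    ## into rate regions where the stiff ODEs would dominate run time
    over <- sum(pmax(lp - hi, 0)^2) + sum(pmax(lo - lp, 0)^2)
    if (over > 0) return(1e8 * (1 + over))
    par <- setNames(exp(lp), ids)
    val <- tryCatch(
      -tree_loglik(tree, st, spec_to_params(spec, par, breakpoint),
                   f = f, cond = cond),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  base <- log(.start_values(spec, tree))
  start_mat <- with_seed(seed, {
    m <- matrix(rep(base, starts), nrow = starts, byrow = TRUE)
    if (starts > 1)
      m[-1, ] <- m[-1, ] + matrix(rnorm((starts - 1) * length(ids), 0, 1),
                                  starts - 1)
    m
  })
  runs <- lapply(seq_len(starts), function(i) {
    p0 <- pmin(pmax(start_mat[i, ], lo), hi)
    if (length(ids) == 1) {
      o <- tryCatch(optim(p0, nll, method = "Brent", lower = lo,
                          upper = hi),
                    error = function(e) NULL)
      if (is.null(o)) return(NULL)
      return(list(par = o$par, value = o$value, conv = TRUE))
    }
    o1 <- tryCatch(optim(p0, nll, method = "Nelder-Mead",
                         control = list(maxit = nm_maxit)),
                   error = function(e) NULL)
    p1 <- if (!is.null(o1)) o1$par else p0
    o2 <- tryCatch(optim(pmin(pmax(p1, lo), hi), nll, method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(maxit = bfgs_maxit)),
                   error = function(e) NULL)
    cand <- list(
      if (!is.null(o1)) list(par = o1$par, value = o1$value, conv = TRUE),
      if (!is.null(o2)) list(par = o2$par, value = o2$value, conv = TRUE))
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) return(NULL)
    cand[[which.min(vapply(cand, `[[`, 0, "value"))]]
  })
  runs <- Filter(function(r) !is.null(r) && is.finite(r$value) &&
                   r$value < 1e9, runs)
  if (!length(runs))
    stop("all optimizer starts failed for model '", spec$name, "'")
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(vals)]]
  par <- setNames(exp(best$par), ids)
  logL <- -best$value
  structure(list(
    spec = spec, par = par, logL = logL, k = spec$k,
    AIC = aic(logL, spec$k), converged = TRUE,
    breakpoint = breakpoint, f = f, cond = cond,
    trace = data.frame(start = seq_along(vals), nll = vals)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result '", x$spec$name, "': logL = ", format(x$logL),
      ", k = ", x$k, ", AIC = ", format(x$AIC), "\n", sep = "")
  print(round(x$par, 6))
  invisible(x)
}

#' Approximate covariance of the log-rate MLE
#'
#' Numerical (central-difference) Hessian of the negative log-likelihood
#' with respect to the log-rates at the MLE, inverted to a covariance
#' matrix.  Used for Wald intervals on log-rates and log-rate contrasts.
#'
#' @param fit a `fit_result` from [fit_mle()].
#' @param tree,traits data the model was fit to.
#' @param h finite-difference step on the log scale.
#' @return covariance matrix over `free_params(fit$spec)` (log scale).
#' @export
fit_vcov_log <- function(fit, tree, traits, h = 1e-4) {
  st <- .tip_states(tree, traits)
  ids <- free_params(fit$spec)
  nll <- function(lp) {
    par <- setNames(exp(lp), ids)
    val <- tryCatch(
      -tree_loglik(tree, st, spec_to_params(fit$spec, par, fit$breakpoint),
                   f = fit$f, cond = fit$cond),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  x0 <- log(fit$par)
  n <- length(x0)
  H <- matrix(NA_real_, n, n)
  f0 <- nll(x0)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
    if (i == j) {
      H[i, i] <- (nll(x0 + ei) - 2 * f0 + nll(x0 - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (nll(x0 + ei + ej) - nll(x0 + ei - ej) -
           nll(x0 - ei + ej) + nll(x0 - ei - ej)) / (4 * h^2)
    }
  }
  V <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-8, n))
  })
  dimnames(V) <- list(ids, ids)
  V
}

#' Bayesian MCMC over the free parameters of a model
#'
#' Univariate slice sampling (one coordinate sweep per generation) on the
#' natural rate scale, with independent exponential priors on each free
#' rate.  The chain starts from the supplied initial point (typically the
#' MLE) and step widths are tuned during a warm-up phase that is not
#' recorded.
#'
#' @param tree,traits,f,cond data and conventions as in [tree_loglik()].
#' @param spec a [constraint_spec()].
#' @param breakpoint epoch boundary age (Ma).
#' @param generations recorded generations (default 10000).
#' @param seed integer seed; chains are reproducible given the seed.
#' @param prior_rate exponential prior rate; default `1 / (2 rhat)` with
#'   `rhat` the net-diversification heuristic from tip count and age.
#' @param init named initial parameter vector; default [fit_mle()] point.
#' @param warmup unrecorded tuning generations (default 500).
#' @param tree_id identifier stored with the chain.
#' @return an object of class `mcmc_chain`: `samples` (generations x k
#'   matrix), `logL` trace, `prior_rate`, `seed`, `tree_id`, `width`.
#' @export
run_mcmc <- function(tree, traits, spec, breakpoint, f = c(1, 1),
                     cond = lik_condition(), generations = 10000,
                     seed = NULL, prior_rate = NULL, init = NULL,
                     warmup = 500, tree_id = NA_character_) {
  stopifnot(generations >= 1)
  st <- .tip_states(tree, traits)
  ids <- free_params(spec)
  if (is.null(prior_rate)) prior_rate <- 1 / (2 * .rhat(tree))
  loglik <- function(par) {
    tryCatch(
      tree_loglik(tree, st, spec_to_params(spec, setNames(par, ids),
                                           breakpoint),
                  f = f, cond = cond),
      error = function(e) -Inf)
  }
  logpost <- function(par) {
    if (any(par <= 0)) return(-Inf)
    ll <- loglik(par)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(dexp(par, rate = prior_rate, log = TRUE))
  }
  if (is.null(init)) {
    init <- fit_mle(tree, traits, spec, breakpoint, f = f, cond = cond,
                    starts = 3, seed = seed)$par
  }
  x <- pmax(as.numeric(init[ids]), 1e-8)
  lp <- logpost(x)
  if (!is.finite(lp)) stop("non-finite posterior at the initial point")
  w <- pmax(x / 2, 0.05)
  k <- length(ids)
  samples <- matrix(NA_real_, generations, k, dimnames = list(NULL, ids))
  llout <- numeric(generations)
  with_seed(seed, {
    total <- warmup + generations
    for (g in seq_len(total)) {
      for (j in seq_len(k)) {
        y <- lp - rexp(1)
        u <- runif(1)
        L <- x[j] - u * w[j]
        R <- L + w[j]
        steps <- 0
        xl <- x; xr <- x
        while (L > 0 && steps < 50) {
          xl[j] <- L
          if (logpost(xl) <= y) break
          L <- L - w[j]; steps <- steps + 1
        }
        L <- max(L, 0)
        steps <- 0
        while (steps < 50) {
          xr[j] <- R
          if (logpost(xr) <= y) break
          R <- R + w[j]; steps <- steps + 1
        }
        repeat {
          xj <- runif(1, L, R)
          xp <- x; xp[j] <- xj
          lpp <- logpost(xp)
          if (lpp > y) {
            if (g <= warmup)
              w[j] <- 0.9 * w[j] + 0.1 * max(R - L, 1e-3)
            x <- xp; lp <- lpp
            break
          }
          if (xj < x[j]) L <- xj else R <- xj
          if (R - L < 1e-12) { x[j] <- x[j]; break }
        }
      }
      if (g > warmup) {
        samples[g - warmup, ] <- x
        llout[g - warmup] <- loglik(x)
      }
    }
  })
  structure(list(samples = samples, logL = llout, spec = spec,
                 breakpoint = breakpoint, prior_rate = prior_rate,
                 seed = seed, tree_id = tree_id, width = w),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("mcmc_chain: ", nrow(x$samples), " generations, ",
      ncol(x$samples), " parameters (tree ", x$tree_id, ")\n", sep = "")
  invisible(x)
}

#' Pooled posterior quantiles across chains
#'
#' Pools post-burn-in samples across chains (typically one chain per
#' posterior tree), expands the free parameters back onto the 12 rate
#' slots, derives per-state net diversification per epoch, and reports the
#' 5/25/50/75/95% quantiles.
#'
#' @param chains a list of `mcmc_chain`s sharing one `constraint_spec`.
#' @param burn_in fraction of each chain discarded (default 0.1).
#' @return a data frame keyed by `rate` and `epoch` with quantile columns
#'   `q05, q25, q50, q75, q95` and attribute `"n_pooled"`.
#' @export
summarize_posterior <- function(chains, burn_in = 0.1) {
  if (inherits(chains, "mcmc_chain")) chains <- list(chains)
  if (!length(chains)) stop("need at least one chain")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  spec <- chains[[1]]$spec
  kept <- lapply(chains, function(ch) {
    n <- nrow(ch$samples)
    drop <- floor(burn_in * n)
    if (drop >= n) stop("empty post-burn-in sample")
    ch$samples[(drop + 1):n, , drop = FALSE]
  })
  pooled <- do.call(rbind, kept)
  ## expand to slot values
  slots <- matrix(NA_real_, nrow(pooled), 12,
                  dimnames = list(NULL, SLOT_NAMES))
  for (sl in names(spec$map)) slots[, sl] <- pooled[, spec$map[[sl]]]
  if (!is.null(spec$fixed))
    for (sl in names(spec$fixed)) slots[, sl] <- spec$fixed[[sl]]
  derived <- cbind(
    "net0.recent" = slots[, "lambda0.recent"] - slots[, "mu0.recent"],
    "net1.recent" = slots[, "lambda1.recent"] - slots[, "mu1.recent"],
    "net0.old" = slots[, "lambda0.old"] - slots[, "mu0.old"],
    "net1.old" = slots[, "lambda1.old"] - slots[, "mu1.old"])
  all <- cbind(slots, derived)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  qs <- t(apply(all, 2, quantile, probs = probs, names = FALSE))
  nm <- strsplit(colnames(all), ".", fixed = TRUE)
  out <- data.frame(
    rate = vapply(nm, `[[`, "", 1),
    epoch = vapply(nm, `[[`, "", 2),
    q05 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3], q75 = qs[, 4],
    q95 = qs[, 5], row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_pooled") <- nrow(pooled)
  out
}

#' Effective sample size of a chain trace
#'
#' Initial-positive-sequence autocorrelation estimator.
#'
#' @param x numeric vector (one parameter's trace).
#' @return estimated effective sample size.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (i in seq_along(ac)) {
    if (ac[i] < 0) break
    s <- s + ac[i]
  }
  n / (1 + 2 * s)
}
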