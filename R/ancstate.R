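## Ancestral states: marginal probabilities under the (time-sliced) BiSSE
## process, and stochastic character maps under the Mk reduction.

#' Marginal ancestral state probabilities under BiSSE
#'
#' For each internal node, the marginal probability of each state given all
#' tip data, obtained by combining the post-order partial likelihoods below
#' the node with a pre-order pass that transports the likelihood of the
#' rest of the tree down each branch (via the linear propagator of the D
#' system, with E fixed by the same integration).
#'
#' @param tree,traits,params,f,cond as in [tree_loglik()].
#' @param rtol,atol integrator tolerances.
#' @return a matrix (internal nodes x 2) of state probabilities, rows
#'   named by node id; each row sums to 1.
#' @export
marginal_ancestral_states <- function(tree, traits, params, f = c(1, 1),
                                      cond = lik_condition(),
                                      rtol = 1e-8, atol = 1e-10) {
  st <- .tip_states(tree, traits)
  tr <- ape::reorder.phylo(tree, "postorder")
  age <- node_ages(tr)
  ntip <- ape::Ntip(tr)
  nnode <- ntip + ape::Nnode(tr)
  nedge <- nrow(tr$edge)
  eps <- params$epochs; breaks <- params$breakpoints
  lam_at <- function(a) eps[epoch_index(a, breaks) + 1L, c("lambda0", "lambda1")]

  Dnode <- matrix(NA_real_, nnode, 2)   # partials below each node (scaled)
  Enode <- matrix(NA_real_, nnode, 2)
  Dtop <- matrix(NA_real_, nedge, 2)    # branch-top partials per edge
  Ebot <- matrix(NA_real_, nedge, 2)    # E at the branch's younger end
  Dnode[seq_len(ntip), ] <- cbind(ifelse(st == 0, f[1], 0),
                                  ifelse(st == 1, f[2], 0))
  Enode[seq_len(ntip), ] <- matrix(1 - f, ntip, 2, byrow = TRUE)

  for (e in seq_len(nedge)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    y0 <- c(Enode[ch, ], Dnode[ch, ])
    Ebot[e, ] <- Enode[ch, ]
    y <- if (age[par] - age[ch] > 1e-12)
      .bisse_ode_cpp(y0, age[ch], age[par], eps, breaks, rtol, atol)
    else y0
    Dtop[e, ] <- y[3:4]
    if (is.na(Dnode[par, 1])) {
      Enode[par, ] <- y[1:2]
      Dnode[par, ] <- y[3:4]
    } else {
      Enode[par, ] <- (Enode[par, ] + y[1:2]) / 2
      Dnode[par, ] <- lam_at(age[par]) * Dnode[par, ] * y[3:4]
      mx <- max(Dnode[par, ])
      if (mx <= 0) stop("likelihood underflow in ancestral-state pass")
      Dnode[par, ] <- Dnode[par, ] / mx
      ## rescale the stored branch tops consistently is unnecessary: each
      ## node's marginal is normalized, so per-node scaling cancels
    }
  }

  root <- tr$edge[nedge, 1]
  d <- Dnode[root, ]
  w <- switch(cond$root_mode,
              fitzjohn = d / sum(d),
              equal = c(0.5, 0.5),
              prior = cond$root_prior)
  G <- matrix(NA_real_, nnode, 2)       # likelihood of the rest of the tree
  g_root <- w
  if (cond$condition_on_survival) {
    lam_r <- lam_at(age[root])
    g_root <- g_root / (lam_r * (1 - Enode[root, ])^2)
  }
  G[root, ] <- g_root / sum(g_root)

  children <- split(seq_len(nedge), tr$edge[, 1])
  for (e in rev(seq_len(nedge))) {      # pre-order over edges
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sibs <- setdiff(children[[as.character(par)]], e)
    gtop <- G[par, ] * lam_at(age[par]) * Dtop[sibs, ]
    if (age[par] - age[ch] > 1e-12) {
      ## columns of the branch propagator M: D_top = M D_bottom
      m1 <- .bisse_ode_cpp(c(Ebot[e, ], 1, 0), age[ch], age[par], eps,
                           breaks, rtol, atol)[3:4]
      m2 <- .bisse_ode_cpp(c(Ebot[e, ], 0, 1), age[ch], age[par], eps,
                           breaks, rtol, atol)[3:4]
      g <- c(gtop[1] * m1[1] + gtop[2] * m1[2],
             gtop[1] * m2[1] + gtop[2] * m2[2])   # t(M) %*% gtop
    } else g <- gtop
    G[ch, ] <- g / sum(g)
  }

  internal <- (ntip + 1L):nnode
  p <- G[internal, , drop = FALSE] * Dnode[internal, , drop = FALSE]
  p <- p / rowSums(p)
  rownames(p) <- internal
  colnames(p) <- c("state0", "state1")
  p
}

## ---- stochastic character maps (Mk) ----------------------------------

## R^n entries for the uniformized chain, closed form (2 states)
.unif_Rn <- function(q01, q10, omega, n) {
  s <- q01 + q10
  p1 <- q01 / s; p0 <- q10 / s
  g <- (1 - s / omega)^n
  matrix(c(p0 + p1 * g, p0 - p0 * g,
           p1 - p1 * g, p1 + p0 * g), 2, 2)  # [i, j], 1-based states
}

## sample a CTMC bridge on a branch of length t with endpoint states i, j
## (0/1); returns jump ages measured from the older end, and the state
## sequence.  Exact via uniformization; no rejection.
.mk_bridge <- function(i, j, t, q01, q10, retry = 1e4) {
  if (q01 + q10 == 0 || t <= 0) {
    if (i != j) stop("impossible endpoint combination with zero rates")
    return(list(times = numeric(0), states = i))
  }
  omega <- max(q01, q10)
  Pij <- .mk_pmat(q01, q10, t)[i + 1, j + 1]
  for (att in seq_len(retry)) {
    ## sample the number of uniformized jumps N
    u <- runif(1) * Pij
    n <- 0; acc <- 0; wn <- exp(-omega * t)
    repeat {
      Rn <- .unif_Rn(q01, q10, omega, n)
      acc <- acc + wn * Rn[i + 1, j + 1]
      if (acc >= u || n > 5000) break
      n <- n + 1
      wn <- wn * omega * t / n
    }
    if (n > 5000) next  # numeric corner; retry
    if (n == 0) return(list(times = numeric(0), states = i))
    jump_t <- sort(runif(n)) * t
    R1 <- .unif_Rn(q01, q10, omega, 1)
    states <- integer(n + 1); states[1] <- i
    ok <- TRUE
    for (k in seq_len(n)) {
      rem <- n - k
      a <- states[k]
      Rrem <- .unif_Rn(q01, q10, omega, rem)
      Rrem1 <- .unif_Rn(q01, q10, omega, rem + 1)
      pr <- c(R1[a + 1, 1] * Rrem[1, j + 1],
              R1[a + 1, 2] * Rrem[2, j + 1]) / Rrem1[a + 1, j + 1]
      if (any(!is.finite(pr)) || sum(pr) <= 0) { ok <- FALSE; break }
      states[k + 1] <- (runif(1) < pr[2] / sum(pr)) * 1L
    }
    if (!ok) next
    if (states[n + 1] != j) next  # guard; the bridge should force j
    ## strip virtual (self) jumps
    real <- which(diff(states) != 0)
    return(list(times = jump_t[real], states = c(i, states[real + 1])))
  }
  stop("endpoint-conditioned branch sampling failed after ", retry,
       " retries")
}

#' Stochastic character maps of a binary trait
#'
#' Samples joint character histories conditional on the tip states under a
#' two-state Markov model: node states are drawn root-to-tips from their
#' conditional distributions, then each branch history is drawn exactly,
#' conditional on its endpoint states, by uniformization.
#'
#' @param tree a validated `phylo`.
#' @param traits a `trait_dataset` or named 0/1 vector.
#' @param q01,q10 transition rates (Myr^-1).
#' @param n_maps number of maps (default 500).
#' @param seed integer seed.
#' @param root_prior `"stationary"` (default), `"equal"`, `"fitzjohn"`, or
#'   a numeric length-2 prior.
#' @return a list: `maps` (each a per-branch segment table with `edge`,
#'   `parent`, `child`, `state`, `start_age`, `end_age`), `node_freq`
#'   (per-node frequency of state 1 across maps, named by node id) and
#'   `n_transitions` per map.
#' @export
stochastic_maps <- function(tree, traits, q01, q10, n_maps = 500,
                            seed = NULL, root_prior = "stationary") {
  stopifnot(n_maps >= 1, q01 >= 0, q10 >= 0)
  st <- .tip_states(tree, traits)
  tr <- ape::reorder.phylo(tree, "postorder")
  age <- node_ages(tr)
  ntip <- ape::Ntip(tr)
  nnode <- ntip + ape::Nnode(tr)
  nedge <- nrow(tr$edge)
  ## down-pass conditional likelihoods
  F <- matrix(NA_real_, nnode, 2)
  F[cbind(seq_len(ntip), st + 1)] <- 1
  F[cbind(seq_len(ntip), 2 - st)] <- 0
  for (e in seq_len(nedge)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    v <- as.vector(.mk_pmat(q01, q10, tr$edge.length[e]) %*% F[ch, ])
    if (is.na(F[par, 1])) F[par, ] <- v
    else {
      F[par, ] <- F[par, ] * v
      F[par, ] <- F[par, ] / max(F[par, ])
    }
  }
  root <- tr$edge[nedge, 1]
  pi_root <- if (is.numeric(root_prior)) root_prior
  else switch(root_prior,
              stationary = if (q01 + q10 > 0)
                c(q10, q01) / (q01 + q10) else c(0.5, 0.5),
              equal = c(0.5, 0.5),
              fitzjohn = F[root, ] / sum(F[root, ]),
              stop("unknown root prior"))
  preorder <- rev(seq_len(nedge))
  state1_count <- numeric(nnode)
  maps <- vector("list", n_maps)
  n_trans <- integer(n_maps)
  with_seed(seed, {
    for (m in seq_len(n_maps)) {
      node_state <- integer(nnode)
      pr <- pi_root * F[root, ]
      node_state[root] <- (runif(1) < pr[2] / sum(pr)) * 1L
      segs <- vector("list", nedge)
      ntr <- 0L
      for (e in preorder) {
        par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        i <- node_state[par]
        P <- .mk_pmat(q01, q10, tr$edge.length[e])
        pj <- P[i + 1, ] * F[ch, ]
        jst <- (runif(1) < pj[2] / sum(pj)) * 1L
        node_state[ch] <- jst
        br <- .mk_bridge(i, jst, tr$edge.length[e], q01, q10)
        ntr <- ntr + length(br$times)
        bounds <- c(age[par], age[par] - br$times, age[ch])
        k <- length(br$states)
        segs[[e]] <- data.frame(edge = e, parent = par, child = ch,
                                state = br$states,
                                start_age = bounds[seq_len(k)],
                                end_age = bounds[-1])
      }
      state1_count <- state1_count + node_state
      maps[[m]] <- do.call(rbind, segs)
      n_trans[m] <- ntr
    }
  })
  list(maps = maps, node_freq = setNames(state1_count / n_maps,
                                         seq_len(nnode)),
       n_transitions = n_trans)
}
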