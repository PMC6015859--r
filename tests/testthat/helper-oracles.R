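# Independent oracles, deliberately sharing no code with the package's
# compiled integrator: a fixed-step classical RK4 BiSSE integrator and
# pruning likelihood in plain R, and a matrix-exponential Mk likelihood.

rk4_rhs <- function(y, r) {
  E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
  c(r["mu0"] - (r["lambda0"] + r["mu0"] + r["q01"]) * E0 + r["q01"] * E1 +
      r["lambda0"] * E0^2,
    r["mu1"] - (r["lambda1"] + r["mu1"] + r["q10"]) * E1 + r["q10"] * E0 +
      r["lambda1"] * E1^2,
    -(r["lambda0"] + r["mu0"] + r["q01"]) * D0 + r["q01"] * D1 +
      2 * r["lambda0"] * E0 * D0,
    -(r["lambda1"] + r["mu1"] + r["q10"]) * D1 + r["q10"] * D0 +
      2 * r["lambda1"] * E1 * D1)
}

## fixed-step RK4 over [a0, a1], splitting at epoch breakpoints
rk4_integrate <- function(y, a0, a1, params, step = 1e-3) {
  breaks <- params$breakpoints
  bounds <- c(a0, breaks[breaks > a0 & breaks < a1], a1)
  for (j in seq_len(length(bounds) - 1)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    r <- params$epochs[sum(breaks <= lo) + 1, ]
    n <- max(1L, ceiling((hi - lo) / step))
    h <- (hi - lo) / n
    for (i in seq_len(n)) {
      k1 <- rk4_rhs(y, r)
      k2 <- rk4_rhs(y + h / 2 * k1, r)
      k3 <- rk4_rhs(y + h / 2 * k2, r)
      k4 <- rk4_rhs(y + h * k3, r)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  y
}

## full pruning likelihood with the RK4 integrator (FitzJohn root +
## survival conditioning, matching the package defaults)
rk4_loglik <- function(tree, states, params, f = c(1, 1), step = 1e-3,
                       condition = TRUE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  age <- node_ages(tr)
  ntip <- ape::Ntip(tr)
  breaks <- params$breakpoints
  nnode <- ntip + tr$Nnode
  Y <- matrix(NA_real_, nnode, 4)
  st <- states[tr$tip.label]
  Y[seq_len(ntip), 1] <- 1 - f[1]
  Y[seq_len(ntip), 2] <- 1 - f[2]
  Y[seq_len(ntip), 3] <- ifelse(st == 0, f[1], 0)
  Y[seq_len(ntip), 4] <- ifelse(st == 1, f[2], 0)
  logcomp <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    y <- Y[ch, ]
    if (age[par] > age[ch] + 1e-14)
      y <- rk4_integrate(y, age[ch], age[par], params, step)
    if (is.na(Y[par, 1])) Y[par, ] <- y
    else {
      lam <- params$epochs[sum(breaks <= age[par]) + 1, c("lambda0", "lambda1")]
      D <- lam * Y[par, 3:4] * y[3:4]
      mx <- max(D)
      logcomp <- logcomp + log(mx)
      Y[par, ] <- c((Y[par, 1:2] + y[1:2]) / 2, D / mx)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  d <- Y[root, 3:4]; Ev <- Y[root, 1:2]
  w <- d / sum(d)
  lam <- params$epochs[sum(breaks <= age[root]) + 1, c("lambda0", "lambda1")]
  contrib <- if (condition) d / (lam * (1 - Ev)^2) else d
  log(sum(w * contrib)) + logcomp
}

## Mk likelihood via expm of the full rate matrix (equal root weights)
expm2 <- function(Q, t) {
  ev <- eigen(Q)
  Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors))
}

mk_loglik_expm <- function(tree, states, q01, q10,
                           root_w = c(0.5, 0.5)) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  L <- matrix(NA_real_, ntip + tr$Nnode, 2)
  st <- states[tr$tip.label]
  L[cbind(seq_len(ntip), st + 1)] <- 1
  L[cbind(seq_len(ntip), 2 - st)] <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- expm2(Q, tr$edge.length[e])
    v <- as.vector(P %*% L[ch, ])
    if (is.na(L[par, 1])) L[par, ] <- v else L[par, ] <- L[par, ] * v
  }
  root <- tr$edge[nrow(tr$edge), 1]
  if (identical(root_w, "fitzjohn")) root_w <- L[root, ] / sum(L[root, ])
  log(sum(root_w * L[root, ]))
}

## random small ultrametric test tree with a trait
random_instance <- function(ntip = 10, seed = 1) {
  tr <- sim_bd_tree(ntip, runif(1, 5, 20), runif(1, 0.2, 0.5),
                    runif(1, 0, 0.15), seed = seed)
  st <- sim_mk_trait(tr, runif(1, 0.05, 0.4), runif(1, 0.05, 0.4),
                     seed = seed + 1)$tip_states
  if (length(unique(st)) == 1) st[1] <- 1 - st[1]  # keep both states present
  list(tree = tr, states = st)
}
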