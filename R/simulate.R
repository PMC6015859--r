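## Simulators: neutral binary traits on fixed trees, birth-death trees
## conditioned jointly on tip count and crown age, and joint tree+trait
## simulation under time-sliced state-dependent rates.

## Convert lineage records to an ape phylo.  Lineages are rows: parent
## lineage id (0 for the two crown lineages), birth age, end age (0 for
## extant tips, >0 for extinct tips or split ages).  `has_child` marks
## lineages that split.  A synthetic crown node joins lineages 1 and 2.
.records_to_phylo <- function(parent, birth, end, has_child,
                              tip_prefix = "t") {
  n_lin <- length(parent)
  is_tip <- !has_child
  ntip <- sum(is_tip)
  if (ntip < 2) stop("fewer than two tips; cannot build a tree")
  tip_id <- integer(n_lin)
  tip_id[is_tip] <- seq_len(ntip)
  node_id <- integer(n_lin)
  node_id[has_child] <- ntip + 1L + seq_len(sum(has_child))
  node_of <- function(l) if (is_tip[l]) tip_id[l] else node_id[l]
  edge <- matrix(0L, n_lin, 2)
  elen <- numeric(n_lin)
  for (l in seq_len(n_lin)) {
    p <- parent[l]
    edge[l, 1] <- if (p == 0L) ntip + 1L else node_of(p)
    edge[l, 2] <- node_of(l)
    elen[l] <- birth[l] - end[l]
  }
  labels <- paste0(tip_prefix, which(is_tip))
  tr <- list(edge = edge, edge.length = elen, tip.label = labels,
             Nnode = sum(has_child) + 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "lineage_of_tip") <- setNames(which(is_tip), labels)
  tr
}

#' Simulate a neutral binary trait on a fixed tree
#'
#' Exact continuous-time Markov simulation down the tree (exponential
#' waiting times between state flips), recording the full character
#' history.
#'
#' @param tree a validated ultrametric `phylo`.
#' @param q01,q10 transition rates (Myr^-1), 0->1 and 1->0.
#' @param root_state 0, 1 or `NULL` (draw from the stationary distribution;
#'   50/50 when both rates are zero).
#' @param seed integer seed; the history replays deterministically.
#' @return an object of class `sim_history` with elements `tree`,
#'   `tip_states` (named 0/1 vector), `segments` (per-edge state segments,
#'   ages decreasing), `events` (transition log) and `params`.
#' @export
sim_mk_trait <- function(tree, q01, q10, root_state = NULL, seed = NULL) {
  if (q01 < 0 || q10 < 0) stop("rates must be non-negative")
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  with_seed(seed, {
    if (is.null(root_state)) {
      p1 <- if (q01 + q10 > 0) q01 / (q01 + q10) else 0.5
      root_state <- rbinom(1, 1, p1)
    }
    node_state <- integer(ntip + ape::Nnode(tree))
    node_state[root] <- root_state
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    seg <- vector("list", nrow(tr$edge))
    ev <- vector("list", nrow(tr$edge))
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      a <- age[par]; a_end <- age[ch]
      s <- node_state[par]
      starts <- a; states <- s
      repeat {
        rate <- if (s == 0) q01 else q10
        if (rate <= 0) break
        dt <- rexp(1, rate)
        if (a - dt <= a_end) break
        a <- a - dt
        s <- 1L - s
        starts <- c(starts, a); states <- c(states, s)
      }
      node_state[ch] <- s
      k <- length(starts)
      seg[[e]] <- data.frame(edge = e, parent = par, child = ch,
                             state = states, start_age = starts,
                             end_age = c(starts[-1], a_end))
      if (k > 1)
        ev[[e]] <- data.frame(age = starts[-1], edge = e,
                              from = states[-k], to = states[-1])
    }
    tip_states <- setNames(node_state[seq_len(ntip)], tr$tip.label)
    structure(list(tree = tree, tip_states = tip_states,
                   node_states = node_state,
                   segments = do.call(rbind, seg),
                   events = do.call(rbind, ev),
                   params = c(q01 = q01, q10 = q10,
                              root_state = root_state),
                   seed = seed),
              class = "sim_history")
  })
}

#' @export
print.sim_history <- function(x, ...) {
  cat("sim_history: ", ape::Ntip(x$tree), " tips, ",
      if (is.null(x$events)) 0 else nrow(x$events), " recorded events\n",
      sep = "")
  invisible(x)
}

#' Simulate a birth-death tree conditioned on tip count and crown age
#'
#' Draws a reconstructed constant-rate birth-death tree with exactly
#' `n_tips` extant tips and crown age exactly `age`, using the
#' inverse-CDF construction for the n-2 interior speciation times
#' conditional on survival to the present (not rejection sampling, which is
#' infeasible for large trees near criticality).  Given the times, the
#' topology is assembled by splitting a uniformly chosen extant lineage at
#' each successive speciation.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param age crown age (Ma, > 0).
#' @param lambda speciation rate (> 0).
#' @param mu extinction rate (>= 0).
#' @param seed integer seed.
#' @return an ultrametric `phylo` with `n_tips` tips and height `age`.
#' @export
sim_bd_tree <- function(n_tips, age, lambda, mu = 0, seed = NULL) {
  stopifnot(n_tips >= 2, age > 0, lambda > 0, mu >= 0)
  r <- lambda - mu
  near_crit <- abs(r) < 1e-12 * lambda
  ## u(t) = integral of the conditional speciation-time density kernel
  u_of <- function(t) {
    if (near_crit) t / (1 + lambda * t)
    else (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
  }
  inv_u <- function(c) {
    if (near_crit) c / (1 - lambda * c)
    else -log((1 - c * lambda) / (1 - c * mu)) / r
  }
  with_seed(seed, {
    n_extra <- n_tips - 2L
    times <- if (n_extra > 0) {
      uT <- u_of(age)
      sort(vapply(runif(n_extra) * uT, inv_u, 0), decreasing = TRUE)
    } else numeric(0)
    ## forward assembly: split a uniformly chosen current lineage
    n_lin <- 2L * n_tips - 2L
    parent <- integer(n_lin); birth <- numeric(n_lin); end <- numeric(n_lin)
    has_child <- logical(n_lin)
    parent[1:2] <- 0L; birth[1:2] <- age
    alive <- c(1L, 2L)
    nxt <- 3L
    for (t in times) {
      pick <- alive[sample.int(length(alive), 1)]
      end[pick] <- t
      has_child[pick] <- TRUE
      parent[nxt] <- pick; birth[nxt] <- t
      parent[nxt + 1L] <- pick; birth[nxt + 1L] <- t
      alive <- c(alive[alive != pick], nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    end[alive] <- 0
    tr <- .records_to_phylo(parent[seq_len(nxt - 1L)],
                            birth[seq_len(nxt - 1L)],
                            end[seq_len(nxt - 1L)],
                            has_child[seq_len(nxt - 1L)])
    validate_tree(tr)
  })
}

#' Joint tree and trait simulation under time-sliced BiSSE
#'
#' Forward-in-time Gillespie simulation from two crown lineages at
#' `root_age`, with per-state speciation, extinction and transition rates
#' switching at the breakpoints of `params`.  Extinct lineages are pruned
#' to give the reconstructed tree; a draw is rejected and redrawn unless
#' the number of surviving tips falls inside `[min_tips, max_tips]`.  The
#' full pre-pruning history is retained.
#'
#' @param params a [time_slice_params()].
#' @param root_age crown age (Ma).
#' @param root_state 0, 1 or `NULL` (draw 50/50 per attempt); both crown
#'   lineages inherit it.
#' @param min_tips,max_tips acceptance window on surviving tip count.
#' @param seed integer seed.
#' @param max_attempts rejection budget.
#' @param max_lineages explosion guard; exceeding it rejects the attempt.
#' @return a `sim_history` with the reconstructed `tree`, `tip_states`,
#'   `full_tree`, per-lineage `segments`, `events`, `params`, `seed` and
#'   the number of attempts used.
#' @export
sim_bisse_timeslice <- function(params, root_age, root_state = NULL,
                                min_tips = 2, max_tips = Inf, seed = NULL,
                                max_attempts = 1000, max_lineages = 1e5) {
  stopifnot(inherits(params, "timeslice_params"), root_age > 0)
  breaks <- params$breakpoints
  eps <- params$epochs
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      rs <- if (is.null(root_state)) rbinom(1, 1, 0.5) else root_state
      sim <- .gillespie_once(eps, breaks, root_age, rs, max_lineages)
      if (is.null(sim)) next
      n_extant <- sum(sim$end == 0 & !sim$has_child)
      if (n_extant < max(min_tips, 2) || n_extant > max_tips) next
      full <- .records_to_phylo(sim$parent, sim$birth, sim$end,
                                sim$has_child)
      lin_of <- attr(full, "lineage_of_tip")
      extinct <- names(lin_of)[sim$end[lin_of] > 0]
      rec <- if (length(extinct)) ape::drop.tip(full, extinct) else full
      final_state <- vapply(sim$state_hist, function(h) h$state[length(h$state)],
                            0L)
      tip_states <- setNames(final_state[lin_of[rec$tip.label]],
                             rec$tip.label)
      seg <- do.call(rbind, lapply(seq_along(sim$state_hist), function(l) {
        h <- sim$state_hist[[l]]
        k <- length(h$state)
        data.frame(lineage = l, state = h$state, start_age = h$age,
                   end_age = c(h$age[-1], sim$end[l]))
      }))
      return(structure(list(
        tree = rec, full_tree = full, tip_states = tip_states,
        segments = seg, events = sim$events, params = params,
        root_state = rs, seed = seed, attempts = attempt,
        n_extant = n_extant), class = "sim_history"))
    }
    stop("rejection budget exhausted after ", max_attempts,
         " attempts (acceptance rate < ", format(1 / max_attempts),
         "); widen the tip window or adjust rates")
  })
}

## one forward Gillespie pass; returns NULL if everything went extinct or
## the lineage cap was hit
.gillespie_once <- function(eps, breaks, root_age, root_state,
                            max_lineages) {
  root_state <- as.integer(root_state)
  cap <- 4096L
  parent <- integer(cap); birth <- numeric(cap); end <- numeric(cap)
  has_child <- logical(cap); state <- integer(cap)
  state_hist <- vector("list", cap)
  grow <- function(n) {
    length(parent) <<- n; length(birth) <<- n; length(end) <<- n
    length(has_child) <<- n; length(state) <<- n
    length(state_hist) <<- n
  }
  parent[1:2] <- 0L; birth[1:2] <- root_age; state[1:2] <- root_state
  state_hist[[1]] <- list(age = root_age, state = root_state)
  state_hist[[2]] <- list(age = root_age, state = root_state)
  alive0 <- integer(0); alive1 <- integer(0)
  if (root_state == 0) alive0 <- c(1L, 2L) else alive1 <- c(1L, 2L)
  nxt <- 3L
  ev_age <- numeric(0); ev_lin <- integer(0); ev_type <- character(0)
  a <- root_age
  repeat {
    n0 <- length(alive0); n1 <- length(alive1)
    if (n0 + n1 == 0L) return(NULL)
    if (n0 + n1 > max_lineages) return(NULL)
    ep <- sum(breaks < a) + 1L   # row of the epoch containing (b, a)
    l0 <- eps[ep, 1]; l1 <- eps[ep, 2]; m0 <- eps[ep, 3]; m1 <- eps[ep, 4]
    q01 <- eps[ep, 5]; q10 <- eps[ep, 6]
    R <- n0 * (l0 + m0 + q01) + n1 * (l1 + m1 + q10)
    b_next <- if (ep > 1) breaks[ep - 1] else 0
    a_new <- if (R > 0) a - rexp(1, R) else -Inf
    if (a_new <= b_next) {
      if (b_next == 0) break     # reached the present
      a <- b_next
      next                       # epoch change; redraw waiting time
    }
    a <- a_new
    w <- c(n0 * l0, n0 * m0, n0 * q01, n1 * l1, n1 * m1, n1 * q10)
    type <- sample.int(6L, 1L, prob = w)
    in0 <- type <= 3L
    pool <- if (in0) alive0 else alive1
    idx <- sample.int(length(pool), 1L)
    lin <- pool[idx]
    if (type %in% c(1L, 4L)) {           # speciation
      if (nxt + 1L > length(parent)) grow(2L * length(parent))
      end[lin] <- a; has_child[lin] <- TRUE
      s <- state[lin]
      for (child in c(nxt, nxt + 1L)) {
        parent[child] <- lin; birth[child] <- a; state[child] <- s
        end[child] <- 0; has_child[child] <- FALSE  # length<- pads with NA
        state_hist[[child]] <- list(age = a, state = s)
      }
      if (in0) {
        alive0 <- c(alive0[-idx], nxt, nxt + 1L)
      } else {
        alive1 <- c(alive1[-idx], nxt, nxt + 1L)
      }
      nxt <- nxt + 2L
      ev_type <- c(ev_type, "speciation")
    } else if (type %in% c(2L, 5L)) {    # extinction
      end[lin] <- a
      if (in0) alive0 <- alive0[-idx] else alive1 <- alive1[-idx]
      ev_type <- c(ev_type, "extinction")
    } else {                             # state transition
      s_new <- if (in0) 1L else 0L
      state[lin] <- s_new
      h <- state_hist[[lin]]
      state_hist[[lin]] <- list(age = c(h$age, a),
                                state = c(h$state, s_new))
      if (in0) {
        alive0 <- alive0[-idx]; alive1 <- c(alive1, lin)
      } else {
        alive1 <- alive1[-idx]; alive0 <- c(alive0, lin)
      }
      ev_type <- c(ev_type, "transition")
    }
    ev_age <- c(ev_age, a); ev_lin <- c(ev_lin, lin)
  }
  end[c(alive0, alive1)] <- 0
  keep <- seq_len(nxt - 1L)
  list(parent = parent[keep], birth = birth[keep], end = end[keep],
       has_child = has_child[keep], state_hist = state_hist[keep],
       events = data.frame(age = ev_age, lineage = ev_lin,
                           type = ev_type, stringsAsFactors = FALSE))
}

#' Subsample tips by per-state sampling fractions
#'
#' Independently retains each tip of state i with probability `f_i` and
#' prunes the tree, emulating the skeletal-tree sampling process that the
#' likelihood's sampling-fraction correction assumes.
#'
#' @param history a `sim_history`, or a `phylo` (then supply `tip_states`).
#' @param f0,f1 retention probabilities in `(0, 1]`.
#' @param seed integer seed.
#' @param tip_states named 0/1 vector when `history` is a bare tree.
#' @return a list with `tree`, `tip_states`, `realized_f` (named length-2
#'   vector of realized per-state retention) and `dropped` labels.
#' @export
apply_sampling <- function(history, f0, f1, seed = NULL, tip_states = NULL) {
  if (any(c(f0, f1) <= 0) || any(c(f0, f1) > 1))
    stop("sampling fractions must be in (0, 1]")
  if (inherits(history, "sim_history")) {
    tree <- history$tree; st <- history$tip_states
  } else {
    tree <- history; st <- tip_states
  }
  st <- st[tree$tip.label]
  with_seed(seed, {
    keep_p <- ifelse(st == 0, f0, f1)
    keep <- runif(length(st)) < keep_p
    if (sum(keep) < 2) stop("fewer than two tips retained after sampling")
    dropped <- tree$tip.label[!keep]
    tr <- if (length(dropped)) ape::drop.tip(tree, dropped) else tree
    realized <- c(
      f0 = if (sum(st == 0)) sum(keep & st == 0) / sum(st == 0) else NA_real_,
      f1 = if (sum(st == 1)) sum(keep & st == 1) / sum(st == 1) else NA_real_)
    list(tree = tr, tip_states = st[tr$tip.label], realized_f = realized,
         dropped = dropped)
  })
}
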