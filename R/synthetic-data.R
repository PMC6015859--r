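## Synthetic palm-like datasets: a large ultrametric radiation carrying a
## rare, phylogenetically clustered fruit-size trait, with per-state
## incomplete sampling, two biogeographic regions and a taggable clade --
## the statistical structure every pipeline stage assumes, generated with
## no external data.

#' Specification of a synthetic dataset
#'
#' Defaults emulate a palm-scale radiation: ~2539 species, crown age 105
#' Ma, megafaunal-fruit prevalence ~12% among measured species, per-state
#' unsampled fractions 32% (small) / 18% (megafaunal), and two regions with
#' measured prevalences ~16% (NW) and ~10% (OW).  The desk profile scales
#' the species count and tree number down for fast tests.
#'
#' @param profile `"desk"` (300 species, 10 trees) or `"full"` (2539
#'   species, 100 trees).
#' @param n_species,n_trees override the profile.
#' @param age crown age (Ma).
#' @param lambda,mu birth-death rates used for the base tree.
#' @param prevalence target state-1 share among measured species.
#' @param unsampled per-state unsampled fractions `c(small, mega)`.
#' @param region_prevalence target measured prevalence per region
#'   (named `NW`, `OW`).
#' @param threshold fruit-length threshold (cm).
#' @param clade_size tip count of the tagged clade.
#' @param q10 megafaunal-to-small transition rate used for the trait
#'   process (sets the clustering scale; q01 is calibrated per region).
#' @param prevalence_tol,region_tol acceptance tolerances on the realized
#'   measured prevalences.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(profile = c("desk", "full"), n_species = NULL,
                           n_trees = NULL, age = 105, lambda = 0.2,
                           mu = 0.19, prevalence = 0.12,
                           unsampled = c(0.32, 0.18),
                           region_prevalence = c(NW = 0.16, OW = 0.10),
                           threshold = 4, clade_size = 98, q10 = 0.1,
                           prevalence_tol = 0.02, region_tol = 0.04) {
  profile <- match.arg(profile)
  n_species <- n_species %||% switch(profile, desk = 300L, full = 2539L)
  n_trees <- n_trees %||% switch(profile, desk = 10L, full = 100L)
  stopifnot(n_species >= 10, prevalence > 0, prevalence < 1,
            all(unsampled >= 0), all(unsampled < 1))
  structure(list(n_species = n_species, n_trees = n_trees, age = age,
                 lambda = lambda, mu = mu, prevalence = prevalence,
                 unsampled = unsampled,
                 region_prevalence = region_prevalence,
                 threshold = threshold, clade_size = clade_size,
                 q10 = q10, prevalence_tol = prevalence_tol,
                 region_tol = region_tol),
            class = "synthetic_spec")
}

## measured prevalence m under per-state sampling (f0, f1) corresponds to
## a true prevalence p = m f0 / (f1 (1 - m) + f0 m)
.true_prevalence <- function(m, f0, f1) m * f0 / (f1 * (1 - m) + f0 * m)

## simulate a binary trait whose 0->1 rate depends on the region painted
## at the child node of each edge (regions are clade-clustered, so the
## per-edge approximation is tight)
.sim_trait_regional <- function(tree, node_region, q10, q01_by_region) {
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  node_state <- integer(ntip + ape::Nnode(tree))
  root <- ntip + 1L
  pr <- q01_by_region[node_region[root]] /
    (q01_by_region[node_region[root]] + q10)
  node_state[root] <- rbinom(1, 1, pr)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    q01 <- q01_by_region[node_region[ch]]
    a <- age[par]; s <- node_state[par]
    repeat {
      rate <- if (s == 0) q01 else q10
      if (rate <= 0) break
      dt <- rexp(1, rate)
      if (a - dt <= age[ch]) break
      a <- a - dt; s <- 1L - s
    }
    node_state[ch] <- s
  }
  setNames(node_state[seq_len(ntip)], tr$tip.label)
}

## lognormal fruit lengths truncated to the correct side of the threshold
.draw_lengths <- function(states, threshold) {
  n <- length(states)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- if (states[i] == 0) rlnorm(1, log(0.45 * threshold), 0.5)
      else rlnorm(1, log(1.6 * threshold), 0.45)
      if ((states[i] == 0 && x < threshold) ||
          (states[i] == 1 && x >= threshold)) break
    }
    out[i] <- x
  }
  out
}

## jitter internal node ages to mimic posterior dating uncertainty;
## topology preserved, parent > child maintained, tips stay at age 0
.jitter_node_ages <- function(tree, sd_frac = 0.02, seed = NULL) {
  with_seed(seed, {
    age <- node_ages(tree)
    ntip <- ape::Ntip(tree)
    tr <- ape::reorder.phylo(tree, "cladewise")
    new_age <- age
    kids <- split(tr$edge[, 2], tr$edge[, 1])
    sdv <- sd_frac * max(age)
    ord <- unique(tr$edge[, 1])  # parents before children in cladewise
    for (nd in ord) {
      ch <- kids[[as.character(nd)]]
      lb <- max(age[ch])         # original child ages guarantee feasibility
      ub <- if (nd == ntip + 1L) age[nd] * 1.1 else new_age[.parent_of(tr, nd)]
      repeat {
        cand <- age[nd] + rnorm(1, 0, sdv)
        if (cand > lb && cand < ub) break
      }
      new_age[nd] <- cand
    }
    tr$edge.length <- new_age[tr$edge[, 1]] - new_age[tr$edge[, 2]]
    validate_tree(tr)
  })
}

.parent_of <- function(tree, node) tree$edge[tree$edge[, 2] == node, 1]

#' Generate a synthetic palm-like dataset
#'
#' Builds a birth-death tree conditioned on the spec's species count and
#' age plus jittered replicates standing in for a posterior tree sample;
#' paints two clade-clustered regions; evolves the binary fruit-size state
#' with region-calibrated transition rates and draws fruit lengths
#' consistent with the threshold; masks tips according to the per-state
#' unsampled fractions; and tags one clade.  Redraws until the realized
#' measured prevalences hit the spec targets within tolerance.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the dataset is reproducible byte-for-byte.
#' @param max_tries redraw budget for the prevalence targets.
#' @return a list: `trees` (`multiPhylo`, first element the base tree),
#'   `traits` (a `trait_dataset` with `state`, `length_cm`, `region`,
#'   `clade`; masked tips have `NA` state and length), `f` realized
#'   per-state sampling fractions, and `truth` (generating parameters and
#'   realized summaries).
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1,
                             max_tries = 50) {
  stopifnot(inherits(spec, "synthetic_spec"))
  f0 <- 1 - spec$unsampled[1]; f1 <- 1 - spec$unsampled[2]
  base <- sim_bd_tree(spec$n_species, spec$age, spec$lambda, spec$mu,
                      seed = seed)
  ntip <- ape::Ntip(base)
  with_seed(seed + 1L, {
    for (try in seq_len(max_tries)) {
      ## clade-clustered regions from a slow symmetric character
      q_reg <- 6 / sum(base$edge.length)
      reg_hist <- sim_mk_trait(base, q_reg, q_reg)
      node_region <- ifelse(reg_hist$node_states == 0, "NW", "OW")
      ## calibrate per-region 0->1 rates to the measured-prevalence targets
      p_true <- vapply(spec$region_prevalence, .true_prevalence, 0,
                       f0 = f0, f1 = f1)
      q01_by_region <- spec$q10 * p_true / (1 - p_true)
      states <- .sim_trait_regional(base, node_region, spec$q10,
                                    q01_by_region)
      region <- setNames(node_region[seq_len(ntip)], base$tip.label)
      ## per-state measurement mask
      miss_p <- ifelse(states == 0, spec$unsampled[1], spec$unsampled[2])
      missing <- runif(ntip) < miss_p
      meas <- !missing
      if (sum(meas) < 10) next
      prev <- mean(states[meas] == 1)
      prev_reg <- vapply(c(NW = "NW", OW = "OW"), function(r) {
        sel <- meas & region == r
        if (!sum(sel)) return(NA_real_)
        mean(states[sel] == 1)
      }, 0)
      ok <- abs(prev - spec$prevalence) <= spec$prevalence_tol &&
        all(!is.na(prev_reg)) &&
        all(abs(prev_reg - spec$region_prevalence) <= spec$region_tol)
      if (ok) break
    }
    if (!ok) stop("prevalence targets not attained in ", max_tries,
                  " redraws; loosen the tolerances or the targets")
    lengths <- .draw_lengths(states, spec$threshold)
    lengths[missing] <- NA
    st_out <- ifelse(missing, NA_integer_, states)
    ## tag the internal clade whose size is closest to the target
    clade_nodes <- (ntip + 2L):(ntip + ape::Nnode(base))
    sizes <- vapply(clade_nodes, function(nd)
      length(.tips_below(base, nd)), 0L)
    best <- clade_nodes[which.min(abs(sizes - spec$clade_size))]
    clade <- rep(NA_character_, ntip)
    clade[.tips_below(base, best)] <- "cladeA"
    traits <- trait_dataset(base$tip.label, st_out, length_cm = lengths,
                            region = region, clade = clade)
    jit <- lapply(seq_len(max(spec$n_trees - 1L, 0L)), function(i)
      .jitter_node_ages(base, seed = NULL))
    trees <- structure(c(list(base), jit), class = "multiPhylo")
    realized_f <- c(f0 = sum(meas & states == 0) / sum(states == 0),
                    f1 = sum(meas & states == 1) / sum(states == 1))
    truth <- list(spec = spec, q01_by_region = q01_by_region,
                  q10 = spec$q10, n_measured = sum(meas),
                  prevalence_measured = prev,
                  region_prevalence_measured = prev_reg,
                  clade_node = best, clade_size = sum(!is.na(clade)),
                  tries = try)
    list(trees = trees, traits = traits, f = realized_f, truth = truth)
  })
}

.tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    tips <- ch[ch <= ntip]
    out <- c(out, tips)
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Deterministic micro-fixtures for unit tests
#'
#' Small hand-checkable instances: a two-tip cherry with the closed-form
#' Mk likelihood, a five-tip Yule-shaped tree with the closed-form
#' birth-death likelihood, and a zero-rate fixture whose likelihood reduces
#' to the root weight alone.  Closed forms are evaluated from their
#' analytic expressions, independent of the pruning code.
#'
#' @return a named list of fixtures; each has `tree`, `states` and, where
#'   applicable, a `closed_form` function of the rate(s).
#' @export
fixture_suite <- function() {
  cherry <- read_newick("(A:1,B:1);")
  yule5 <- read_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  list(
    cherry = list(
      tree = cherry,
      states = c(A = 0L, B = 1L),
      ## equal-root-weight Mk likelihood of tips (0, 1) on unit branches:
      ## L = 1/2 sum_r P_{r0}(1) P_{r1}(1), from the 2x2 matrix exponential
      closed_form = function(q) {
        e <- exp(-2 * q)
        p_same <- (1 + e) / 2; p_diff <- (1 - e) / 2
        log(0.5 * (p_same * p_diff + p_diff * p_same))
      }),
    yule5 = list(
      tree = yule5,
      states = setNames(rep(0L, 5), LETTERS[1:5]),
      ## unconditioned Yule likelihood: (n-1) log(lambda) - lambda * sum(bl)
      closed_form = function(lambda)
        4 * log(lambda) - lambda * sum(yule5$edge.length)),
    zero_rate = list(
      tree = cherry,
      states = c(A = 0L, B = 0L),
      closed_form = function(root_weight) log(root_weight)))
}
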