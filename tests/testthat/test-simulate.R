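test_that("trait simulation respects zero rates and replays from its seed", {
  tr <- sim_bd_tree(20, 10, 0.3, 0, seed = 2)
  h <- sim_mk_trait(tr, 0, 0, root_state = 1, seed = 5)
  expect_true(all(h$tip_states == 1))
  expect_null(h$events)
  ## segments tile each edge exactly
  len <- tapply(h$segments$start_age - h$segments$end_age, h$segments$edge,
                sum)
  tr_post <- ape::reorder.phylo(tr, "cladewise")
  expect_equal(as.vector(len[as.character(seq_len(nrow(tr_post$edge)))]),
               tr_post$edge.length, tolerance = 1e-12)
  ## determinism
  h1 <- sim_mk_trait(tr, 0.3, 0.2, seed = 11)
  h2 <- sim_mk_trait(tr, 0.3, 0.2, seed = 11)
  expect_identical(h1$tip_states, h2$tip_states)
  expect_identical(h1$segments, h2$segments)
  ## tip states equal the last segment state on terminal edges
  term <- h1$segments[h1$segments$child <= 20, ]
  last <- term[!duplicated(term$edge, fromLast = TRUE), ]
  expect_equal(unname(h1$tip_states[tr_post$tip.label[last$child]]),
               last$state)
})

test_that("fast symmetric flipping reaches the half-half stationary mix", {
  tr <- sim_bd_tree(300, 4, 1.2, 0, seed = 13)
  h <- sim_mk_trait(tr, 10, 10, root_state = 0, seed = 17)
  expect_lt(abs(mean(h$tip_states) - 0.5), 0.1)
})

test_that("asymmetric rates reach their stationary frequency on long branches", {
  ## megafaunal->small 0.017, small->megafaunal 0.006: pi_1 = 0.006/0.023
  pooled <- unlist(lapply(1:4, function(i) {
    tr <- sim_bd_tree(150, 700, 0.01, 0, seed = 60 + i)
    sim_mk_trait(tr, 0.006, 0.017, seed = 70 + i)$tip_states
  }))
  expect_lt(abs(mean(pooled) - 0.006 / 0.023), 0.08)
})

test_that("conditioned birth-death trees hit tip count and age exactly", {
  for (s in 1:4) {
    tr <- sim_bd_tree(1774, 105, 0.2, 0.19, seed = s)
    expect_equal(ape::Ntip(tr), 1774)
    expect_equal(tree_height(tr), 105, tolerance = 1e-9)
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  }
  cherry <- sim_bd_tree(2, 7.5, 0.4, 0.2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  expect_equal(tree_height(cherry), 7.5)
})

test_that("conditioned branching times follow the analytic density", {
  ## CDF of an interior speciation age given survival to the crown age:
  ## F(t) = u(t)/u(T), u(t) = (1 - e^{-rt}) / (lambda - mu e^{-rt})
  check_times <- function(lambda, mu, T, n, n_rep, seed0) {
    u <- function(t) (1 - exp(-(lambda - mu) * t)) /
      (lambda - mu * exp(-(lambda - mu) * t))
    ages <- unlist(lapply(seq_len(n_rep), function(s) {
      tr <- sim_bd_tree(n, T, lambda, mu, seed = seed0 + s)
      a <- ape::branching.times(tr)
      a[a < T - 1e-9]
    }))
    ks.test(u(ages) / u(T), "punif")$p.value
  }
  ## Yule case (the closed-form order-statistic density)
  expect_gt(check_times(0.3, 0, 10, 10, 120, 1000), 0.001)
  ## high-turnover case
  expect_gt(check_times(0.4, 0.3, 10, 10, 120, 2000), 0.001)
})

test_that("joint tree+trait simulation matches Yule expectations", {
  p <- time_slice_params(numeric(0), epoch_rates(0.15, 0.15, 0, 0, 0, 0))
  tips <- vapply(1:300, function(s)
    sim_bisse_timeslice(p, 10, root_state = 0, seed = 3000 + s)$n_extant, 0)
  ## two crown lineages, each expecting e^{lambda T} descendants
  expect_lt(abs(mean(tips) - 2 * exp(0.15 * 10)) / (2 * exp(0.15 * 10)),
            0.15)
  ## all rates zero: the crown bifurcation alone survives
  p0 <- time_slice_params(numeric(0), epoch_rates(0, 0, 0, 0, 0, 0))
  h0 <- sim_bisse_timeslice(p0, 5, root_state = 1, seed = 1)
  expect_equal(ape::Ntip(h0$tree), 2)
  expect_equal(tree_height(h0$tree), 5)
  expect_true(all(h0$tip_states == 1))
})

test_that("simulated histories are internally consistent and replayable", {
  p <- time_slice_params(2.6, rbind(
    epoch_rates(0.25, 0.25, 0.05, 0.3, 0.05, 0.05),
    epoch_rates(0.25, 0.25, 0.05, 0.05, 0.05, 0.05)))
  h <- sim_bisse_timeslice(p, 20, min_tips = 20, max_tips = 500, seed = 31)
  h2 <- sim_bisse_timeslice(p, 20, min_tips = 20, max_tips = 500, seed = 31)
  expect_identical(h$tip_states, h2$tip_states)
  expect_identical(write_newick(h$tree), write_newick(h2$tree))
  expect_true(ape::is.ultrametric(h$tree, tol = 1e-6))
  ## event ages lie inside the simulated span and segments tile lineages
  expect_true(all(h$events$age >= 0 & h$events$age <= 20))
  expect_true(all(h$segments$start_age >= h$segments$end_age))
  ## the reconstructed tree's tips all carry states
  expect_setequal(names(h$tip_states), h$tree$tip.label)
})

test_that("a recent extinction shift depresses the shifted state's tips", {
  shift <- time_slice_params(2.6, rbind(
    epoch_rates(0.25, 0.25, 0.02, 0.5, 0.02, 0.02),
    epoch_rates(0.25, 0.25, 0.02, 0.02, 0.02, 0.02)))
  ctrl <- time_slice_params(2.6, rbind(
    epoch_rates(0.25, 0.25, 0.02, 0.02, 0.02, 0.02),
    epoch_rates(0.25, 0.25, 0.02, 0.02, 0.02, 0.02)))
  frac <- function(params, seeds) vapply(seeds, function(s) {
    h <- sim_bisse_timeslice(params, 15, min_tips = 10, max_tips = 2000,
                             seed = s)
    mean(h$tip_states)
  }, 0)
  f_shift <- frac(shift, 5000 + 1:25)
  f_ctrl <- frac(ctrl, 6000 + 1:25)
  expect_lt(mean(f_shift), mean(f_ctrl))
})

test_that("per-state subsampling behaves binomially and reports fractions", {
  tr <- sim_bd_tree(1000, 20, 0.4, 0, seed = 77)
  st <- sim_mk_trait(tr, 5, 5, seed = 78)$tip_states
  ## identity at f = 1
  s1 <- apply_sampling(tr, 1, 1, seed = 1, tip_states = st)
  expect_equal(ape::Ntip(s1$tree), 1000)
  ## half retention
  s2 <- apply_sampling(tr, 0.5, 0.5, seed = 2, tip_states = st)
  expect_lt(abs(ape::Ntip(s2$tree) - 500), 3 * sqrt(1000 * 0.25))
  ## the complements of 32% / 18% missingness
  s3 <- apply_sampling(tr, 0.68, 0.82, seed = 3, tip_states = st)
  n0 <- sum(st == 0); n1 <- sum(st == 1)
  expect_lt(abs(s3$realized_f[["f0"]] - 0.68), 3 * sqrt(0.68 * 0.32 / n0))
  expect_lt(abs(s3$realized_f[["f1"]] - 0.82), 3 * sqrt(0.82 * 0.18 / n1))
  expect_true(ape::is.ultrametric(s3$tree, tol = 1e-6))
  expect_error(apply_sampling(tr, 0, 1, seed = 1, tip_states = st),
               "\\(0, 1]")
})

test_that("histories stay consistent past the lineage-array growth threshold", {
  ## large pure-birth crown forces the internal record arrays to reallocate
  p <- time_slice_params(numeric(0),
                         epoch_rates(0.25, 0.25, 0, 0, 0.01, 0.01))
  h <- sim_bisse_timeslice(p, 33, root_state = 1, min_tips = 4500,
                           max_tips = 30000, seed = 3)
  expect_gt(h$n_extant, 4096)
  expect_false(anyNA(h$tip_states))
  expect_equal(ape::Ntip(h$tree), h$n_extant)
  expect_equal(tree_height(h$tree), 33, tolerance = 1e-9)
})
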