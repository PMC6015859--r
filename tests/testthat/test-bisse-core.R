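const_params <- function(l0, l1 = l0, m0 = 0, m1 = m0, q01 = 0, q10 = q01)
  time_slice_params(numeric(0), epoch_rates(l0, l1, m0, m1, q01, q10))

test_that("ode_rhs matches direct substitution and symmetry", {
  r <- epoch_rates(1, 0, 0.5, 0, 0.1, 0)
  d <- ode_rhs(0, c(0, 0, 1, 0), r)
  expect_equal(d[3], -1.6)   # -(lambda0 + mu0 + q01) * D0
  expect_equal(d[1], 0.5)    # mu0
  expect_equal(ode_rhs(0, c(0.3, 0.2, 1, 2), epoch_rates(0, 0, 0, 0, 0, 0)),
               rep(0, 4))
  ## symmetric rates + symmetric state => symmetric derivatives
  rs <- epoch_rates(0.4, 0.4, 0.2, 0.2, 0.3, 0.3)
  ds <- ode_rhs(0, c(0.1, 0.1, 0.7, 0.7), rs)
  expect_equal(ds[1], ds[2])
  expect_equal(ds[3], ds[4])
  expect_error(ode_rhs(0, c(NaN, 0, 1, 0), rs), "NaN")
})

test_that("branch integration reproduces closed forms", {
  ## pure death: D(s) = D0 e^{-mu s}, E(s) = 1 - (1 - E0) e^{-mu s}
  p <- const_params(0, 0, 0.5, 0.5)
  r <- integrate_branch(c(0, 0), c(1, 1), 0, 2, p)
  expect_equal(r$D * exp(r$log_scale), rep(exp(-1), 2), tolerance = 1e-7)
  expect_equal(r$E, rep(1 - exp(-1), 2), tolerance = 1e-7)

  ## pure Markov: 2-state matrix exponential
  p2 <- const_params(0, 0, 0, 0, 0.5, 0.5)
  r2 <- integrate_branch(c(0, 0), c(1, 0), 0, 1, p2)
  expect_equal(r2$D * exp(r2$log_scale),
               c((1 + exp(-1)) / 2, (1 - exp(-1)) / 2), tolerance = 1e-7)

  ## with mu = q = 0 and E = 0: dD = -lambda D
  p3 <- const_params(0.3)
  r3 <- integrate_branch(c(0, 0), c(1, 1), 0, 2, p3)
  expect_equal(r3$D * exp(r3$log_scale), rep(exp(-0.6), 2), tolerance = 1e-7)

  expect_error(integrate_branch(c(2, 0), c(1, 1), 0, 1, p3), "E must")
  expect_error(integrate_branch(c(0, 0), c(-1, 1), 0, 1, p3), "non-negative")
})

test_that("identical epochs on both sides of a breakpoint are inert", {
  r <- epoch_rates(0.3, 0.5, 0.1, 0.2, 0.05, 0.15)
  p1 <- time_slice_params(numeric(0), r)
  p2 <- time_slice_params(1.3, rbind(r, r))
  y1 <- integrate_branch(c(0.1, 0.2), c(1, 0.5), 0.5, 3, p1)
  y2 <- integrate_branch(c(0.1, 0.2), c(1, 0.5), 0.5, 3, p2)
  expect_equal(y1$D, y2$D, tolerance = 1e-8)
  expect_equal(y1$E, y2$E, tolerance = 1e-8)
  expect_equal(y1$log_scale, y2$log_scale, tolerance = 1e-8)

  inst <- random_instance(25, seed = 31)
  pp1 <- const_params(0.3, 0.4, 0.1, 0.05, 0.2, 0.1)
  for (bk in c(0.7, 2.6, 5)) {
    pp2 <- time_slice_params(bk, rbind(pp1$epochs[1, ], pp1$epochs[1, ]))
    expect_equal(tree_loglik(inst$tree, inst$states, pp2),
                 tree_loglik(inst$tree, inst$states, pp1), tolerance = 1e-8)
  }
})

test_that("tree likelihood is invariant to child order and tip order", {
  inst <- random_instance(20, seed = 5)
  p <- const_params(0.3, 0.4, 0.1, 0.05, 0.2, 0.1)
  l0 <- tree_loglik(inst$tree, inst$states, p)
  rot <- ape::rotateConstr(inst$tree, sample(inst$tree$tip.label))
  expect_equal(tree_loglik(rot, inst$states, p), l0, tolerance = 1e-10)
  ## permuting the trait vector (names carry the mapping)
  perm <- sample(length(inst$states))
  expect_equal(tree_loglik(inst$tree, inst$states[perm], p), l0,
               tolerance = 1e-12)
})

test_that("equal-rates BiSSE factorizes into birth-death times Mk", {
  set.seed(2024)
  for (i in 1:12) {
    n <- sample(20:100, 1)
    inst <- random_instance(n, seed = i)
    lam <- runif(1, 0.2, 0.6); mu <- runif(1, 0, 0.15)
    q01 <- runif(1, 0.05, 0.5); q10 <- runif(1, 0.05, 0.5)
    p <- const_params(lam, lam, mu, mu, q01, q10)
    lhs <- tree_loglik(inst$tree, inst$states, p)
    rhs <- bd_loglik(inst$tree, lam, mu) +
      mk_loglik(inst$tree, inst$states, q01, q10)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("adaptive solver agrees with the fixed-step RK4 oracle", {
  for (i in 1:8) {
    inst <- random_instance(10, seed = 100 + i)
    p <- time_slice_params(2.6, rbind(
      epoch_rates(runif(1, .2, .5), runif(1, .2, .5), runif(1, 0, .2),
                  runif(1, 0, .2), runif(1, .02, .3), runif(1, .02, .3)),
      epoch_rates(runif(1, .2, .5), runif(1, .2, .5), runif(1, 0, .2),
                  runif(1, 0, .2), runif(1, .02, .3), runif(1, .02, .3))))
    expect_equal(tree_loglik(inst$tree, inst$states, p),
                 rk4_loglik(inst$tree, inst$states, p), tolerance = 1e-5)
  }
})

test_that("sampling fractions enter through the tip conditions", {
  inst <- random_instance(15, seed = 77)
  p <- const_params(0.3, 0.4, 0.1, 0.05, 0.2, 0.1)
  ## f = 1 equals no correction
  expect_identical(tree_loglik(inst$tree, inst$states, p, f = c(1, 1)),
                   tree_loglik(inst$tree, inst$states, p))
  ## f < 1 changes the likelihood and matches the RK4 oracle
  f <- c(0.68, 0.82)
  l1 <- tree_loglik(inst$tree, inst$states, p, f = f)
  expect_false(isTRUE(all.equal(l1, tree_loglik(inst$tree, inst$states, p))))
  expect_equal(l1, rk4_loglik(inst$tree, inst$states, p, f = f),
               tolerance = 1e-5)
  expect_error(tree_loglik(inst$tree, inst$states, p, f = c(0, 1)), "\\(0, 1]")
})

test_that("E stays within [0, 1] and grows along integration when mu > 0", {
  p <- const_params(0.3, 0.4, 0.15, 0.2, 0.1, 0.1)
  Es <- t(sapply(seq(0.5, 20, by = 0.5), function(a)
    integrate_branch(c(0, 0), c(1, 1), 0, a, p)$E))
  expect_true(all(Es >= 0 & Es <= 1))
  expect_true(all(diff(Es[, 1]) > -1e-10))
  expect_true(all(diff(Es[, 2]) > -1e-10))
})

test_that("birth-death closed form matches Yule and the one-state reduction", {
  tr <- sim_bd_tree(12, 8, 0.4, 0.1, seed = 55)
  n <- ape::Ntip(tr)
  ## Yule, unconditioned: (n-1) log lambda - lambda sum(branch lengths)
  expect_equal(bd_loglik(tr, 0.4, 0, 1, condition_on_survival = FALSE),
               (n - 1) * log(0.4) - 0.4 * sum(tr$edge.length),
               tolerance = 1e-10)
  ## one effective state: all tips 0, q = 0, mirrored rates
  st <- setNames(rep(0L, n), tr$tip.label)
  p <- const_params(0.4, 0.4, 0.12, 0.12, 0, 0)
  expect_equal(tree_loglik(tr, st, p, cond = lik_condition("prior",
                 root_prior = c(1, 0))),
               bd_loglik(tr, 0.4, 0.12), tolerance = 1e-6)
  ## lambda == mu limit is finite and continuous
  l_at <- bd_loglik(tr, 0.3, 0.3)
  l_near <- bd_loglik(tr, 0.3, 0.3 - 1e-9)
  expect_true(is.finite(l_at))
  expect_equal(l_at, l_near, tolerance = 1e-5)
  ## with sampling: matches equal-rates reduction with f0 = f1 = rho
  expect_equal(tree_loglik(tr, st, p, f = c(0.7, 0.7),
                           cond = lik_condition("prior", root_prior = c(1, 0))),
               bd_loglik(tr, 0.4, 0.12, rho = 0.7), tolerance = 1e-6)
})

test_that("Mk pruning matches the matrix-exponential oracle", {
  ## 2-tip closed form, equal root weights
  fx <- fixture_suite()
  cherry <- fx$cherry
  for (q in c(0.1, 0.5, 2)) {
    expect_equal(mk_loglik(cherry$tree, cherry$states, q, q,
                           cond = lik_condition("equal")),
                 cherry$closed_form(q), tolerance = 1e-12)
  }
  ## asymmetric rates on random trees
  for (i in 1:6) {
    inst <- random_instance(12, seed = 300 + i)
    q01 <- runif(1, 0.05, 1); q10 <- runif(1, 0.05, 1)
    expect_equal(mk_loglik(inst$tree, inst$states, q01, q10,
                           cond = lik_condition("equal")),
                 mk_loglik_expm(inst$tree, inst$states, q01, q10),
                 tolerance = 1e-9)
  }
  ## zero rates, uniform state: log of that state's root weight
  zr <- fx$zero_rate
  expect_equal(mk_loglik(zr$tree, zr$states, 0, 0,
                         cond = lik_condition("equal")),
               zr$closed_form(0.5))
  expect_error(mk_loglik(cherry$tree, cherry$states, 0, 0), "zero transition")
  ## long branches: tip states go independent, logL -> sum log pi(state)
  long <- read_newick("(A:500,B:500);")
  st <- c(A = 0L, B = 1L)
  q01 <- 0.3; q10 <- 0.6
  pi1 <- q01 / (q01 + q10)
  expect_equal(mk_loglik(long, st, q01, q10, cond = lik_condition("equal")),
               log(1 - pi1) + log(pi1), tolerance = 1e-4)
})

test_that("branch integration agrees with a general-purpose ODE solver", {
  skip_if_not_installed("deSolve")
  r <- epoch_rates(0.35, 0.2, 0.12, 0.05, 0.2, 0.08)
  p <- time_slice_params(numeric(0), r)
  y0 <- c(0.1, 0.3, 1, 0.4)
  ours <- integrate_branch(y0[1:2], y0[3:4], 0.5, 6, p)
  ref <- deSolve::lsoda(
    y0, c(0.5, 6),
    function(t, y, parms) list(ode_rhs(t, y, r)),
    parms = NULL, rtol = 1e-10, atol = 1e-12)[2, -1]
  expect_equal(ours$E, unname(ref[1:2]), tolerance = 1e-7)
  expect_equal(ours$D * exp(ours$log_scale), unname(ref[3:4]),
               tolerance = 1e-7)
})
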