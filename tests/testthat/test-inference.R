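## a Yule-only constraint: one shared speciation rate, everything else
## fixed at zero; with a (1, 0) root prior and no survival conditioning the
## posterior under an exponential prior is Gamma(n, S + prior_rate)
yule_spec <- function() {
  lam_slots <- c("lambda0.recent", "lambda1.recent", "lambda0.old",
                 "lambda1.old")
  other <- setdiff(epochsse:::SLOT_NAMES, lam_slots)
  constraint_spec("yule", setNames(rep("lambda", 4), lam_slots),
                  fixed = setNames(rep(0, length(other)), other))
}

yule_cond <- lik_condition("prior", root_prior = c(1, 0),
                           condition_on_survival = FALSE)

test_that("MLE fitting finds the optimum and is seed-deterministic", {
  tr <- sim_bd_tree(40, 12, 0.35, 0.05, seed = 8)
  st <- setNames(rep(0L, 40), tr$tip.label)
  ## Yule MLE has the closed form (n - 1) / S
  fit <- fit_mle(tr, st, yule_spec(), 2.6, cond = yule_cond, starts = 3,
                 seed = 1)
  expect_equal(unname(fit$par[["lambda"]]),
               (40 - 1) / sum(tr$edge.length), tolerance = 1e-4)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logL)
  ## the reported optimum reproduces under re-evaluation
  p <- spec_to_params(fit$spec, fit$par, 2.6)
  expect_equal(tree_loglik(tr, st, p, cond = yule_cond), fit$logL,
               tolerance = 1e-9)
  ## identical seed => identical result; different seed => same optimum
  fit2 <- fit_mle(tr, st, yule_spec(), 2.6, cond = yule_cond, starts = 3,
                  seed = 1)
  expect_identical(fit$par, fit2$par)
  fit3 <- fit_mle(tr, st, yule_spec(), 2.6, cond = yule_cond, starts = 3,
                  seed = 99)
  expect_equal(fit3$logL, fit$logL, tolerance = 1e-5)
})

test_that("constant-rate BiSSE parameters are recoverable from moderate trees", {
  ## two replicates at a few hundred tips: pooled speciation estimates land
  ## near the generating value, and the nested-model logL ordering holds
  truth <- time_slice_params(numeric(0),
                             epoch_rates(0.2, 0.2, 0.05, 0.05, 0.05, 0.05))
  lam_hat <- q_hat <- numeric(2)
  for (i in 1:2) {
    h <- sim_bisse_timeslice(truth, 35, min_tips = 200, max_tips = 600,
                             seed = 400 + i)
    sp_free <- spec_from_patterns("s", "c", "c")   # k = 4
    sp_base <- spec_from_patterns("c", "c", "c")   # k = 3, the truth
    f_free <- fit_mle(h$tree, h$tip_states, sp_free, 2.6, starts = 2,
                      seed = i)
    f_base <- fit_mle(h$tree, h$tip_states, sp_base, 2.6, starts = 2,
                      seed = i)
    expect_gte(f_free$logL, f_base$logL - 1e-4)
    lam_hat[i] <- f_base$par[["lambda"]]
    q_hat[i] <- f_base$par[["q"]]
  }
  expect_lt(abs(mean(lam_hat) - 0.2) / 0.2, 0.3)
  expect_lt(abs(mean(q_hat) - 0.05) / 0.05, 0.6)
})

test_that("slice sampler recovers the analytic Yule posterior", {
  tr <- sim_bd_tree(50, 10, 0.5, 0, seed = 21)
  st <- setNames(rep(0L, 50), tr$tip.label)
  S <- sum(tr$edge.length)
  prior_rate <- 1
  ch <- run_mcmc(tr, st, yule_spec(), 2.6, cond = yule_cond,
                 generations = 10000, seed = 42, prior_rate = prior_rate,
                 init = c(lambda = 49 / S), warmup = 300)
  expect_equal(nrow(ch$samples), 10000)
  expect_true(all(ch$samples >= 0))
  ## posterior is Gamma(n, S + prior_rate): n - 1 tree factors of lambda
  ## plus one from the root-node combination
  shape <- 50; rate <- S + prior_rate
  got <- quantile(ch$samples[, "lambda"], c(0.05, 0.5, 0.95), names = FALSE)
  want <- qgamma(c(0.05, 0.5, 0.95), shape, rate)
  expect_equal(got, want, tolerance = 0.02 / mean(want))
  ## seeded determinism, bit for bit
  ch2 <- run_mcmc(tr, st, yule_spec(), 2.6, cond = yule_cond,
                  generations = 200, seed = 7, prior_rate = 1,
                  init = c(lambda = 0.5), warmup = 50)
  ch3 <- run_mcmc(tr, st, yule_spec(), 2.6, cond = yule_cond,
                  generations = 200, seed = 7, prior_rate = 1,
                  init = c(lambda = 0.5), warmup = 50)
  expect_identical(ch2$samples, ch3$samples)
})

test_that("a concentrated prior dominates a weak likelihood", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  st <- setNames(rep(0L, 3), c("A", "B", "C"))
  ch <- run_mcmc(tr, st, yule_spec(), 0.5, cond = yule_cond,
                 generations = 2000, seed = 3, prior_rate = 1e4,
                 init = c(lambda = 0.5), warmup = 200)
  ## MLE would be (n-1)/S = 0.5; the prior (mean 1e-4) pulls the posterior
  ## three orders of magnitude down
  expect_lt(median(ch$samples[, "lambda"]), 1e-3)
})

test_that("posterior summaries pool, derive and stay monotone", {
  sp <- spec_from_patterns("c", "s1", "c")
  ids <- free_params(sp)
  mk_chain <- function(mat) structure(
    list(samples = mat, logL = rep(0, nrow(mat)), spec = sp,
         breakpoint = 2.6), class = "mcmc_chain")
  const <- matrix(rep(c(0.3, 0.02, 0.1, 0.2, 0.01), each = 100), 100, 5,
                  dimnames = list(NULL, ids))
  s1 <- summarize_posterior(list(mk_chain(const)), burn_in = 0.1)
  ## every quantile of a constant chain equals the constant
  lam_row <- s1[s1$rate == "lambda0" & s1$epoch == "recent", ]
  expect_equal(unname(unlist(lam_row[paste0("q", c("05", "25", "50", "75",
                                                   "95"))])),
               rep(0.3, 5))
  ## derived net diversification = lambda - mu
  net_row <- s1[s1$rate == "net1" & s1$epoch == "recent", ]
  mu1r <- unname(const[1, "mu1.r"])
  expect_equal(net_row$q50, 0.3 - mu1r)
  ## pooling two identical chains equals one chain's summary
  s2 <- summarize_posterior(list(mk_chain(const), mk_chain(const)),
                            burn_in = 0.1)
  expect_equal(s1[, -(1:2)], s2[, -(1:2)])
  ## quantile monotonicity on a random chain
  set.seed(5)
  rnd <- matrix(rexp(500 * 5), 500, 5, dimnames = list(NULL, ids))
  s3 <- summarize_posterior(list(mk_chain(rnd)))
  qm <- as.matrix(s3[, paste0("q", c("05", "25", "50", "75", "95"))])
  expect_true(all(t(apply(qm, 1, diff)) >= 0))
  expect_error(summarize_posterior(list(), 0.1), "at least one")
})
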