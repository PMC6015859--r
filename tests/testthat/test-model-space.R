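test_that("the canonical model set has 43 uniquely named members", {
  m <- enumerate_models()
  expect_length(m, 43)
  expect_false(anyDuplicated(names(m)) > 0)
  ks <- vapply(m, function(s) s$k, 0)
  expect_equal(min(ks), 3)   # all-shared constant model
  expect_equal(max(ks), 12)  # fully free two-epoch model
  expect_equal(spec_from_patterns("st", "st", "st")$k, 12)
  expect_equal(spec_from_patterns("c", "c", "c")$k, 3)
  ## deterministic ordering across calls
  expect_identical(names(enumerate_models()), names(m))
})

test_that("constraint specs expand to per-epoch rate matrices", {
  sp <- spec_from_patterns("c", "s1", "t")
  par <- setNames(c(0.2, 0.02, 0.3, 0.05, 0.01, 0.02),
                  free_params(sp))
  p <- spec_to_params(sp, par, 2.6)
  expect_s3_class(p, "timeslice_params")
  expect_equal(p$breakpoints, 2.6)
  ## lambda shared everywhere
  expect_equal(unique(as.vector(p$epochs[, c("lambda0", "lambda1")])),
               par[["lambda"]])
  ## mu0 constant, mu1 shifts
  expect_equal(p$epochs[1, "mu0"], p$epochs[2, "mu0"])
  expect_false(p$epochs[1, "mu1"] == p$epochs[2, "mu1"])
  ## q time-dependent but state-shared
  expect_equal(unname(p$epochs[1, "q01"]), unname(p$epochs[1, "q10"]))
  expect_false(p$epochs[1, "q01"] == p$epochs[2, "q01"])
})

test_that("AIC and likelihood-ratio tests follow their definitions", {
  expect_equal(aic(-100, 6), 212)
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(-50, 7) - aic(-50, 6), 2)
  expect_error(aic(-10, 0), "k must")

  fit_stub <- function(name, patterns, logL) {
    sp <- do.call(spec_from_patterns, as.list(patterns))
    structure(list(spec = sp, logL = logL, k = sp$k,
                   AIC = aic(logL, sp$k), converged = TRUE),
              class = "fit_result")
  }
  nested <- fit_stub("n", c("c", "c", "c"), -101.9205)
  full <- fit_stub("f", c("s", "c", "c"), -100)
  out <- lrt(nested, full)
  expect_equal(out$df, 1)
  expect_equal(out$statistic, 3.841, tolerance = 1e-4)
  expect_equal(out$p, pchisq(3.841, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(out$p, 0.05, tolerance = 1e-3)
  ## zero statistic
  expect_equal(lrt(fit_stub("n", c("c", "c", "c"), -100), full)$p, 1)
  ## df = 2 oracle
  n2 <- fit_stub("n", c("c", "c", "c"), -105.3)
  f2 <- fit_stub("f", c("s", "s", "c"), -100)
  expect_equal(lrt(n2, f2)$df, 2)
  expect_equal(lrt(n2, f2)$p, pchisq(10.6, 2, lower.tail = FALSE),
               tolerance = 1e-6)
  ## non-nested pair errors
  a <- fit_stub("a", c("s", "c", "c"), -100)
  b <- fit_stub("b", c("c", "s", "c"), -100)
  expect_error(lrt(a, b), "not nested")
})

test_that("nesting is a partial order with the full model at the top", {
  m <- enumerate_models()
  full <- m[["L:st_M:st_Q:st"]]
  for (sp in m) expect_true(is_nested(sp, full))
  base <- m[["L:c_M:c_Q:c"]]
  for (sp in m) expect_true(is_nested(base, sp))
  ## antisymmetry on a sample of pairs
  nm <- names(m)
  set.seed(1)
  for (i in 1:40) {
    a <- m[[sample(nm, 1)]]; b <- m[[sample(nm, 1)]]
    if (a$name != b$name && is_nested(a, b) && is_nested(b, a))
      fail("distinct mutually nested specs")
  }
  ## transitivity: c < s-pattern < st-pattern within one family
  expect_true(is_nested(m[["L:c_M:c_Q:c"]], m[["L:s_M:c_Q:c"]]))
  expect_true(is_nested(m[["L:s_M:c_Q:c"]], m[["L:st_M:c_Q:c"]]))
  expect_true(is_nested(m[["L:c_M:c_Q:c"]], m[["L:st_M:c_Q:c"]]))
  ## time-shared and state-shared patterns are not nested in each other
  expect_false(is_nested(m[["L:s_M:c_Q:c"]], m[["L:t_M:c_Q:c"]]))
  expect_false(is_nested(m[["L:t_M:c_Q:c"]], m[["L:s_M:c_Q:c"]]))
})

test_that("delta-AIC selection prefers the sparsest adequate model", {
  stub <- function(patterns, logL) {
    sp <- do.call(spec_from_patterns, as.list(patterns))
    structure(list(spec = sp, logL = logL, k = sp$k,
                   AIC = aic(logL, sp$k), converged = TRUE),
              class = "fit_result")
  }
  ## B within 2 AIC of A but sparser -> B wins
  A <- stub(c("st", "c", "c"), -44)       # k = 6, AIC = 100
  B <- stub(c("s", "c", "c"), -46.75)     # k = 5, AIC = 101.5
  expect_equal(stepwise_select(list(A, B))$spec$name, B$spec$name)
  ## B outside the window -> A wins
  B2 <- stub(c("s", "c", "c"), -47.5)     # AIC = 103
  expect_equal(stepwise_select(list(A, B2))$spec$name, A$spec$name)
  ## equal AIC and k -> lexicographically first name
  C1 <- stub(c("c", "s", "c"), -45)
  C2 <- stub(c("c", "c", "s"), -45)
  sel <- stepwise_select(list(C2, C1))
  expect_equal(sel$spec$name, sort(c(C1$spec$name, C2$spec$name))[1])
  ## report lists all candidates
  rep <- attr(stepwise_select(list(A, B)), "report")
  expect_equal(nrow(rep), 2)
  expect_true(all(c("name", "k", "AIC", "dAIC", "selected") %in% names(rep)))
  expect_error(stepwise_select(list()), "no converged")
})
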