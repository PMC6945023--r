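test_that("breakpoint models expand to per-level demographies", {
  m <- breakpoint_model(10, 5, c(1e4, 1e3))
  d <- expand_model(m)
  expect_equal(d$N, ifelse(2:10 > 5, 1e4, 1e3))
  m2 <- breakpoint_model(6, c(3, 5), c(10, 20, 30))
  expect_equal(expand_model(m2)$N, c(30, 30, 20, 20, 10))   # levels 2..6
  expect_error(breakpoint_model(6, 6, c(1, 2)), "levels in 2..n-1")
  expect_error(breakpoint_model(6, 3, c(1, 2, 3)), "one size per group")
})

test_that("composite likelihood has zero gradient at a saturated model", {
  # counts constructed to equal the model's expectations exactly
  truth <- breakpoint_model(8, 4, c(2e3, 8e3))
  u <- 1e-8; L <- 1e7
  mu <- expected_sfs(expand_model(truth), u, L)$counts
  x <- sfs(round(mu), 8, L)
  x$counts <- mu                      # exact (non-integer) saturation
  base <- composite_log_likelihood(x, truth, u)
  h <- 1e-3
  for (g in 1:2) {
    sz <- truth$group_sizes
    up <- sz; up[g] <- up[g] + h
    dn <- sz; dn[g] <- dn[g] - h
    deriv <- (composite_log_likelihood(
                x, breakpoint_model(8, 4, up), u) -
              composite_log_likelihood(
                x, breakpoint_model(8, 4, dn), u)) / (2 * h)
    expect_lt(abs(deriv), 1e-6 * abs(base))
  }
})

test_that("likelihood depends on u and N only through their product", {
  x <- sfs(c(60, 30, 20), 4, 1e6)
  m1 <- breakpoint_model(4, integer(), 2000)
  m2 <- breakpoint_model(4, integer(), 1000)
  expect_equal(composite_log_likelihood(x, m1, 1e-8),
               composite_log_likelihood(x, m2, 2e-8))
})

test_that("excluded classes leave the likelihood invariant to their counts", {
  u <- 1e-8
  m <- breakpoint_model(5, integer(), 1500)
  x1 <- sfs(c(10, 20, 9, 4), 5, 1e6, excluded = 1L)
  x2 <- sfs(c(9999, 20, 9, 4), 5, 1e6, excluded = 1L)
  expect_equal(composite_log_likelihood(x1, m, u),
               composite_log_likelihood(x2, m, u))
  f1 <- fit_fixed_breakpoints(x1, 3, u)
  f2 <- fit_fixed_breakpoints(x2, 3, u)
  expect_equal(f1$model$group_sizes, f2$model$group_sizes)
})

test_that("the zero-breakpoint fit is Watterson's estimator", {
  # n = 4, S = 110, u = 1e-8, L = 1e6, a = 11/6 -> 1500
  x <- sfs(c(60, 30, 20), 4, 1e6)
  f <- fit_fixed_breakpoints(x, integer(), 1e-8)
  expect_true(f$converged)
  expect_equal(f$model$group_sizes, 1500, tolerance = 1e-8)
  # arbitrary spectra
  set.seed(61)
  for (i in 1:5) {
    n <- sample(3:40, 1)
    g <- rpois(n - 1, 50 / seq_len(n - 1))
    L <- 1e6
    x <- sfs(g, n, L)
    f <- fit_fixed_breakpoints(x, integer(), 1e-8)
    expect_equal(f$model$group_sizes,
                 sum(g) / (4 * 1e-8 * L * sum(1 / seq_len(n - 1))),
                 tolerance = 1e-8)
  }
})

test_that("noiseless spectra invert to their generating sizes", {
  u <- 1e-8; L <- 1e7
  # one breakpoint
  t1 <- breakpoint_model(10, 5, c(1e4, 1e3))
  x1 <- expectation_sfs(expand_model(t1), u, L)
  f1 <- fit_fixed_breakpoints(x1, 5, u)
  expect_true(f1$converged)
  expect_equal(f1$model$group_sizes, c(1e4, 1e3), tolerance = 1e-6)
  # two breakpoints, folded
  t2 <- breakpoint_model(12, c(8, 4), c(2e4, 2e3, 1e4))
  mu <- expected_sfs(expand_model(t2), u, L, folded = TRUE)$counts
  x2 <- sfs(mu, 12, L, folded = TRUE)
  f2 <- fit_fixed_breakpoints(x2, c(8, 4), u)
  expect_true(f2$converged)
  expect_equal(f2$model$group_sizes, c(2e4, 2e3, 1e4), tolerance = 1e-6)
  # a zero count in some class is handled (Poisson term -mu only)
  g <- round(expected_sfs(expand_model(t1), u, 1e5)$counts)
  g[9] <- 0
  f3 <- fit_fixed_breakpoints(sfs(g, 10, 1e5), 5, u)
  expect_true(f3$converged)
  expect_true(all(is.finite(f3$model$group_sizes)))
})

test_that("Newton optimum matches a brute-force grid search", {
  set.seed(71)
  u <- 1e-8; L <- 1e6
  for (i in 1:5) {
    n <- sample(5:8, 1)
    nbp <- sample(0:2, 1)
    bps <- sort(sample(2:(n - 1), nbp), decreasing = TRUE)
    truth <- breakpoint_model(
      n, bps, exp(runif(nbp + 1, log(1e3), log(5e4))))
    x <- expectation_sfs(expand_model(truth), u, L)
    f <- fit_fixed_breakpoints(x, bps, u)
    g <- grid_search_fit(x, bps, u, lower = 100, upper = 5e5)
    expect_true(f$converged)
    expect_gte(f$log_likelihood, g$ll - 1e-6 * abs(g$ll))
    expect_equal(f$model$group_sizes, g$sizes, tolerance = 5e-3)
  }
})

test_that("stepwise search stops immediately on constant-size data", {
  x <- expectation_sfs(constant_demography(12, 4000), 1e-8, 1e7)
  f <- stepwise_fit(x, 1e-8)
  expect_equal(length(f$model$breakpoints), 0L)
  expect_equal(f$model$group_sizes, 4000, tolerance = 1e-6)
  expect_equal(nrow(f$trace), 1L)
})

test_that("stepwise search recovers a one-breakpoint truth, greedy and
           exhaustive modes agreeing", {
  u <- 1e-8; L <- 1e7
  truth <- breakpoint_model(10, 6, c(1.2e4, 1.5e3))
  x <- expectation_sfs(expand_model(truth), u, L)
  fg <- stepwise_fit(x, u, mode = "greedy")
  fe <- stepwise_fit(x, u, mode = "exhaustive", max_breakpoints = 2)
  expect_equal(fg$model$breakpoints, 6L)
  expect_equal(fe$model$breakpoints, fg$model$breakpoints)
  expect_equal(fg$model$group_sizes, fe$model$group_sizes,
               tolerance = 1e-6)
  expect_equal(fg$model$group_sizes, c(1.2e4, 1.5e3), tolerance = 1e-4)
  # each accepted step improved the likelihood by at least the threshold
  expect_true(all(diff(fg$trace$log_likelihood) >= 2))
})

test_that("step plots start at zero with the tip-group size and increase", {
  f0 <- fit_fixed_breakpoints(sfs(c(60, 30, 20), 4, 1e6), integer(), 1e-8)
  s0 <- history_to_steps(f0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$start_generations, 0)
  expect_equal(s0$Ne, 1500, tolerance = 1e-8)

  m <- breakpoint_model(10, 5, c(1e4, 1e3))
  x <- expectation_sfs(expand_model(m), 1e-8, 1e7)
  f <- fit_fixed_breakpoints(x, 5, 1e-8)
  s <- history_to_steps(f)
  expect_equal(nrow(s), 2L)
  expect_equal(s$start_generations[1], 0)
  # second step starts at sum_{j=6}^{10} 4 N_j / (j (j-1)) of the fit
  js <- 6:10
  expect_equal(s$start_generations[2],
               sum(4 * f$demography$N[js - 1] / (js * (js - 1))))
  expect_true(all(diff(s$start_generations) > 0))
})

test_that("non-convergence is reported, never masked", {
  x <- sfs(c(100, 5, 20), 4, 1e6)
  f <- fit_fixed_breakpoints(x, 2, 1e-8, max_iter = 1L)
  expect_false(f$converged)
})
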