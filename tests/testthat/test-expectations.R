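test_that("interval times and level start times follow the coalescent", {
  expect_equal(interval_time(2, 1000), 2000)
  expect_equal(interval_time(10, 500), 2000 / 90)
  expect_equal(interval_time(2, 0), 0)
  expect_error(interval_time(1, 100), ">= 2")

  # n = 3, constant 1000: tau_3 = 0, tau_2 = 4*1000/6
  tau <- level_start_times(constant_demography(3, 1000))
  expect_equal(unname(tau), c(0, 4000 / 6))

  expect_equal(unname(level_start_times(constant_demography(2, 500))), 0)

  # telescoping: constant N, tau_2 = sum 4N/(j(j-1)) = 4N (1 - 1/n) - 4N/1...
  # checked against brute-force summation
  for (n in c(5, 17, 60)) {
    tau <- level_start_times(constant_demography(n, 1234))
    brute <- sum(4 * 1234 / ((3:n) * ((3:n) - 1)))
    expect_equal(unname(tau[as.character(2)]), brute)
    expect_true(all(diff(unname(tau)) >= 0))   # non-decreasing into the past
  }
})

test_that("level weights are normalised and numerically stable", {
  expect_equal(level_weight(4, 1, 2), 1 / 3)
  # brute-force binomial sum equals the closed normalisation
  for (n in c(5, 12, 40)) {
    for (r in seq_len(n - 1)) {
      ks <- 2:(n - r + 1)
      expect_equal(sum(choose(n - ks, r - 1)) / choose(n - 1, r), 1,
                   tolerance = 1e-12)
      expect_equal(sum(level_weight(n, r, ks)), 1, tolerance = 1e-12)
    }
  }
  # log-space evaluation survives binomials that overflow naively
  w <- level_weight(200, 100, 3)
  expect_true(is.finite(w) && w >= 0)
  expect_error(level_weight(10, 10, 2), "out of range")
  expect_error(level_weight(10, 3, 9), "out of range")
})

test_that("expected SFS reduces to theta L / r under constant size", {
  e <- expected_sfs(constant_demography(4, 1000), 1e-8, 1e6)
  expect_equal(e$counts, c(40, 20, 40 / 3), tolerance = 1e-12)
  # single-branch case
  expect_equal(expected_sfs(constant_demography(2, 777), 1e-8, 1e6)$counts,
               4 * 777 * 1e-8 * 1e6)
})

test_that("expected SFS matches the hand-evaluated two-epoch example and
           is linear in the level sizes", {
  d <- demography(c(4000, 2000, 1000))   # N_2, N_3, N_4
  e <- expected_sfs(d, 1e-8, 1e6)$counts
  expect_equal(e, c(93 + 1 / 3, 66 + 2 / 3, 53 + 1 / 3), tolerance = 1e-12)

  set.seed(7)
  for (n in c(4, 9, 23)) {
    d1 <- random_demography(n)
    d2 <- random_demography(n)
    u <- 1e-8; L <- 1e6
    e1 <- expected_sfs(d1, u, L)$counts
    e2 <- expected_sfs(d2, u, L)$counts
    mix <- demography(0.3 * d1$N + 0.7 * d2$N, n = n)
    expect_equal(expected_sfs(mix, u, L)$counts, 0.3 * e1 + 0.7 * e2,
                 tolerance = 1e-12)
    dbl <- demography(2 * d1$N, n = n)
    expect_equal(expected_sfs(dbl, u, L)$counts, 2 * e1, tolerance = 1e-12)
    # singleton identity: E[G_1] = 4 u L * mean(N_2..N_n)
    expect_equal(e1[1], 4 * u * L * mean(d1$N), tolerance = 1e-12)
  }
})

test_that("folded expectations equal the fold of unfolded expectations", {
  set.seed(11)
  for (n in c(4, 5, 10, 13)) {
    d <- random_demography(n)
    eu <- expected_sfs(d, 1e-8, 1e6)
    ef <- expected_sfs(d, 1e-8, 1e6, folded = TRUE)
    folded_by_hand <- fold_sfs(sfs(round(eu$counts * 1e6), n,
                                   1e13))$counts / 1e6
    expect_equal(ef$counts, folded_by_hand, tolerance = 1e-6)
    m <- n %/% 2
    manual <- vapply(seq_len(m), function(r)
      if (2 * r == n) eu$counts[r] else eu$counts[r] + eu$counts[n - r],
      numeric(1))
    expect_equal(ef$counts, manual, tolerance = 1e-14)
  }
})

test_that("the branch-count route reproduces the weighted-average route", {
  # constant size limit
  e <- expected_sfs_via_W(constant_demography(6, 2500), 1e-8, 1e6)
  expect_equal(e$counts, 4 * 2500 * 1e-8 * 1e6 / (1:5), tolerance = 1e-10)
  # the worked two-epoch example
  d <- demography(c(4000, 2000, 1000))
  expect_equal(expected_sfs_via_W(d, 1e-8, 1e6)$counts,
               expected_sfs(d, 1e-8, 1e6)$counts, tolerance = 1e-12)
  # random demographies, n up to 20
  set.seed(8)
  for (n in c(2, 3, 8, 20)) {
    d <- random_demography(n)
    a <- expected_sfs_via_W(d, 1e-8, 1e6)$counts
    b <- expected_sfs(d, 1e-8, 1e6)$counts
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("expected SFS writer emits a readable two-column TSV", {
  e <- expected_sfs(constant_demography(4, 1000), 1e-8, 1e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expected_sfs(e, path)
  tab <- read.delim(path)
  expect_equal(tab$class, 1:3)
  expect_equal(tab$expected_count, e$counts)
})

test_that("demography constructor validates its input", {
  expect_error(demography(c(1, 2), n = 4), "need 3 sizes")
  expect_error(demography(c(100, -5, 100)), "positive")
  expect_error(demography(numeric(0), n = 1), ">= 2")
})
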