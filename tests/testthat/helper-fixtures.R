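# Shared fixtures: demographies, spectra and a brute-force grid optimiser
# used as an independent check on the Newton fit.

# Random level-indexed demography with sizes spread over ~1.5 orders of
# magnitude.
random_demography <- function(n) {
  demography(exp(stats::runif(n - 1L, log(300), log(3e4))), n = n)
}

# Two-epoch level-indexed demography: N_recent for levels above `split`,
# N_ancient for levels <= split.
two_epoch_demography <- function(n, split, n_recent, n_ancient) {
  demography(ifelse(2:n > split, n_recent, n_ancient), n = n)
}

# SFS whose counts equal the (rounded or exact) expectations of a model.
expectation_sfs <- function(dem, u, L, round_counts = FALSE) {
  mu <- expected_sfs(dem, u, L)$counts
  if (round_counts) mu <- round(mu)
  sfs(mu, n = dem$n, L = L)
}

# Brute-force maximiser of the composite likelihood over group sizes for
# a fixed breakpoint set, independent of the Newton path: a coarse full
# grid locates the basin, then cyclic one-dimensional Brent searches on
# the log scale refine each coordinate in turn (the likelihood is concave
# in the sizes, so coordinate ascent reaches the optimum) to ~0.1%.
grid_search_fit <- function(x, breakpoints, u, lower = 10, upper = 1e6) {
  ngrp <- length(breakpoints) + 1L
  ll_of <- function(sizes)
    composite_log_likelihood(
      x, breakpoint_model(x$n, breakpoints, sizes), u)
  axes <- rep(list(exp(seq(log(lower), log(upper), length.out = 15))),
              ngrp)
  grid <- as.matrix(expand.grid(axes))
  lls <- apply(grid, 1, ll_of)
  sizes <- unname(grid[which.max(lls), ])
  for (sweep in 1:40) {
    for (g in seq_len(ngrp)) {
      f1 <- function(ls) {
        s <- sizes; s[g] <- exp(ls); ll_of(s)
      }
      opt <- stats::optimize(f1, c(log(lower), log(upper)),
                             maximum = TRUE, tol = 1e-6)
      sizes[g] <- exp(opt$maximum)
    }
  }
  list(ll = ll_of(sizes), sizes = sizes)
}
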