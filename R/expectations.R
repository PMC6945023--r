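#' Level-indexed piecewise-constant demography
#'
#' Assigns an effective population size `N_k` (diploid individuals) to each
#' coalescent level `k = 2..n`: `N_n` governs the interval from the sample
#' to the first coalescence, `N_{n-1}` the next interval, and so on down to
#' `N_2`, the last interval before the root. This is the object the
#' stepwise fit estimates, and the model under which expected spectra,
#' allele ages and experienced population sizes are computed.
#'
#' @param sizes numeric vector of length `n - 1` giving `N_k` for
#'   `k = 2, 3, ..., n` in that order; all positive and finite.
#' @param n sample size (haploid genomes); defaults to `length(sizes) + 1`.
#' @return An object of class `"demography"` with fields `n` and `N`
#'   (where `N[k - 1]` is `N_k`).
#' @examples
#' demography(rep(1000, 3))                 # constant N = 1000, n = 4
#' demography(c(4000, 2000, 1000))          # N_2=4000, N_3=2000, N_4=1000
#' @export
demography <- function(sizes, n = length(sizes) + 1L) {
  n <- as.integer(n)
  sizes <- as.numeric(sizes)
  if (n < 2L) stop("n must be >= 2")
  if (length(sizes) != n - 1L)
    stop(sprintf("need %d sizes (levels 2..%d), got %d", n - 1L, n,
                 length(sizes)))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all level sizes must be positive and finite")
  structure(list(n = n, N = sizes), class = "demography")
}

#' Constant-size demography
#'
#' @param n sample size (haploid genomes).
#' @param N effective population size shared by every level.
#' @return A [demography] object.
#' @export
constant_demography <- function(n, N) demography(rep(N, n - 1L), n = n)

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("Level-indexed demography, n = %d\n", x$n))
  grp <- rle(rev(x$N))              # tips (k = n) first
  hi <- x$n
  for (i in seq_along(grp$values)) {
    lo <- hi - grp$lengths[i] + 1L
    cat(sprintf("  levels %d..%d: N = %g\n", hi, lo, grp$values[i]))
    hi <- lo - 1L
  }
  invisible(x)
}

#' Expected coalescent interval length
#'
#' The interval during which `k` lineages persist has expected length
#' `4 N_k / (k (k - 1))` generations.
#'
#' @param k coalescent level (>= 2).
#' @param N_k effective population size during the interval.
#' @return Expected interval length in generations.
#' @export
interval_time <- function(k, N_k) {
  if (any(k < 2)) stop("level k must be >= 2")
  4 * N_k / (k * (k - 1))
}

#' Expected start times of coalescent levels
#'
#' The interval with `k` lineages begins, in expectation,
#' `tau_k = sum_{j = k+1}^{n} 4 N_j / (j (j - 1))` generations before the
#' present; `tau_n = 0`. These are the times at which the stepwise history
#' changes value.
#'
#' @param dem a [demography] object.
#' @return Named numeric vector of `tau_k` for `k = n, n-1, ..., 2`
#'   (non-decreasing).
#' @export
level_start_times <- function(dem) {
  stopifnot(inherits(dem, "demography"))
  n <- dem$n
  ks <- n:2
  tk <- interval_time(ks, dem$N[ks - 1L])       # t_n, t_{n-1}, ..., t_2
  tau <- c(0, cumsum(tk)[-length(tk)])          # tau_n = 0
  names(tau) <- ks
  tau
}

#' Branch-weight of a coalescent level for a frequency class
#'
#' The expected spectrum is a weighted average of the level sizes:
#' `E[G_r] = (4 u L / r) * sum_k w(n, r, k) N_k` with
#' `w(n, r, k) = C(n-k, r-1) / C(n-1, r)`. The weights over
#' `k = 2..n-r+1` sum to one (hockey-stick identity). Binomials are
#' evaluated in log-space so large `n` (hundreds) is safe.
#'
#' @param n sample size.
#' @param r frequency class, `1 <= r <= n - 1`.
#' @param k coalescent level, `2 <= k <= n - r + 1` (vectorised).
#' @return Weight(s) in `[0, 1]`.
#' @export
level_weight <- function(n, r, k) {
  if (r < 1 || r > n - 1) stop("class r out of range")
  if (any(k < 2) || any(k > n - r + 1)) stop("level k out of range")
  exp(lchoose(n - k, r - 1) - lchoose(n - 1, r))
}

# Matrix of level weights: rows r = 1..n-1, cols k = 2..n; zero where
# k > n - r + 1 (lchoose returns -Inf there, exp gives 0).
level_weight_matrix <- function(n) {
  r <- seq_len(n - 1L)
  k <- 2:n
  exp(outer(r, k, function(r, k) lchoose(n - k, r - 1)) -
        lchoose(n - 1, r))
}

#' Expected site-frequency spectrum under a level-indexed demography
#'
#' Closed form for the expected number of sites in each frequency class:
#' `E[G_r] = (4 u L / r) * sum_{k=2}^{n-r+1} C(n-k, r-1)/C(n-1, r) N_k`.
#' With constant `N` this reduces to the classical `4 N u L / r`, and the
#' singleton class always equals `4 u L` times the arithmetic mean of
#' `N_2..N_n`. Folded expectations are the fold of the unfolded ones:
#' `E[F_r] = E[G_r] + E[G_{n-r}]` (middle class unpaired for even `n`).
#'
#' @param dem a [demography] object.
#' @param u mutation rate per site per generation (> 0).
#' @param L number of surveyed sites (> 0).
#' @param folded return folded (minor-allele) expectations?
#' @return An object of class `"expected_sfs"`: list with `n`, `counts`
#'   (expected per-class counts), `u`, `L`, `folded`.
#' @export
expected_sfs <- function(dem, u, L, folded = FALSE) {
  stopifnot(inherits(dem, "demography"))
  if (u <= 0) stop("u must be positive")
  if (L <= 0) stop("L must be positive")
  n <- dem$n
  W <- level_weight_matrix(n)
  eg <- as.vector(W %*% dem$N) * (4 * u * L / seq_len(n - 1L))
  counts <- if (folded) fold_counts(eg, n) else eg
  structure(list(n = n, counts = counts, u = u, L = L,
                 folded = isTRUE(folded)),
            class = "expected_sfs")
}

# Fold a vector of unfolded per-class values.
fold_counts <- function(g, n) {
  m <- n %/% 2L
  vapply(seq_len(m), function(r)
    if (2L * r == n) g[r] else g[r] + g[n - r], numeric(1))
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf("Expected %s SFS: n = %d, u = %g, L = %g\n",
              if (x$folded) "folded" else "unfolded", x$n, x$u, x$L))
  print(stats::setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Expected SFS via per-level branch counts (cross-check path)
#'
#' Computes the same expectations as [expected_sfs()] along an independent
#' algebraic route: the expected number of order-`r` branch segments
#' present at level `k` is `W_k(r) = k C(n-r-1, k-2) / C(n-1, k-1)`, of
#' which a fraction `(r-1)/(n-k)` start at level `k`; a branch starting at
#' level `k` carries a mutation with probability `4 u Nbar(k) / k`, where
#' `Nbar(k)` is the arithmetic mean of `N_2..N_k`. Summing the
#' contributions over starting levels gives
#' `E[G_r] = 4 u L (r-1) sum_{k=2}^{n-r+1} W_k(r) / (k (n-k)) Nbar(k)`
#' for `r >= 2`; singletons come from the mean-size identity
#' `E[G_1] = 4 u L Nbar(n)`. Used as a two-path consistency guard on the
#' weighted-average form.
#'
#' @inheritParams expected_sfs
#' @return An `"expected_sfs"` object (always unfolded).
#' @export
expected_sfs_via_W <- function(dem, u, L) {
  stopifnot(inherits(dem, "demography"))
  if (u <= 0) stop("u must be positive")
  if (L <= 0) stop("L must be positive")
  n <- dem$n
  N <- dem$N
  nbar <- cumsum(N) / seq_len(n - 1L)   # Nbar(k) = mean(N_2..N_k), index k-1
  eg <- numeric(n - 1L)
  eg[1] <- 4 * u * L * nbar[n - 1L]
  if (n >= 3L) {
    for (r in 2:(n - 1L)) {
      ks <- 2:(n - r + 1L)
      Wk <- ks * exp(lchoose(n - r - 1, ks - 2) - lchoose(n - 1, ks - 1))
      eg[r] <- 4 * u * L * (r - 1) *
        sum(Wk / (ks * (n - ks)) * nbar[ks - 1L])
    }
  }
  structure(list(n = n, counts = eg, u = u, L = L, folded = FALSE),
            class = "expected_sfs")
}

#' Write expected SFS as TSV
#'
#' @param x an `"expected_sfs"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expected_sfs <- function(x, path) {
  stopifnot(inherits(x, "expected_sfs"))
  utils::write.table(
    data.frame(class = seq_along(x$counts), expected_count = x$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
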