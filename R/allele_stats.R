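# Shared machinery for class-level allele statistics.
#
# Every moment below is a ratio of sums over the level at which the
# carrying branch starts, weighted by N_k * C(n-k, r-1). The inner sums
# over later (more ancient) levels are suffix cumulative arrays of
# w_l = N_l / (l (l - 1)), so each class costs O(n) after O(n) setup.
# Binomial factors are kept in log-space with the maximum subtracted
# before exponentiation, so samples of hundreds of genomes are safe.
age_weights <- function(n, r) {
  ks <- 2:n
  lw <- lchoose(n - ks, r - 1)        # -Inf where the class cannot start
  lw <- lw - max(lw)
  exp(lw)
}

#' Moments of the age of an allele of given frequency
#'
#' For an unfolded spectrum, the expected age (generations before present)
#' of a derived allele seen in `r` of `n` genomes is a weighted average
#' over the level at which its branch starts, with each level's
#' contribution integrating the expected interval lengths back to the
#' root:
#' `E[A_r] = 4 [sum_k N_k C(n-k, r-1) sum_{l=k}^{n} N_l/(l(l-1))] /
#'            [sum_k N_k C(n-k, r-1)]`,
#' and the second moment carries one more nested interval sum with
#' coefficient 32. The variance is `E[A_r^2] - E[A_r]^2`.
#'
#' @param dem a [demography] object.
#' @param r frequency class, `1 <= r <= n - 1`.
#' @return List with `mean`, `second_moment`, `variance` (generations,
#'   generations^2).
#' @export
allele_age_moments <- function(dem, r) {
  stopifnot(inherits(dem, "demography"))
  n <- dem$n
  if (r < 1 || r > n - 1) stop("class r out of range")
  N <- dem$N                               # N[k-1] = N_k, k = 2..n
  ks <- 2:n
  w <- N / (ks * (ks - 1))                 # w_l, l = 2..n
  T1 <- rev(cumsum(rev(w)))                # T1[k-1] = sum_{l=k}^{n} w_l
  T2 <- rev(cumsum(rev(w * T1)))           # sum_{l=k}^{n} w_l T1(l)
  cw <- N * age_weights(n, r)
  den <- sum(cw)
  m1 <- 4 * sum(cw * T1) / den
  m2 <- 32 * sum(cw * T2) / den
  list(mean = m1, second_moment = m2, variance = m2 - m1^2)
}

#' Probability that a minor-allele SNP is the derived variant
#'
#' A folded class `r` mixes derived alleles of order `r` with ancestral
#' alleles of order `n - r`. The derived fraction is
#' `pd = E[G_r] / (E[G_r] + E[G_{n-r}])`, computed from the expected
#' unfolded spectrum; under constant size this is `(n - r) / n`.
#'
#' @param dem a [demography] object.
#' @param u mutation rate per site per generation.
#' @param L number of surveyed sites.
#' @param r minor-allele class, `1 <= r <= floor(n/2)`.
#' @return `pd` in `[0, 1]`; the ancestral fraction is `1 - pd`.
#' @export
derived_fraction <- function(dem, u, L, r) {
  stopifnot(inherits(dem, "demography"))
  n <- dem$n
  if (r < 1 || r > n %/% 2) stop("class r out of range for folded spectrum")
  eg <- expected_sfs(dem, u, L)$counts
  if (2 * r == n) return(0.5)
  eg[r] / (eg[r] + eg[n - r])
}

#' Age moments for a class of a folded spectrum
#'
#' Mixture of the derived (order `r`) and ancestral (order `n - r`)
#' components: `E[A*_r] = pd E[A_r] + pa E[A_{n-r}]` and
#' `Var(A*_r) = pd^2 Var(A_r) + pa^2 Var(A_{n-r})`, with `pd` from
#' [derived_fraction()].
#'
#' @inheritParams derived_fraction
#' @return List with `mean`, `variance`, `pd`, `pa`.
#' @export
folded_age_moments <- function(dem, u, L, r) {
  n <- dem$n
  if (r < 1 || r > n %/% 2) stop("class r out of range for folded spectrum")
  pd <- derived_fraction(dem, u, L, r)
  pa <- 1 - pd
  ad <- allele_age_moments(dem, r)
  aa <- allele_age_moments(dem, n - r)
  list(mean = pd * ad$mean + pa * aa$mean,
       variance = pd^2 * ad$variance + pa^2 * aa$variance,
       pd = pd, pa = pa)
}

#' Long-term effective size experienced by alleles of a class
#'
#' The mean population size over an allele's lifetime, defined as the
#' ratio of expectations `E[integral of N(s) ds over the allele's age] /
#' E[age]`. In the level-indexed model both expectations decompose over
#' the starting level, giving
#' `E[P_r] = [sum_k N_k C(n-k, r-1) sum_{l=k}^{n} 4 N_l^2/(l(l-1))] /
#'            [sum_k N_k C(n-k, r-1) sum_{l=k}^{n} 4 N_l/(l(l-1))]`,
#' a weighted average of the `N_k` (so always within their range, and
#' exactly `N` under constant size).
#'
#' @param dem a [demography] object.
#' @param r frequency class, `1 <= r <= n - 1`.
#' @return `E[P_r]` in diploid individuals.
#' @export
experienced_ne <- function(dem, r) {
  stopifnot(inherits(dem, "demography"))
  n <- dem$n
  if (r < 1 || r > n - 1) stop("class r out of range")
  N <- dem$N
  ks <- 2:n
  w1 <- 4 * N / (ks * (ks - 1))
  w2 <- 4 * N^2 / (ks * (ks - 1))
  S1 <- rev(cumsum(rev(w1)))
  S2 <- rev(cumsum(rev(w2)))
  cw <- N * age_weights(n, r)
  sum(cw * S2) / sum(cw * S1)
}

#' Experienced Ne for a class of a folded spectrum
#'
#' Applies the same derived/ancestral mixture weights as
#' [folded_age_moments()] to the experienced sizes of orders `r` and
#' `n - r`.
#'
#' @inheritParams derived_fraction
#' @return Mixture `pd * E[P_r] + pa * E[P_{n-r}]`.
#' @export
folded_experienced_ne <- function(dem, u, L, r) {
  n <- dem$n
  if (r < 1 || r > n %/% 2) stop("class r out of range for folded spectrum")
  pd <- derived_fraction(dem, u, L, r)
  pd * experienced_ne(dem, r) + (1 - pd) * experienced_ne(dem, n - r)
}

#' Per-class allele age and experienced-Ne report
#'
#' Tabulates, for every frequency class of the (folded or unfolded)
#' spectrum, the derived fraction, mean and standard deviation of allele
#' age, and the mean experienced population size.
#'
#' @param dem a [demography] object.
#' @param u mutation rate per site per generation.
#' @param L number of surveyed sites.
#' @param folded report folded (minor-allele) classes?
#' @return A data.frame with columns `class`, `pd`, `mean_age`, `sd_age`,
#'   `mean_experienced_ne`. For unfolded reports `pd` is 1 by definition.
#' @export
allele_class_summary <- function(dem, u, L, folded = FALSE) {
  n <- dem$n
  classes <- if (folded) seq_len(n %/% 2) else seq_len(n - 1L)
  rows <- lapply(classes, function(r) {
    if (folded) {
      m <- folded_age_moments(dem, u, L, r)
      data.frame(class = r, pd = m$pd, mean_age = m$mean,
                 sd_age = sqrt(max(m$variance, 0)),
                 mean_experienced_ne = folded_experienced_ne(dem, u, L, r))
    } else {
      m <- allele_age_moments(dem, r)
      data.frame(class = r, pd = 1, mean_age = m$mean,
                 sd_age = sqrt(max(m$variance, 0)),
                 mean_experienced_ne = experienced_ne(dem, r))
    }
  })
  do.call(rbind, rows)
}
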