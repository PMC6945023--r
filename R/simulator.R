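#' Time-indexed piecewise-constant demography for simulation
#'
#' Epochs are given looking backwards from the present: the first starts
#' at generation 0, each later one at a strictly larger time, and each has
#' a single diploid effective size. This is the natural parameterisation
#' for specifying "truth" scenarios; the inference model itself is
#' level-indexed (see [demography()]) and the simulator supports both.
#'
#' @param starts numeric vector of epoch start times (generations before
#'   present), strictly increasing with `starts[1] == 0`.
#' @param sizes positive diploid effective size of each epoch.
#' @return An object of class `"epoch_demography"`.
#' @examples
#' epoch_demography(c(0, 5000), c(1000, 10000))  # 10-fold ancient increase
#' @export
epoch_demography <- function(starts, sizes) {
  starts <- as.numeric(starts); sizes <- as.numeric(sizes)
  if (length(starts) != length(sizes) || !length(starts))
    stop("starts and sizes must have equal positive length")
  if (starts[1] != 0) stop("first epoch must start at generation 0")
  if (any(diff(starts) <= 0)) stop("epoch starts must be strictly increasing")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("epoch sizes must be positive and finite")
  structure(list(starts = starts, sizes = sizes),
            class = "epoch_demography")
}

#' @export
print.epoch_demography <- function(x, ...) {
  cat("Time-indexed demography (generations before present):\n")
  for (i in seq_along(x$starts))
    cat(sprintf("  from %g: N = %g\n", x$starts[i], x$sizes[i]))
  invisible(x)
}

#' Preset demographic scenarios
#'
#' Fixed time-indexed demographies used in tests and demonstrations:
#' `"constant"` (N = 10,000), `"two_epoch_decline"` (N = 1,000 since
#' generation 5,000 before present, N = 10,000 earlier — a 10-fold
#' decline towards the present), `"two_epoch_expansion"` (the reverse),
#' and `"bottleneck"` (N = 10,000 recently, N = 500 between 2,000 and
#' 6,000 generations ago, N = 10,000 before that).
#'
#' @param name one of `"constant"`, `"two_epoch_decline"`,
#'   `"two_epoch_expansion"`, `"bottleneck"`.
#' @return An [epoch_demography] object.
#' @export
scenario_presets <- function(name) {
  switch(name,
    constant = epoch_demography(0, 1e4),
    two_epoch_decline = epoch_demography(c(0, 5e3), c(1e3, 1e4)),
    two_epoch_expansion = epoch_demography(c(0, 5e3), c(1e4, 1e3)),
    bottleneck = epoch_demography(c(0, 2e3, 6e3), c(1e4, 5e2, 1e4)),
    stop(sprintf("unknown scenario '%s'", name)))
}

# Waiting time to the next coalescence for k lineages starting at time t0,
# under a time-indexed demography: the pair rate is k(k-1)/(4 N(t)), so
# the exponential hazard is integrated epoch by epoch.
epoch_waiting_time <- function(k, dem, t0) {
  target <- stats::rexp(1)
  rate_scale <- k * (k - 1) / 4
  starts <- dem$starts; sizes <- dem$sizes
  bounds <- c(starts, Inf)
  t <- t0
  i <- findInterval(t0, starts)
  acc <- 0
  repeat {
    seg_end <- bounds[i + 1L]
    rate <- rate_scale / sizes[i]
    need <- (target - acc) / rate
    if (t + need <= seg_end) return(t + need - t0)
    acc <- acc + rate * (seg_end - t)
    t <- seg_end
    i <- i + 1L
  }
}

# One genealogy's realised level waiting times t_n..t_2.
draw_level_times <- function(n, dem) {
  if (inherits(dem, "demography")) {
    if (dem$n != n) stop("demography has wrong sample size")
    ks <- n:2
    stats::rexp(n - 1L, rate = ks * (ks - 1) / (4 * dem$N[ks - 1L]))
  } else if (inherits(dem, "epoch_demography")) {
    tk <- numeric(n - 1L)
    t <- 0
    for (i in seq_len(n - 1L)) {
      k <- n - i + 1L
      tk[i] <- epoch_waiting_time(k, dem, t)
      t <- t + tk[i]
    }
    tk
  } else stop("dem must be a demography or epoch_demography")
}

#' Simulate a coalescent genealogy
#'
#' Draws a random genealogy of `n` lineages under a piecewise-constant
#' demography. In level-indexed mode the waiting time while `k` lineages
#' persist is exponential with mean `4 N_k / (k (k - 1))`; in time-indexed
#' mode the pairwise coalescence rate is `k (k - 1) / (4 N(t))`,
#' integrated across epoch boundaries. The coalescing pair is always
#' chosen uniformly. All times are generations before present.
#'
#' @param n sample size (>= 2).
#' @param dem a [demography] (level-indexed) or [epoch_demography]
#'   (time-indexed) object.
#' @param seed optional integer seed (reproducible given the seed).
#' @return An object of class `"genealogy"`: list with `n`,
#'   `level_times` (realised `t_n..t_2`), and `branches`, a data.frame
#'   with one row per non-root branch giving its descendant tip count
#'   `r`, creation time `t_start`, and end (coalescence) time `t_end`.
#' @export
simulate_genealogy <- function(n, dem, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tk <- draw_level_times(n, dem)
  cnt <- rep(1L, n)
  born <- numeric(n)
  br_r <- integer(2L * (n - 1L)); br_s <- numeric(2L * (n - 1L))
  br_e <- numeric(2L * (n - 1L))
  t <- 0
  j <- 0L
  for (i in seq_len(n - 1L)) {
    k <- n - i + 1L
    t <- t + tk[i]
    pair <- sample.int(k, 2L)
    br_r[j + 1:2] <- cnt[pair]
    br_s[j + 1:2] <- born[pair]
    br_e[j + 1:2] <- t
    j <- j + 2L
    cnt[pair[1L]] <- cnt[pair[1L]] + cnt[pair[2L]]
    born[pair[1L]] <- t
    cnt <- cnt[-pair[2L]]
    born <- born[-pair[2L]]
  }
  structure(list(n = n, level_times = tk,
                 branches = data.frame(r = br_r, t_start = br_s,
                                       t_end = br_e)),
            class = "genealogy")
}

# Per-class total branch lengths for `reps` genealogies: a reps x (n-1)
# matrix whose (i, r) entry is the summed length of branches with r tip
# descendants in replicate i. The merge loop only needs tip counts, so
# each level contributes its waiting time to the classes present.
sim_class_lengths <- function(n, dem, reps) {
  out <- matrix(0, reps, n - 1L)
  for (i in seq_len(reps)) {
    tk <- draw_level_times(n, dem)
    cnt <- rep(1L, n)
    len <- numeric(n - 1L)
    for (s in seq_len(n - 1L)) {
      k <- n - s + 1L
      len <- len + tk[s] * tabulate(cnt, nbins = n - 1L)
      pair <- sample.int(k, 2L)
      cnt[pair[1L]] <- cnt[pair[1L]] + cnt[pair[2L]]
      cnt <- cnt[-pair[2L]]
    }
    out[i, ] <- len
  }
  out
}

#' Simulate a site-frequency spectrum
#'
#' Generates an unfolded SFS under the infinite-sites model: the `L`
#' sites are split over `loci` independent genealogies (unlinked loci),
#' and each branch receives a Poisson number of mutations with mean
#' `u * sites_per_locus * branch length`, every mutation hitting a new
#' site and incrementing the class equal to its branch's descendant
#' count. Fold afterwards with [fold_sfs()] if required.
#'
#' @param n sample size.
#' @param dem a [demography] or [epoch_demography].
#' @param u mutation rate per site per generation.
#' @param L total number of sites.
#' @param loci number of independent genealogies sharing the `L` sites.
#' @param seed optional integer seed.
#' @return An unfolded [sfs] object.
#' @export
simulate_sfs <- function(n, dem, u, L, loci = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (u < 0) stop("u must be non-negative")
  lens <- sim_class_lengths(n, dem, loci)
  mu <- u * (L / loci) * lens
  counts <- colSums(matrix(stats::rpois(length(mu), mu), nrow(mu)))
  if (sum(counts) > L)
    stop("simulated polymorphisms exceed L; infinite-sites assumption broken")
  sfs(counts, n = n, L = L, folded = FALSE)
}

#' Mean simulated SFS with Monte-Carlo standard errors
#'
#' Simulates `reps` independent single-genealogy spectra (each over `L`
#' sites) and returns the per-class mean count and its standard error —
#' the Monte-Carlo oracle against which the closed-form expected SFS is
#' validated.
#'
#' @inheritParams simulate_sfs
#' @param reps number of replicate genealogies.
#' @return A data.frame with columns `class`, `mean`, `se`.
#' @export
simulate_mean_sfs <- function(n, dem, u, L, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sim_class_lengths(n, dem, reps)
  counts <- matrix(stats::rpois(length(lens), u * L * lens), reps)
  data.frame(class = seq_len(n - 1L),
             mean = colMeans(counts),
             se = apply(counts, 2, stats::sd) / sqrt(reps))
}

# Cumulative integral of N(s) ds from the present to time t, for a
# genealogy's realised level intervals (level-indexed demography) or for
# the epochs of a time-indexed demography.
make_n_integral <- function(dem, level_times = NULL, n = NULL) {
  if (inherits(dem, "demography")) {
    bounds <- cumsum(level_times)                  # ends of levels n..2
    sizes <- dem$N[(n:2) - 1L]                     # N_n..N_2
    starts <- c(0, bounds[-length(bounds)])
  } else {
    starts <- dem$starts
    sizes <- dem$sizes
    bounds <- c(dem$starts[-1], Inf)
  }
  cum <- c(0, cumsum(sizes * (bounds - starts)))
  function(t) {
    i <- findInterval(t, starts)
    # beyond the last realised level the last size extends to the root
    i <- pmin(i, length(sizes))
    cum[i] + (t - starts[i]) * sizes[i]
  }
}

#' Simulate mutation ages and lifetime population-size integrals
#'
#' The Monte-Carlo oracle for allele-age and experienced-Ne theory. For
#' each replicate genealogy, every branch receives a Poisson number of
#' mutations with mean `u` times its length (interpret `u` as an
#' aggregate per-generation rate chosen to give a convenient yield);
#' each mutation lands uniformly along its branch. Per mutation the
#' record holds its class `r` (descendant count), its age (generations
#' before present), and the exact integral of `N(s)` over `[0, age]`. In
#' level-indexed mode `N(s)` follows the genealogy's own realised
#' coalescent intervals, matching the definition of the experienced size
#' as a ratio of expectations; in time-indexed mode it follows the
#' epochs.
#'
#' @param n sample size.
#' @param dem a [demography] or [epoch_demography].
#' @param u expected mutations per generation of branch length.
#' @param reps number of replicate genealogies.
#' @param seed optional integer seed.
#' @return A data.frame with columns `r`, `age`, `n_integral`.
#' @export
simulate_mutation_ages <- function(n, dem, u, reps, seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  acc_r <- vector("list", reps); acc_a <- vector("list", reps)
  acc_i <- vector("list", reps)
  for (i in seq_len(reps)) {
    gen <- simulate_genealogy(n, dem)
    br <- gen$branches
    m <- stats::rpois(nrow(br), u * (br$t_end - br$t_start))
    if (sum(m) == 0) next
    idx <- rep.int(seq_len(nrow(br)), m)
    age <- stats::runif(length(idx), br$t_start[idx], br$t_end[idx])
    nint <- make_n_integral(dem, gen$level_times, n)
    acc_r[[i]] <- br$r[idx]
    acc_a[[i]] <- age
    acc_i[[i]] <- nint(age)
  }
  lens <- vapply(acc_r, length, integer(1))
  data.frame(rep = rep.int(seq_len(reps), lens),
             r = unlist(acc_r) %||% integer(),
             age = unlist(acc_a) %||% numeric(),
             n_integral = unlist(acc_i) %||% numeric())
}

#' Per-class summary of simulated mutation records
#'
#' Summarises [simulate_mutation_ages()] output per frequency class: the
#' mean mutation age and the experienced-size estimate formed as
#' (mean integral) / (mean age) — the ratio of means, matching the
#' theoretical definition. Mutations sharing a genealogy share its
#' realised history and are correlated, so standard errors treat
#' genealogies (not mutations) as the independent units, via the
#' ratio-estimator variance over per-genealogy totals.
#'
#' @param records data.frame from [simulate_mutation_ages()].
#' @return A data.frame with columns `class`, `n_mut`, `mean_age`,
#'   `se_age`, `experienced_ne`, `se_experienced_ne`.
#' @export
summarize_mutation_ages <- function(records) {
  cls <- sort(unique(records$r))
  # cluster-robust SE of R = sum(num) / sum(den) over genealogy totals;
  # genealogies with no mutations in the class contribute zero to every
  # sum and to the squared residuals, so they can be left implicit.
  ratio_se <- function(num_i, den_i) {
    R <- sum(num_i) / sum(den_i)
    G <- length(num_i)
    if (G < 2) return(NA_real_)
    sqrt(sum((num_i - R * den_i)^2) * G / (G - 1)) / sum(den_i)
  }
  rows <- lapply(cls, function(r) {
    sel <- records$r == r
    g <- records$rep[sel]
    m_i <- tapply(rep(1, sum(sel)), g, sum)
    a_i <- tapply(records$age[sel], g, sum)
    v_i <- tapply(records$n_integral[sel], g, sum)
    data.frame(class = r, n_mut = sum(sel),
               mean_age = sum(a_i) / sum(m_i),
               se_age = ratio_se(a_i, m_i),
               experienced_ne = sum(v_i) / sum(a_i),
               se_experienced_ne = ratio_se(v_i, a_i))
  })
  do.call(rbind, rows)
}
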