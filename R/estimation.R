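#' Breakpoint parameterisation of a demography
#'
#' A breakpoint at level `b` (with `2 <= b <= n - 1`) splits the levels so
#' that `N_i` takes one value for `i > b` and another for `i <= b`.
#' A set of `m` breakpoints partitions levels `2..n` into `m + 1`
#' contiguous groups, each sharing a single effective size; this is the
#' parameterisation the stepwise search explores.
#'
#' @param n sample size (haploid genomes).
#' @param breakpoints integer vector of distinct levels in `2..n-1`
#'   (stored in decreasing order, i.e. from the tips towards the root).
#' @param group_sizes one positive size per group, ordered from the tip
#'   group to the root group (`length(breakpoints) + 1` values).
#' @return An object of class `"breakpoint_model"`.
#' @export
breakpoint_model <- function(n, breakpoints, group_sizes) {
  n <- as.integer(n)
  breakpoints <- sort(unique(as.integer(breakpoints)), decreasing = TRUE)
  if (length(breakpoints) > n - 2L)
    stop("at most n - 2 breakpoints are possible")
  if (length(breakpoints) && (any(breakpoints < 2L) ||
                              any(breakpoints > n - 1L)))
    stop("breakpoints must be levels in 2..n-1")
  if (length(group_sizes) != length(breakpoints) + 1L)
    stop("need one size per group (breakpoints + 1)")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  structure(list(n = n, breakpoints = breakpoints,
                 group_sizes = as.numeric(group_sizes)),
            class = "breakpoint_model")
}

# Group index (1 = tip group) of every level k = 2..n.
level_groups <- function(n, breakpoints) {
  ks <- 2:n
  1L + vapply(ks, function(k) sum(k <= breakpoints), integer(1))
}

#' Expand a breakpoint model to per-level sizes
#'
#' @param model a [breakpoint_model].
#' @return The corresponding [demography] object.
#' @export
expand_model <- function(model) {
  stopifnot(inherits(model, "breakpoint_model"))
  g <- level_groups(model$n, model$breakpoints)
  demography(model$group_sizes[g], n = model$n)
}

# Design matrix mapping group sizes to expected class counts:
# mu = A %*% group_sizes for the classes kept in the likelihood.
# Rows follow the spectrum's own classes (folded or unfolded) minus the
# excluded ones; attribute "a0" holds the column sums over ALL polymorphic
# classes (used for the monomorphic mean L - a0 %*% x).
sfs_design <- function(n, breakpoints, u, L, folded, excluded = integer()) {
  W <- level_weight_matrix(n)                       # (n-1) x (n-1), k = 2..n
  g <- level_groups(n, breakpoints)
  ngrp <- length(breakpoints) + 1L
  M <- matrix(0, n - 1L, ngrp)
  M[cbind(seq_len(n - 1L), g)] <- 1                 # level -> group indicator
  A <- (W %*% M) * (4 * u * L / seq_len(n - 1L))    # unfolded classes
  if (folded) {
    m <- n %/% 2L
    Af <- A[seq_len(m), , drop = FALSE]
    for (r in seq_len(m))
      if (2L * r != n) Af[r, ] <- A[r, ] + A[n - r, ]
    A <- Af
  }
  a0 <- colSums(A)
  if (length(excluded)) A <- A[-excluded, , drop = FALSE]
  attr(A, "a0") <- a0
  A
}

# Poisson composite log-likelihood, gradient and Hessian in the group
# sizes x (mu = A x is linear in x, so the likelihood is concave).
# Log-factorial constants are dropped throughout.
poisson_ll <- function(x, A, g, mono = NULL) {
  mu <- as.vector(A %*% x)
  if (any(!is.finite(mu))) return(-Inf)
  if (any(mu <= 0)) {
    if (any(mu <= 0 & g > 0)) return(-Inf)
    mu <- pmax(mu, .Machine$double.xmin)
  }
  ll <- sum(ifelse(g > 0, g * log(mu), 0) - mu)
  if (!is.null(mono)) {
    mu0 <- mono$L - sum(mono$a0 * x)
    if (mu0 <= 0) return(-Inf)
    ll <- ll + (if (mono$G0 > 0) mono$G0 * log(mu0) else 0) - mu0
  }
  ll
}

poisson_grad <- function(x, A, g, mono = NULL) {
  mu <- pmax(as.vector(A %*% x), .Machine$double.xmin)
  gr <- as.vector(crossprod(A, g / mu - 1))
  if (!is.null(mono)) {
    mu0 <- max(mono$L - sum(mono$a0 * x), .Machine$double.xmin)
    gr <- gr - mono$a0 * (mono$G0 / mu0 - 1)
  }
  gr
}

poisson_hess <- function(x, A, g, mono = NULL) {
  mu <- pmax(as.vector(A %*% x), .Machine$double.xmin)
  H <- -crossprod(A * sqrt(g) / mu)
  if (!is.null(mono)) {
    mu0 <- max(mono$L - sum(mono$a0 * x), .Machine$double.xmin)
    H <- H - tcrossprod(mono$a0) * (mono$G0 / mu0^2)
  }
  H
}

# Damped Newton ascent on theta = log(x), with a gradient-ascent fallback
# and a positivity floor x >= eps. Convergence: projected-gradient norm
# below tol * max(1, |ll|).
newton_fit_sizes <- function(A, g, x0, eps, mono = NULL,
                             max_iter = 200L, tol = 1e-8) {
  theta <- log(pmax(x0, eps))
  lo <- log(eps)
  hi <- 170                                        # e^170 ~ 1e73: no overflow
  x <- exp(theta)
  ll <- poisson_ll(x, A, g, mono)
  if (!is.finite(ll)) stop("infeasible starting point for size optimisation")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gx <- poisson_grad(x, A, g, mono)
    gt <- x * gx                                   # gradient in theta
    pg <- gt
    pg[theta <= lo + 1e-12 & gt < 0] <- 0          # projected at the floor
    if (sqrt(sum(pg^2)) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    Hx <- poisson_hess(x, A, g, mono)
    Ht <- (x %o% x) * Hx + diag(gt, length(x))
    # active set: coordinates pinned at the floor with an outward pull are
    # frozen, so they cannot poison the conditioning of the Newton system
    free <- which(!(theta <= lo + 1e-12 & gt < 0))
    dir <- numeric(length(x))
    if (length(free)) {
      d_f <- tryCatch(solve(Ht[free, free, drop = FALSE], -gt[free]),
                      error = function(e) NULL)
      if (is.null(d_f) || sum(d_f * gt[free]) <= 0)
        d_f <- gt[free] / max(sqrt(sum(gt[free]^2)), 1e-300)  # ascent fallback
      dir[free] <- d_f
    }
    step <- 1
    slope <- sum(dir * gt)
    repeat {
      theta_new <- pmin(pmax(theta + step * dir, lo), hi)
      ll_new <- poisson_ll(exp(theta_new), A, g, mono)
      if (is.finite(ll_new) && ll_new >= ll + 1e-4 * step * slope) break
      step <- step / 2
      if (step < 1e-14) { theta_new <- theta; ll_new <- ll; break }
    }
    if (ll_new <= ll && step < 1e-14) {            # stalled: optimum may sit
      gx <- poisson_grad(x, A, g, mono)            # on the boundary
      pg <- x * gx
      pg[theta <= lo + 1e-12 & pg < 0] <- 0
      converged <- sqrt(sum(pg^2)) < tol * max(1, abs(ll))
      break
    }
    theta <- theta_new
    x <- exp(theta)
    ll <- ll_new
  }
  list(sizes = x, log_likelihood = ll, n_iterations = iter,
       converged = converged)
}

#' Composite Poisson log-likelihood of an SFS under a demographic model
#'
#' Treats the per-class counts as independent Poisson observations with
#' means equal to the expected spectrum under the model (folded means for
#' a folded spectrum), and returns
#' `sum over kept classes of (G_r log mu_r - mu_r)` with log-factorial
#' constants dropped. The monomorphic class is excluded by default; with
#' `include_monomorphic = TRUE` a Poisson term for
#' `G_0 = L - sum(counts)` with mean `L - sum(mu_r)` is added.
#'
#' @param x an [sfs] object (its `excluded` classes are skipped).
#' @param model a [breakpoint_model] or [demography].
#' @param u mutation rate per site per generation.
#' @param include_monomorphic add the monomorphic-class Poisson term?
#' @return The composite log-likelihood; `-Inf` if some kept class has a
#'   zero mean but a positive count.
#' @export
composite_log_likelihood <- function(x, model, u,
                                     include_monomorphic = FALSE) {
  stopifnot(inherits(x, "sfs"))
  if (u <= 0) stop("u must be positive")
  dem <- if (inherits(model, "breakpoint_model")) expand_model(model)
         else model
  stopifnot(inherits(dem, "demography"))
  if (dem$n != x$n) stop("model and SFS sample sizes differ")
  mu <- expected_sfs(dem, u, x$L, folded = x$folded)$counts
  g <- x$counts
  keep <- setdiff(seq_along(g), x$excluded)
  if (any(mu[keep] <= 0 & g[keep] > 0)) return(-Inf)
  ll <- sum(ifelse(g[keep] > 0, g[keep] * log(mu[keep]), 0) - mu[keep])
  if (include_monomorphic) {
    mu0 <- x$L - sum(mu)
    G0 <- x$L - sum(g)
    if (mu0 <= 0) return(-Inf)
    ll <- ll + (if (G0 > 0) G0 * log(mu0) else 0) - mu0
  }
  ll
}

#' Maximum-likelihood sizes for a fixed set of breakpoints
#'
#' Maximises the composite Poisson likelihood over the group sizes of a
#' fixed breakpoint configuration. Because every expected class count is
#' linear in the group sizes, the likelihood is concave and a damped
#' Newton iteration on the log-sizes converges reliably; sizes are floored
#' at `1e-6` times the Watterson estimate. With no breakpoints, no folding
#' and no exclusions the optimum is Watterson's estimator
#' `S / (4 u L a)`.
#'
#' @param x an [sfs] object.
#' @param breakpoints integer vector of levels in `2..n-1` (possibly
#'   empty for the constant-size model).
#' @param u mutation rate per site per generation.
#' @param init optional vector of starting group sizes (tips to root);
#'   defaults to the Watterson estimate for every group.
#' @param exclude classes to exclude, merged with `x$excluded`.
#' @param include_monomorphic see [composite_log_likelihood()].
#' @param max_iter Newton iteration cap; exceeding it flags
#'   non-convergence.
#' @return An object of class `"sfs_fit"`: the fitted [breakpoint_model],
#'   `log_likelihood`, expanded `demography`, `steps` (a data.frame of
#'   `(start_generations, Ne)` pairs), `n_iterations`, `converged`.
#' @export
fit_fixed_breakpoints <- function(x, breakpoints, u, init = NULL,
                                  exclude = NULL,
                                  include_monomorphic = FALSE,
                                  max_iter = 200L) {
  stopifnot(inherits(x, "sfs"))
  if (u <= 0) stop("u must be positive")
  n <- x$n
  breakpoints <- sort(unique(as.integer(breakpoints)), decreasing = TRUE)
  excluded <- sort(union(x$excluded, as.integer(exclude %||% integer())))
  nclass <- length(x$counts)
  if (length(excluded) && any(excluded < 1 | excluded > nclass))
    stop("excluded class index out of range")
  if (length(excluded) >= nclass)
    stop("cannot exclude every class")
  A <- sfs_design(n, breakpoints, u, x$L, x$folded, excluded)
  g <- x$counts[setdiff(seq_len(nclass), excluded)]
  ne_w <- watterson_theta(x, u)$Ne_hat
  eps <- 1e-6 * max(ne_w, 1)
  ngrp <- length(breakpoints) + 1L
  x0 <- if (is.null(init)) rep(max(ne_w, eps * 10), ngrp) else init
  if (length(x0) != ngrp) stop("init must have one size per group")
  mono <- if (include_monomorphic)
    list(L = x$L, G0 = x$L - sum(x$counts), a0 = attr(A, "a0")) else NULL
  opt <- newton_fit_sizes(A, g, x0, eps, mono, max_iter = max_iter)
  model <- breakpoint_model(n, breakpoints, opt$sizes)
  dem <- expand_model(model)
  structure(list(model = model, log_likelihood = opt$log_likelihood,
                 demography = dem,
                 steps = steps_from_model(model),
                 n_iterations = opt$n_iterations,
                 converged = opt$converged,
                 excluded = excluded, u = u),
            class = "sfs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sfs_fit <- function(x, ...) {
  cat(sprintf("Stepwise SFS fit: n = %d, %d breakpoint(s), logL = %.4f%s\n",
              x$model$n, length(x$model$breakpoints), x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  print(x$steps)
  invisible(x)
}

# (start time, Ne) step pairs for a breakpoint model: each group starts at
# the expected onset of its most tip-ward level.
steps_from_model <- function(model) {
  dem <- expand_model(model)
  tau <- level_start_times(dem)                    # named by k = n..2
  hi <- c(model$n, model$breakpoints)              # highest level per group
  data.frame(start_generations = unname(tau[as.character(hi)]),
             Ne = model$group_sizes)
}

#' Step-function representation of a fitted history
#'
#' Converts a fit to `(start time, Ne)` pairs: the fitted per-level sizes
#' define expected interval lengths, whose cumulative sums place each
#' group's onset in generations before present. The first step starts at
#' time 0 with the tip-group size; times increase strictly across steps.
#'
#' @param fit an `"sfs_fit"` object.
#' @return A data.frame with columns `start_generations` and `Ne`.
#' @export
history_to_steps <- function(fit) {
  stopifnot(inherits(fit, "sfs_fit"))
  fit$steps
}

#' Stepwise breakpoint search with likelihood-gain stopping
#'
#' Starts from the constant-size model (whose optimum is Watterson's
#' estimator) and adds one breakpoint per iteration. In `"greedy"` mode
#' every unused candidate level is tried in addition to the already
#' accepted breakpoints (all group sizes re-optimised jointly each time);
#' in `"exhaustive"` mode every subset of `m` candidate levels is
#' re-evaluated at step `m`, so earlier breakpoint positions can move. The
#' best proposal is accepted only if it improves the composite
#' log-likelihood by at least `threshold` (default 2.0, the conventional
#' one-extra-parameter information-criterion cost); otherwise the current
#' model is returned. Ties are broken towards the smallest (most ancient)
#' level. The search is deterministic.
#'
#' @param x an [sfs] object.
#' @param u mutation rate per site per generation.
#' @param threshold minimum log-likelihood gain to accept a breakpoint.
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param max_breakpoints cap on the number of breakpoints; defaults to
#'   `n - 2` for greedy search and 3 for exhaustive search (whose cost
#'   grows combinatorially).
#' @param exclude classes to exclude from the likelihood.
#' @param include_monomorphic see [composite_log_likelihood()].
#' @param seed unused (the search is deterministic); accepted so callers
#'   can treat all fitting entry points uniformly.
#' @return An `"sfs_fit"` object, with an additional `trace` data.frame
#'   recording the accepted models' breakpoint counts and log-likelihoods.
#' @export
stepwise_fit <- function(x, u, threshold = 2,
                         mode = c("greedy", "exhaustive"),
                         max_breakpoints = NULL, exclude = NULL,
                         include_monomorphic = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "sfs"))
  n <- x$n
  if (is.null(max_breakpoints))
    max_breakpoints <- if (mode == "greedy") n - 2L else min(n - 2L, 3L)
  if (max_breakpoints > n - 2L) stop("max_breakpoints must be <= n - 2")
  candidates <- if (n >= 3L) 2:(n - 1L) else integer()
  cur <- fit_fixed_breakpoints(x, integer(), u, exclude = exclude,
                               include_monomorphic = include_monomorphic)
  trace <- data.frame(n_breakpoints = 0L,
                      log_likelihood = cur$log_likelihood)
  m <- 0L
  while (m < max_breakpoints) {
    m <- m + 1L
    proposals <- if (mode == "greedy") {
      lapply(setdiff(candidates, cur$model$breakpoints), function(b)
        sort(c(cur$model$breakpoints, b), decreasing = TRUE))
    } else {
      sets <- utils::combn(candidates, m, simplify = FALSE)
      lapply(sets, function(s) sort(s, decreasing = TRUE))
    }
    best <- NULL
    for (bp in proposals) {            # ascending order: ties keep the
      fit <- fit_fixed_breakpoints(    # smallest (most ancient) level
        x, bp, u, exclude = exclude,
        include_monomorphic = include_monomorphic)
      if (!fit$converged) next
      if (is.null(best) || fit$log_likelihood > best$log_likelihood)
        best <- fit
    }
    if (is.null(best) ||
        best$log_likelihood - cur$log_likelihood < threshold) break
    cur <- best
    trace <- rbind(trace,
                   data.frame(n_breakpoints = m,
                              log_likelihood = cur$log_likelihood))
  }
  cur$trace <- trace
  cur
}
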