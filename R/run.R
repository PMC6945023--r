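# High-level operations behind the command-line front end (exec/sfstep).
# Each writes a TSV result plus a JSON sidecar recording settings and
# seed, so every run is reproducible from its sidecar alone.

#' Evaluate a step-function history on a time grid
#'
#' Histories are right-continuous step functions given as
#' `(start_generations, Ne)` rows. Before its first start time a history
#' contributes its first value; beyond its last step, its last value.
#'
#' @param steps data.frame with columns `start_generations`, `Ne`.
#' @param times numeric vector of evaluation times (generations).
#' @return Numeric vector of Ne values at `times`.
#' @export
eval_steps <- function(steps, times) {
  i <- findInterval(times, steps$start_generations)
  steps$Ne[pmax(i, 1L)]
}

#' Logarithmic time grid spanning a set of histories
#'
#' @param histories list of step data.frames.
#' @param points number of grid points.
#' @param probs quantile range of all positive step times used as grid
#'   end points.
#' @return Increasing numeric vector of times.
#' @export
make_time_grid <- function(histories, points = 200L,
                           probs = c(0.01, 0.99)) {
  times <- unlist(lapply(histories, function(h) h$start_generations))
  times <- times[times > 0]
  if (!length(times)) return(seq(0, 1, length.out = points))
  rng <- stats::quantile(times, probs, names = FALSE)
  if (rng[1] <= 0 || rng[1] == rng[2])
    rng <- range(times) + c(0, 1)
  exp(seq(log(rng[1]), log(rng[2]), length.out = points))
}

#' Fit a stepwise history and write its report
#'
#' Runs [stepwise_fit()] on an SFS (object or file) and writes the step
#' function as TSV (`<out>.tsv`: `step_start_generations`, `Ne`) with a
#' JSON sidecar (`<out>.json`: likelihood trace, breakpoints, settings).
#'
#' @param x an [sfs] object or path to an SFS file.
#' @param u mutation rate per site per generation.
#' @param out output path prefix; `NULL` skips writing.
#' @param ... passed to [stepwise_fit()].
#' @return The `"sfs_fit"` object, invisibly when writing.
#' @export
run_fit <- function(x, u, out = NULL, ...) {
  if (is.character(x)) x <- read_sfs(x)
  fit <- stepwise_fit(x, u, ...)
  if (!is.null(out)) {
    utils::write.table(
      data.frame(step_start_generations = fit$steps$start_generations,
                 Ne = fit$steps$Ne),
      paste0(out, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar <- list(subcommand = "fit", n = x$n, L = x$L,
                    folded = x$folded, u = u,
                    excluded = as.list(fit$excluded),
                    breakpoints = as.list(fit$model$breakpoints),
                    group_sizes = as.list(fit$model$group_sizes),
                    log_likelihood = fit$log_likelihood,
                    trace = fit$trace, converged = fit$converged,
                    settings = list(...))
    jsonlite::write_json(sidecar, paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}

#' Bootstrap confidence bands for the fitted history
#'
#' Resamples the SFS ([bootstrap_sfs()]), refits each replicate with
#' [stepwise_fit()], evaluates every fitted step function on a common
#' logarithmic time grid, and returns the pointwise mean, median and
#' requested quantiles. Replicates whose optimisation fails to converge
#' are dropped and counted.
#'
#' @param x an [sfs] object or path to an SFS file.
#' @param u mutation rate per site per generation.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param quantiles probabilities for the pointwise bands.
#' @param grid optional explicit time grid; default log-spaced between
#'   the 1st and 99th percentile of all replicate step times, 200 points.
#' @param grid_points grid size when `grid` is `NULL`.
#' @param seed integer seed (resampling is reproducible given it).
#' @param out output path prefix; `NULL` skips writing.
#' @param ... passed to [stepwise_fit()].
#' @return List with `band` (data.frame: `time`, `mean`, plus one column
#'   per quantile), `fits` (the replicate fits), `n_dropped`.
#' @export
run_bootstrap <- function(x, u, replicates, quantiles = c(0.05, 0.5, 0.95),
                          grid = NULL, grid_points = 200L, seed = NULL,
                          out = NULL, ...) {
  if (is.character(x)) x <- read_sfs(x)
  if (replicates < 1) stop("replicates must be >= 1")
  reps <- bootstrap_sfs(x, replicates, seed = seed)
  fits <- lapply(reps, function(b) stepwise_fit(b, u, ...))
  keep <- vapply(fits, function(f) f$converged, logical(1))
  n_dropped <- sum(!keep)
  fits <- fits[keep]
  if (!length(fits)) stop("no bootstrap replicate converged")
  histories <- lapply(fits, `[[`, "steps")
  if (is.null(grid)) grid <- make_time_grid(histories, grid_points)
  vals <- vapply(histories, eval_steps, numeric(length(grid)),
                 times = grid)
  vals <- matrix(vals, nrow = length(grid))
  qs <- t(apply(vals, 1, stats::quantile, probs = quantiles,
                names = FALSE))
  band <- data.frame(time = grid, mean = rowMeans(vals))
  for (j in seq_along(quantiles))
    band[[sprintf("q%g", 100 * quantiles[j])]] <- qs[, j]
  if (!is.null(out)) {
    utils::write.table(band, paste0(out, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subcommand = "bootstrap", n = x$n, L = x$L, folded = x$folded,
           u = u, replicates = replicates, seed = seed,
           quantiles = quantiles, n_dropped = n_dropped,
           settings = list(...)),
      paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  list(band = band, fits = fits, n_dropped = n_dropped)
}

#' Average several step-function histories on a common grid
#'
#' Used to combine median histories inferred from independent spectra of
#' the same population (e.g. different sample-size partitions): each
#' history is evaluated on the grid (step-function convention of
#' [eval_steps()]) and the pointwise mean and standard error across
#' histories are returned, optionally weighted.
#'
#' @param histories list of step data.frames
#'   (`start_generations`/`Ne`), or of `"sfs_fit"` objects.
#' @param grid numeric time grid; default from [make_time_grid()].
#' @param weights optional non-negative weights, one per history
#'   (default unweighted).
#' @return A data.frame with columns `time`, `mean`, `se`.
#' @export
aggregate_histories <- function(histories, grid = NULL, weights = NULL) {
  if (!length(histories)) stop("need at least one history")
  histories <- lapply(histories, function(h)
    if (inherits(h, "sfs_fit")) h$steps else h)
  if (is.null(grid)) grid <- make_time_grid(histories)
  m <- length(histories)
  vals <- vapply(histories, eval_steps, numeric(length(grid)),
                 times = grid)
  vals <- matrix(vals, nrow = length(grid))
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative, one per history")
  w <- weights / sum(weights)
  mu <- as.vector(vals %*% w)
  if (m > 1) {
    dev2 <- (vals - mu)^2
    se <- sqrt(as.vector(dev2 %*% w) * m / (m - 1)) / sqrt(m)
  } else se <- rep(0, length(grid))
  data.frame(time = grid, mean = mu, se = se)
}

#' Allele age and experienced-Ne report for a demography
#'
#' Wraps [allele_class_summary()] over a fitted or supplied demography
#' and optionally writes the TSV report (`class`, `pd`, `mean_age`,
#' `sd_age`, `mean_experienced_ne`).
#'
#' @param dem a [demography], [breakpoint_model] or `"sfs_fit"` object.
#' @param u mutation rate per site per generation.
#' @param L number of surveyed sites.
#' @param folded report folded (minor-allele) classes?
#' @param out output path prefix; `NULL` skips writing.
#' @return The report data.frame.
#' @export
run_ages <- function(dem, u, L, folded = FALSE, out = NULL) {
  if (inherits(dem, "sfs_fit")) dem <- dem$demography
  if (inherits(dem, "breakpoint_model")) dem <- expand_model(dem)
  stopifnot(inherits(dem, "demography"))
  report <- allele_class_summary(dem, u, L, folded = folded)
  if (!is.null(out)) {
    utils::write.table(report, paste0(out, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subcommand = "ages", n = dem$n, u = u, L = L, folded = folded),
      paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
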