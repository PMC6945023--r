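#' Construct a site-frequency spectrum object
#'
#' A site-frequency spectrum (SFS) summarises polymorphism in a sample of
#' `n` haploid genomes surveyed at `L` nucleotide sites. In the unfolded
#' form, `counts[r]` is the number of sites carrying `r` copies of the
#' derived allele (`r = 1..n-1`); in the folded form, `counts[r]` is the
#' number of sites whose minor allele has `r` copies (`r = 1..floor(n/2)`).
#' Monomorphic sites are never stored: their count is `L - sum(counts)`.
#'
#' @param counts vector of per-class site counts (class 1 first); integers
#'   for observed data, but exact expected spectra (real-valued) are also
#'   accepted, e.g. for noiseless inversion checks.
#' @param n number of sampled haploid genomes (>= 2).
#' @param L total number of sites surveyed (monomorphic + polymorphic).
#' @param folded logical; is `counts` a folded (minor-allele) spectrum?
#' @param excluded integer vector of class indices to omit from likelihood
#'   computations (e.g. singletons suspected of sequencing error). Excluded
#'   classes stay in the object so folding and bootstrapping remain exact.
#' @return An object of class `"sfs"`.
#' @examples
#' sfs(c(40, 20, 13), n = 4, L = 1e6)
#' @export
sfs <- function(counts, n, L, folded = FALSE, excluded = integer()) {
  n <- as.integer(n)
  L <- as.numeric(L)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("n must be a single integer >= 2")
  if (length(L) != 1L || is.na(L) || L < 0)
    stop("L must be a single non-negative number")
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative numbers")
  want <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != want)
    stop(sprintf("expected %d classes for %s SFS with n = %d, got %d",
                 want, if (folded) "a folded" else "an unfolded", n,
                 length(counts)))
  if (sum(counts) > L)
    stop("sum of polymorphic counts exceeds L")
  excluded <- sort(unique(as.integer(excluded)))
  if (length(excluded) && (any(excluded < 1L) || any(excluded > want)))
    stop("excluded class index out of range")
  structure(list(n = n, L = L, counts = counts, folded = isTRUE(folded),
                 excluded = excluded),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s site-frequency spectrum: n = %d, L = %s\n",
              if (x$folded) "Folded" else "Unfolded", x$n,
              format(x$L, big.mark = ",")))
  cat(sprintf("  polymorphic sites S = %s over %d classes\n",
              format(sum(x$counts), big.mark = ","), length(x$counts)))
  if (length(x$excluded))
    cat("  excluded classes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Read a site-frequency spectrum from a text file
#'
#' The file dialect is minimal: header lines `#n <int>`, `#L <int>`,
#' `#folded <0|1>` (any order, before the data), then one line per class
#' `r<TAB>count` (any whitespace accepted) with `r` strictly increasing.
#' Missing classes are treated as zero. Other lines starting with `#` are
#' comments.
#'
#' @param path path to an SFS text file.
#' @return An [sfs] object.
#' @seealso [write_sfs()]
#' @export
read_sfs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- NA_integer_; L <- NA_real_; folded <- FALSE
  rs <- integer(); cs <- numeric()
  last_r <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
      if (length(kv) >= 2L && kv[1] %in% c("n", "L", "folded")) {
        val <- suppressWarnings(as.numeric(kv[2]))
        if (is.na(val))
          stop(sprintf("line %d: bad header value in '%s'", i, ln))
        if (kv[1] == "n") n <- as.integer(val)
        if (kv[1] == "L") L <- val
        if (kv[1] == "folded") folded <- val != 0
      }
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 2L)
      stop(sprintf("line %d: expected 'class count', got '%s'", i, ln))
    r <- suppressWarnings(as.integer(f[1]))
    ct <- suppressWarnings(as.numeric(f[2]))
    if (is.na(r) || is.na(ct))
      stop(sprintf("line %d: malformed entry '%s'", i, ln))
    if (ct < 0)
      stop(sprintf("line %d: negative count '%s'", i, ln))
    if (r <= last_r)
      stop(sprintf("line %d: class index %d not strictly increasing", i, r))
    last_r <- r
    rs <- c(rs, r); cs <- c(cs, ct)
  }
  if (is.na(n)) stop("missing '#n' header")
  if (is.na(L)) stop("missing '#L' header")
  nclass <- if (folded) n %/% 2L else n - 1L
  if (length(rs) && max(rs) > nclass)
    stop(sprintf("class index %d out of range for n = %d (%s)",
                 max(rs), n, if (folded) "folded" else "unfolded"))
  counts <- numeric(nclass)
  counts[rs] <- cs
  sfs(counts, n = n, L = L, folded = folded)
}

#' Write a site-frequency spectrum to a text file
#'
#' Emits the dialect read by [read_sfs()]; the round trip is exact.
#'
#' @param x an [sfs] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n %d", x$n),
               sprintf("#L %s", format(x$L, scientific = FALSE)),
               sprintf("#folded %d", as.integer(x$folded)),
               sprintf("%d\t%s", seq_along(x$counts),
                       format(x$counts, scientific = FALSE, trim = TRUE))),
             con)
  invisible(path)
}

#' Fold an unfolded site-frequency spectrum
#'
#' Collapses derived-allele classes into minor-allele classes:
#' `F_r = G_r + G_{n-r}` for `r < n/2`, and `F_{n/2} = G_{n/2}` when `n`
#' is even. `n` and `L` are unchanged; excluded classes are dropped from
#' the folded object (their indexing does not carry over).
#'
#' @param x an unfolded [sfs] object.
#' @return A folded [sfs] object with the same total polymorphic count.
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) stop("SFS is already folded")
  n <- x$n
  m <- n %/% 2L
  f <- numeric(m)
  for (r in seq_len(m)) {
    f[r] <- if (2L * r == n) x$counts[r] else x$counts[r] + x$counts[n - r]
  }
  sfs(f, n = n, L = x$L, folded = TRUE)
}

#' Bootstrap resampling of a site-frequency spectrum
#'
#' Resamples the `L` surveyed sites with replacement: each replicate draws
#' site counts from a multinomial over the classes 0 (monomorphic,
#' probability `(L - S)/L`) and `1..n-1` (probability `G_r / L`), so the
#' total `L` is conserved exactly in every replicate.
#'
#' @param x an [sfs] object.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; replicates are reproducible given the seed.
#' @return A list of `replicates` [sfs] objects.
#' @export
bootstrap_sfs <- function(x, replicates, seed = NULL) {
  stopifnot(inherits(x, "sfs"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (x$L == 0) stop("cannot bootstrap an SFS with L = 0")
  if (!is.null(seed)) set.seed(seed)
  p <- c(x$L - sum(x$counts), x$counts) / x$L
  draws <- stats::rmultinom(replicates, size = x$L, prob = p)
  lapply(seq_len(replicates), function(j)
    sfs(draws[-1L, j], n = x$n, L = x$L, folded = x$folded,
        excluded = x$excluded))
}

#' Watterson's estimator from a site-frequency spectrum
#'
#' The number of segregating sites `S = sum(counts)` yields the classical
#' estimate `theta_W = S / (L * a)` with `a = sum(1/i, i = 1..n-1)`, and,
#' given a per-site per-generation mutation rate `u`, the constant-size
#' effective population size `Ne_hat = theta_W / (4u)` (diploid scaling).
#' This is also the starting point of the stepwise fit.
#'
#' @param x an [sfs] object.
#' @param u optional mutation rate per site per generation.
#' @return A list with `S`, `theta_per_site`, and (when `u` is given)
#'   `Ne_hat`.
#' @export
watterson_theta <- function(x, u = NULL) {
  stopifnot(inherits(x, "sfs"))
  S <- sum(x$counts)
  a <- sum(1 / seq_len(x$n - 1L))
  theta <- if (x$L > 0) S / (x$L * a) else 0
  out <- list(S = S, theta_per_site = theta)
  if (!is.null(u)) out$Ne_hat <- theta / (4 * u)
  out
}

# Harmonic number a_n = sum_{i=1}^{n-1} 1/i, used throughout.
harmonic <- function(n) sum(1 / seq_len(n - 1L))
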