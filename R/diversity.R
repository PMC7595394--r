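## Hill-number diversity, sample-size-based rarefaction/extrapolation with
## bootstrap intervals, and Shannon landscape diversity with the non-crop
## transform.

#' Hill numbers of order 0, 1, 2
#'
#' Effective species numbers from an abundance vector: `q = 0` is species
#' richness S, `q = 1` the exponential of Shannon entropy `exp(H')`, and
#' `q = 2` the inverse Simpson concentration `1 / sum(p_i^2)`.  Sensitivity
#' to rare species decreases with `q`: richness is driven by uncommon
#' species, inverse Simpson by the common ones.
#'
#' @param counts non-negative integer abundance vector (zeros allowed).
#' @param q diversity order, one of 0, 1, 2.
#' @return effective number of species.
#' @examples
#' hill_number(c(5, 5), 1)      # 2 (two equally common species)
#' hill_number(c(9, 1), 2)      # 1.2195
#' @export
hill_number <- function(counts, q) {
  check_abundance(counts)
  if (!q %in% c(0, 1, 2)) stop("q must be 0, 1 or 2")
  p <- counts[counts > 0] / sum(counts)
  switch(as.character(q),
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2))
}

check_abundance <- function(counts) {
  if (length(counts) == 0 || any(counts < 0) || any(counts %% 1 != 0))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("abundance vector is all zero")
  invisible(TRUE)
}

#' Exact rarefied richness
#'
#' Expected number of species in a random subsample of `m` individuals drawn
#' without replacement, by the hypergeometric closed form
#' `S_obs - sum_i C(n - X_i, m) / C(n, m)`.
#'
#' @param counts non-negative integer abundance vector.
#' @param m subsample size, `1 <= m <= n`.
#' @return expected richness (numeric).
#' @examples
#' rarefy_richness(c(2, 2), 2)  # 5/3
#' @export
rarefy_richness <- function(counts, m) {
  check_abundance(counts)
  n <- sum(counts)
  if (m < 1 || m %% 1 != 0) stop("m must be a positive integer")
  if (m > n) stop("m exceeds n; use rarefaction_curve() for extrapolation")
  x <- counts[counts > 0]
  # lchoose for numerical stability at large n
  length(x) - sum(exp(lchoose(n - x, m) - lchoose(n, m)))
}

# Chao1-style extrapolated richness at n + mstar additional individuals
extrapolate_richness <- function(counts, mstar) {
  x <- counts[counts > 0]
  n <- sum(x)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(rep(s_obs, length(mstar)))
  f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
  if (f0 == 0) return(rep(s_obs, length(mstar)))
  s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
}

# multivariate-hypergeometric subsample of a count vector, returned as counts
subsample_counts <- function(counts, m) {
  n <- sum(counts)
  idx <- sample.int(n, m)
  cuts <- cumsum(counts)
  tabulate(findInterval(idx - 1L, c(0L, cuts), rightmost.closed = FALSE),
           nbins = length(counts))
}

# Monte-Carlo expectation of a Hill number at subsample size m
mc_hill <- function(counts, q, m, n_sub) {
  mean(vapply(seq_len(n_sub), function(i) {
    hill_number(subsample_counts(counts, m), q)
  }, numeric(1)))
}

#' Sample-size-based rarefaction and extrapolation curve
#'
#' Diversity of order `q` as a function of sample size `m`, with 95%
#' bootstrap confidence bounds.  Interpolation (`m <= n`) uses the exact
#' hypergeometric closed form for `q = 0` and a seeded Monte-Carlo
#' subsampling expectation for `q = 1, 2`; extrapolation (`m > n`) uses a
#' Chao1-augmented asymptote approach for `q = 0` and holds the asymptotic
#' plug-in estimate for `q = 1, 2`.  Extrapolation beyond `2n` is refused
#' with a warning (long-range extrapolation is unreliable).  Confidence
#' bounds are `estimate +/- 1.96 * SE` with the SE taken over bootstrap
#' resamples of individuals (multinomial), so the interval always contains
#' the point estimate.
#'
#' @param counts non-negative integer abundance vector.
#' @param q diversity order (0, 1 or 2).
#' @param m_grid increasing vector of sample sizes; default 20 sizes from 1
#'   to `2n`, always including the observed `n`.
#' @param n_boot bootstrap resamples for the confidence bounds.
#' @param seed integer seed controlling subsampling and bootstrap.
#' @param n_sub Monte-Carlo subsamples per interpolated point for
#'   `q = 1, 2`.
#' @return data frame of class `rarefaction_curve` with columns
#'   `q, m, kind` (`interpolated`/`observed`/`extrapolated`),
#'   `estimate, lo95, hi95`.
#' @export
rarefaction_curve <- function(counts, q, m_grid = NULL, n_boot = 100,
                              seed = 1, n_sub = 100) {
  check_abundance(counts)
  if (!q %in% c(0, 1, 2)) stop("q must be 0, 1 or 2")
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- sum(counts)
  if (is.null(m_grid)) {
    m_grid <- unique(sort(c(round(seq(1, 2 * n, length.out = 20)), n)))
  } else {
    if (length(m_grid) == 0) stop("m_grid is empty")
    if (any(m_grid < 1)) stop("m_grid must be positive")
    m_grid <- unique(sort(c(round(m_grid), n)))
  }
  if (any(m_grid > 2 * n)) {
    warning("refusing extrapolation beyond 2n; dropping ",
            sum(m_grid > 2 * n), " grid point(s)")
    m_grid <- m_grid[m_grid <= 2 * n]
  }
  set.seed(as.integer(seed) %% 2147483647L)
  est_curve <- function(cts) {
    nn <- sum(cts)
    vapply(m_grid, function(m) {
      if (m <= nn) {
        if (q == 0) rarefy_richness(cts, m)
        else if (m == nn) hill_number(cts, q)
        else mc_hill(cts, q, m, n_sub)
      } else {
        if (q == 0) extrapolate_richness(cts, m - nn)
        else hill_number(cts, q)
      }
    }, numeric(1))
  }
  est <- est_curve(counts)
  p <- counts / n
  boot <- matrix(NA_real_, n_boot, length(m_grid))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- est_curve(as.integer(rmultinom(1, n, p)))
  }
  se <- apply(boot, 2, sd)
  out <- data.frame(q = q, m = m_grid,
                    kind = ifelse(m_grid < n, "interpolated",
                                  ifelse(m_grid == n, "observed",
                                         "extrapolated")),
                    estimate = est,
                    lo95 = pmax(0, est - 1.96 * se),
                    hi95 = est + 1.96 * se)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "observed") <- hill_number(counts, q)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("Rarefaction/extrapolation curve, q = ", x$q[1],
      " (n = ", attr(x, "n"), ", observed qD = ",
      round(attr(x, "observed"), 3), ")\n", sep = "")
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, main = NULL, ...) {
  plot(x$m, x$estimate, type = "n",
       xlab = "number of individuals", ylab = paste0("qD (q=", x$q[1], ")"),
       ylim = range(c(x$lo95, x$hi95)),
       main = main %||% "Sample-size-based rarefaction/extrapolation")
  polygon(c(x$m, rev(x$m)), c(x$lo95, rev(x$hi95)),
          col = "grey85", border = NA)
  ip <- x$kind != "extrapolated"
  lines(x$m[ip], x$estimate[ip], lty = 1)
  lines(x$m[!ip | x$kind == "observed"], x$estimate[!ip | x$kind == "observed"],
        lty = 3)
  points(x$m[x$kind == "observed"], x$estimate[x$kind == "observed"], pch = 19)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon landscape diversity
#'
#' `H's = -sum(p_i * log(p_i))` over land-cover category proportions within
#' a 3-km radius; zero-proportion categories contribute nothing.
#'
#' @param proportions numeric vector of category proportions summing to 1
#'   (tolerance 1e-9), or a [land_cover()] table restricted to one field.
#' @return Shannon index (>= 0).
#' @examples
#' shannon_landscape_diversity(c(0.5, 0.3, 0.2))  # 1.0297
#' @export
shannon_landscape_diversity <- function(proportions) {
  p <- landcover_props(proportions)
  if (abs(sum(p) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Non-crop proportion of a land-cover profile
#'
#' Summed proportion of categories flagged non-crop; the landscape-complexity
#' axis on which habitat-management benefit is interpreted (8-69% across the
#' study fields).
#'
#' @param proportions numeric vector of proportions, or a [land_cover()]
#'   table restricted to one field (in which case `noncrop` is taken from
#'   the table).
#' @param noncrop logical flags, parallel to `proportions`.
#' @return proportion in \[0, 1\].
#' @export
noncrop_proportion <- function(proportions, noncrop = NULL) {
  if (is.data.frame(proportions) && is.null(noncrop))
    noncrop <- proportions$noncrop
  p <- landcover_props(proportions)
  if (is.null(noncrop)) stop("noncrop flags are required")
  if (length(noncrop) != length(p)) stop("noncrop flags do not match profile")
  sum(p[as.logical(noncrop)])
}

landcover_props <- function(x) {
  if (is.data.frame(x)) {
    if (length(unique(x$field)) > 1)
      stop("profile spans multiple fields; subset to one field")
    x$proportion
  } else as.numeric(x)
}

#' Per-field landscape summary
#'
#' @param lc a [land_cover()] table.
#' @return data frame with one row per field: Shannon diversity `H` and
#'   `noncrop` proportion.
#' @export
landcover_summary <- function(lc) {
  fields <- unique(lc$field)
  out <- data.frame(
    field = fields,
    H = vapply(fields, function(f)
      shannon_landscape_diversity(lc$proportion[lc$field == f]), numeric(1)),
    noncrop = vapply(fields, function(f)
      noncrop_proportion(lc$proportion[lc$field == f],
                         lc$noncrop[lc$field == f]), numeric(1)))
  rownames(out) <- NULL
  out
}
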