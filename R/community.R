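## Common/uncommon partitioning, Bray-Curtis distances, the multi-response
## permutation procedure (MRPP), and PCoA-based multivariate dispersion
## (the beta-dispersion reading of community evenness).

#' Partition bee taxa into common and uncommon classes
#'
#' A taxon is common iff its study-wide relative abundance (all sites,
#' treatments, years and months pooled) strictly exceeds `threshold`
#' (default the ~1% boundary).  The pooled *Dialictus* taxon can mask other
#' common species, so two variants exist: `exclude_pooled` drops it from the
#' candidate set (the "8 common" reading) while `include_pooled` classifies
#' it like any other taxon (the "9 common" reading).  The relative-abundance
#' denominator is always the whole community, pooled taxon included.
#'
#' @param bees a bee [survey_table()].
#' @param registry the matching [taxon_registry()].
#' @param threshold commonness boundary on relative abundance (default 0.01).
#' @param mode `"exclude_pooled"` or `"include_pooled"`.
#' @return data frame of class `commonness_partition` with columns
#'   `taxon, total, rel_abund, class`.
#' @export
classify_commonness <- function(bees, registry, threshold = 0.01,
                                mode = c("include_pooled", "exclude_pooled")) {
  mode <- match.arg(mode)
  if (nrow(bees) == 0) stop("empty survey table")
  tot <- tapply(bees$value, bees$taxon, sum)
  grand <- sum(tot)
  if (grand <= 0) stop("total abundance must be positive")
  out <- data.frame(taxon = names(tot), total = as.numeric(tot),
                    rel_abund = as.numeric(tot) / grand)
  out$class <- ifelse(out$rel_abund > threshold, "common", "uncommon")
  pooled_id <- registry$taxon[registry$role == "bee" & registry$pooled]
  if (mode == "exclude_pooled" && length(pooled_id))
    out <- out[!out$taxon %in% pooled_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  class(out) <- c("commonness_partition", "data.frame")
  out
}

#' Bray-Curtis distance matrix among sampling units
#'
#' Builds the unit-by-taxon community matrix (absences as zeros) and returns
#' pairwise Bray-Curtis dissimilarities `sum|x - y| / sum(x + y)`.
#' With `margin = "species"` the matrix is transposed first, giving
#' distances between species profiles across sampling units.
#'
#' @param bees a bee [survey_table()].
#' @param unit_keys key columns defining a sampling unit (default
#'   site x treatment x year x month, i.e. one trapping event).
#' @param taxa optional taxon subset (e.g. a commonness class).
#' @param margin `"units"` (default) or `"species"`.
#' @return a `dist` object with `metric` attribute `"bray"`.
#' @export
bray_curtis_matrix <- function(bees,
                               unit_keys = c("site", "treatment", "year", "month"),
                               taxa = NULL, margin = c("units", "species")) {
  margin <- match.arg(margin)
  mat <- community_matrix(bees, unit_keys, taxa)
  if (margin == "species") mat <- t(mat)
  if (nrow(mat) < 2) stop("need at least 2 units for a distance matrix")
  zero <- rownames(mat)[rowSums(mat) == 0]
  if (length(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero units: ",
         paste(zero, collapse = ", "))
  d <- vegan::vegdist(mat, method = "bray")
  attr(d, "metric") <- "bray"
  d
}

#' Multi-response permutation procedure
#'
#' Tests whether within-group dissimilarities are smaller than expected
#' under random relabeling.  The observed statistic is the weighted
#' within-group mean distance `delta = sum_g (n_g / N) * mean d(within g)`.
#' Group labels are permuted (group sizes fixed); the standardized effect
#' `T = (delta_obs - mean delta_perm) / sd delta_perm`, the chance-corrected
#' agreement `A = 1 - delta_obs / mean delta_perm`, and the permutation
#' p-value `p = (1 + #\{delta_perm <= delta_obs\}) / (n_perm + 1)` are
#' reported.  With `exhaustive = TRUE` every distinct relabeling is
#' enumerated instead and `p = #\{delta <= delta_obs\} / #relabelings`
#' (the observed arrangement included).
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups group labels, one per unit; every group needs >= 2 units.
#' @param n_perm number of Monte-Carlo permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all distinct relabelings (feasible for small
#'   N only).
#' @return object of class `mrpp_result` with elements `delta, T, A, p,
#'   n_perm, seed, exhaustive`.
#' @export
mrpp <- function(d, groups, n_perm = 9999, seed = 1, exhaustive = FALSE) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("groups must have one label per unit")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 units, got size ",
                           min(sizes), " for group '",
                           names(sizes)[which.min(sizes)], "'")
  delta_of <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      s <- s + length(i) / length(g) * mean(dm[i, i][lower.tri(dm[i, i])])
    }
    s
  }
  delta_obs <- delta_of(groups)
  if (exhaustive) {
    perms <- multiset_permutations(groups)
    deltas <- vapply(perms, delta_of, numeric(1))
    p <- sum(deltas <= delta_obs + 1e-12) / length(deltas)
    e_delta <- mean(deltas)
    s_delta <- sd(deltas)
    n_used <- length(deltas)
  } else {
    set.seed(as.integer(seed) %% 2147483647L)
    deltas <- vapply(seq_len(n_perm), function(i) delta_of(sample(groups)),
                     numeric(1))
    p <- (1 + sum(deltas <= delta_obs)) / (n_perm + 1)
    e_delta <- mean(deltas)
    s_delta <- sd(deltas)
    n_used <- n_perm
  }
  structure(list(delta = delta_obs,
                 T = (delta_obs - e_delta) / s_delta,
                 A = 1 - delta_obs / e_delta,
                 p = p, n_perm = n_used, seed = as.integer(seed),
                 exhaustive = exhaustive, expected_delta = e_delta),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("Multi-response permutation procedure",
      if (x$exhaustive) " (exhaustive)" else "", "\n", sep = "")
  cat(sprintf("  delta = %.4f (expected %.4f)\n", x$delta, x$expected_delta))
  cat(sprintf("  T = %.3f, A = %.4f, p = %.4g  (%d %s)\n", x$T, x$A, x$p,
              x$n_perm,
              if (x$exhaustive) "relabelings" else "permutations"))
  invisible(x)
}

# all distinct permutations of a label multiset (small N only)
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n > 10) stop("exhaustive enumeration is limited to 10 units")
  rec <- function(remaining) {
    if (length(remaining) == 1) return(list(remaining))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(labels)
}

#' Principal coordinates analysis
#'
#' Gower-centered double-centering eigendecomposition of a distance matrix.
#' All axes are retained: real coordinates for positive eigenvalues and,
#' when the distance is non-Euclidean (as Bray-Curtis generally is),
#' imaginary-axis coordinates for negative eigenvalues, scaled by
#' `sqrt(|lambda|)`.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @return object of class `pcoa_result`: `points` (real axes),
#'   `imaginary` (axes for negative eigenvalues, possibly 0 columns),
#'   `eig` (all eigenvalues, non-increasing).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  ipts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), length(neg))
  rownames(pts) <- rownames(ipts) <- rownames(dm)
  structure(list(points = pts, imaginary = ipts, eig = e$values),
            class = "pcoa_result")
}

#' Multivariate dispersion (beta dispersion) between groups
#'
#' Embeds the units by [pcoa()], computes each unit's distance to its own
#' group centroid (squared imaginary-axis contributions are subtracted, the
#' standard correction for non-Euclidean distances), and compares group mean
#' distances by one-way ANOVA.  Used as a proxy for community evenness:
#' lower dispersion means individuals are spread more evenly across species
#' among sampling units.
#'
#' @param d a `dist` or symmetric distance matrix among sampling units.
#' @param groups group labels (>= 2 groups of >= 2 units).
#' @param n_perm optional number of label permutations for a permutation
#'   p-value on F (0 = parametric only).
#' @param seed seed for the permutation test.
#' @return object of class `dispersion_result`: `distances` (per unit),
#'   `groups`, `means` (per-group mean distance), `F`, `p` (parametric),
#'   `p_perm` (or `NA`), `eig`.
#' @export
multivariate_dispersion <- function(d, groups, n_perm = 0, seed = 1) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("groups must have one label per unit")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 groups with >= 2 units each")
  emb <- pcoa(dm)
  zdist <- numeric(length(groups))
  for (lev in unique(groups)) {
    i <- which(groups == lev)
    c_re <- colMeans(emb$points[i, , drop = FALSE])
    c_im <- colMeans(emb$imaginary[i, , drop = FALSE])
    d2 <- rowSums(sweep(emb$points[i, , drop = FALSE], 2, c_re)^2) -
      rowSums(sweep(emb$imaginary[i, , drop = FALSE], 2, c_im)^2)
    zdist[i] <- sqrt(pmax(d2, 0))
  }
  if (all(tapply(zdist, groups, sd) == 0))
    stop("zero-variance distances in every group; F undefined")
  fit <- anova(lm(zdist ~ factor(groups)))
  f_obs <- fit[["F value"]][1]
  p_par <- fit[["Pr(>F)"]][1]
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed) %% 2147483647L)
    f_of <- function(g) anova(lm(zdist ~ factor(g)))[["F value"]][1]
    fs <- vapply(seq_len(n_perm), function(i) f_of(sample(groups)),
                 numeric(1))
    p_perm <- (1 + sum(fs >= f_obs)) / (n_perm + 1)
  }
  structure(list(distances = setNames(zdist, rownames(dm)), groups = groups,
                 means = tapply(zdist, groups, mean),
                 F = f_obs, p = p_par, p_perm = p_perm, eig = emb$eig),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion (distances to group centroids)\n")
  cat("  group means:",
      paste(sprintf("%s = %.4f", names(x$means), x$means), collapse = ", "),
      "\n")
  cat(sprintf("  F = %.3f, parametric p = %.4g", x$F, x$p))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}
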