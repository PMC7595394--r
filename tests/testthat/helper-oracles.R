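# Independent brute-force oracles and tiny fixture builders shared across
# the suite.  Oracles are deliberately naive re-derivations, kept separate
# from the implementation paths they check.

# minimal registry: n_bee bees (first one optionally pooled), n_plant plants
# alternating native/exotic across two families
tiny_registry <- function(n_bee = 3, n_plant = 3, pooled_first = FALSE) {
  taxon_registry(data.frame(
    taxon = c(paste0("b", seq_len(n_bee)), paste0("p", seq_len(n_plant))),
    role = rep(c("bee", "plant"), c(n_bee, n_plant)),
    family = c(rep(c("Halictidae", "Apidae"), length.out = n_bee),
               rep(c("Asteraceae", "Fabaceae"), length.out = n_plant)),
    origin = c(rep("not_applicable", n_bee),
               rep(c("native_prairie", "exotic_weedy"), length.out = n_plant)),
    pooled = c(pooled_first, rep(FALSE, n_bee + n_plant - 1))))
}

# long survey rows from a unit x taxon matrix (one site per row label)
survey_from_matrix <- function(mat, registry, treatment = "strip",
                               year = 2016, month = "May") {
  df <- data.frame(site = rownames(mat)[row(mat)],
                   treatment = treatment, year = year, month = month,
                   taxon = colnames(mat)[col(mat)],
                   value = as.numeric(mat))
  survey_table(df[df$value > 0, , drop = FALSE], registry)
}

# naive double-loop Bray-Curtis
bray_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(mat[i, ] - mat[j, ])) / sum(mat[i, ] + mat[j, ])
  d
}

# brute-force MRPP delta for a label assignment
delta_oracle <- function(dm, groups) {
  s <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    tot <- 0; k <- 0
    for (a in seq_along(i)) for (b in seq_along(i)) if (a < b) {
      tot <- tot + dm[i[a], i[b]]; k <- k + 1
    }
    s <- s + length(i) / length(groups) * tot / k
  }
  s
}

# exhaustive-relabeling MRPP: p, mean and sd of the delta distribution
mrpp_exhaustive_oracle <- function(dm, groups) {
  perms <- unique(combinat_perms(groups))
  deltas <- vapply(perms, function(g) delta_oracle(dm, g), numeric(1))
  obs <- delta_oracle(dm, groups)
  list(p = mean(deltas <= obs + 1e-12), mean = mean(deltas),
       sd = sd(deltas), deltas = deltas, obs = obs)
}

combinat_perms <- function(labels) {
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (tail in combinat_perms(rest)) out[[length(out) + 1L]] <- c(u, tail)
  }
  out
}

# brute-force BH step-up on a p-value vector
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# exhaustive expected richness for subsamples of size m (small n only)
rarefy_oracle <- function(counts, m) {
  ind <- rep(seq_along(counts), counts)
  subs <- combn(length(ind), m)
  mean(apply(subs, 2, function(k) length(unique(ind[k]))))
}
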