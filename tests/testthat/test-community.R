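make_abund <- function(values, registry) {
  # one site per taxon occurrence spread over sites to stay key-unique
  df <- data.frame(site = "s1", treatment = "strip", year = 2016,
                   month = "May", taxon = names(values),
                   value = as.numeric(values))
  survey_table(df, registry)
}

test_that("commonness uses a strict study-wide 1% boundary", {
  reg <- tiny_registry(4, 2)
  tab <- make_abund(c(b1 = 500, b2 = 480, b3 = 10, b4 = 10), reg)
  part <- classify_commonness(tab, reg)
  expect_setequal(part$taxon[part$class == "common"], c("b1", "b2"))
  # exactly at the boundary is uncommon (strict >)
  tab2 <- make_abund(c(b1 = 99, b2 = 1), reg)  # b2 at exactly 1%
  part2 <- classify_commonness(tab2, reg)
  expect_identical(part2$class[part2$taxon == "b2"], "uncommon")
  tab3 <- make_abund(c(b1 = 989, b2 = 11), reg)  # 1.1% -> common
  part3 <- classify_commonness(tab3, reg)
  expect_identical(part3$class[part3$taxon == "b2"], "common")
  # scale invariance
  part_k <- classify_commonness(make_abund(c(b1 = 500, b2 = 480, b3 = 10,
                                             b4 = 10) * 7, reg), reg)
  expect_identical(part_k$class, part$class)
  expect_error(classify_commonness(tab[0, ], reg), "empty")
})

test_that("pooled-taxon handling gives the 8- vs 9-common variants", {
  reg <- tiny_registry(10, 2, pooled_first = TRUE)  # b1 is pooled
  vals <- c(2000, rep(150, 8), 10)                  # 9 taxa above 1%
  names(vals) <- paste0("b", 1:10)
  tab <- make_abund(vals, reg)
  with_pool <- classify_commonness(tab, reg, mode = "include_pooled")
  expect_equal(sum(with_pool$class == "common"), 9)
  no_pool <- classify_commonness(tab, reg, mode = "exclude_pooled")
  expect_equal(sum(no_pool$class == "common"), 8)
  expect_false("b1" %in% no_pool$taxon)
  # denominator still includes the pooled taxon in both modes
  expect_equal(no_pool$rel_abund[no_pool$taxon == "b2"],
               150 / sum(vals))
})

test_that("Bray-Curtis distances match hand values and the naive oracle", {
  reg <- tiny_registry(2, 2)
  mat <- rbind(u1 = c(b1 = 1, b2 = 2), u2 = c(b1 = 3, b2 = 0))
  d <- bray_curtis_matrix(survey_from_matrix(mat, reg),
                          unit_keys = "site")
  expect_equal(as.numeric(d), (2 + 2) / 6)
  # identical units -> 0; disjoint supports -> 1
  mat2 <- rbind(u1 = c(b1 = 2, b2 = 0), u2 = c(b1 = 2, b2 = 0),
                u3 = c(b1 = 0, b2 = 5))
  d2 <- as.matrix(bray_curtis_matrix(survey_from_matrix(mat2, reg),
                                     unit_keys = "site"))
  expect_equal(d2["u1", "u2"], 0)
  expect_equal(d2["u1", "u3"], 1)
  set.seed(8)
  mat3 <- matrix(rpois(8 * 5, 3), 8, 5,
                 dimnames = list(paste0("u", 1:8), paste0("b", 1:5)))
  mat3[rowSums(mat3) == 0, 1] <- 1  # no all-zero rows
  reg5 <- tiny_registry(5, 2)
  d3 <- bray_curtis_matrix(survey_from_matrix(mat3, reg5), unit_keys = "site")
  m3 <- as.matrix(d3)[rownames(mat3), rownames(mat3)]
  expect_equal(m3, bray_oracle(mat3), ignore_attr = TRUE, tolerance = 1e-12)
  # all-zero pairs are refused by name
  mat4 <- rbind(u1 = c(b1 = 1, b2 = 1), u2 = c(b1 = 0, b2 = 0),
                u3 = c(b1 = 0, b2 = 0))
  tab4 <- survey_table(data.frame(site = c("u1", "u1", "u2", "u3"),
                                  treatment = "strip", year = 2016,
                                  month = "May",
                                  taxon = c("b1", "b2", "b1", "b1"),
                                  value = c(1, 1, 0, 0)), reg)
  expect_error(bray_curtis_matrix(tab4, unit_keys = "site"),
               "all-zero units: u2, u3")
})

test_that("MRPP matches exhaustive enumeration and a brute-force oracle", {
  # 4 points on a line, groups {0,1} vs {10,11}: p = 1/3 exactly
  dm <- as.matrix(dist(c(0, 1, 10, 11)))
  g <- c("a", "a", "b", "b")
  ex <- mrpp(dm, g, exhaustive = TRUE)
  expect_equal(ex$p, 1 / 3)
  oracle <- mrpp_exhaustive_oracle(dm, g)
  expect_equal(ex$p, oracle$p)
  expect_equal(ex$delta, oracle$obs, tolerance = 1e-12)
  expect_equal(ex$T, (oracle$obs - oracle$mean) / oracle$sd,
               tolerance = 1e-12)
  expect_equal(ex$A, 1 - oracle$obs / oracle$mean, tolerance = 1e-12)
  # Monte-Carlo p within 3 binomial SE of exhaustive p on random fixtures
  set.seed(5)
  for (i in 1:4) {
    n <- sample(6:8, 1)
    pts <- matrix(rnorm(n * 2), n)
    grp <- rep(c("a", "b"), length.out = n)
    if (min(table(grp)) < 2) next
    dmat <- as.matrix(dist(pts))
    ex_p <- mrpp_exhaustive_oracle(dmat, grp)$p
    mc <- mrpp(dmat, grp, n_perm = 2000, seed = i)
    se <- sqrt(ex_p * (1 - ex_p) / 2000)
    expect_lt(abs(mc$p - ex_p), 3 * se + 2 / 2000)
  }
})

test_that("MRPP agrees with the reference implementation and detects structure", {
  set.seed(10)
  mat <- matrix(rpois(12 * 6, 4), 12, 6,
                dimnames = list(paste0("u", 1:12), paste0("s", 1:6)))
  mat[1:6, 1:3] <- mat[1:6, 1:3] + 6  # real group signal
  grp <- rep(c("a", "b"), each = 6)
  d <- vegan::vegdist(mat, "bray")
  mine <- mrpp(d, grp, n_perm = 999, seed = 2)
  ref <- vegan::mrpp(mat, grp, permutations = 999, distance = "bray",
                     weight.type = 1)
  expect_equal(mine$delta, ref$delta, tolerance = 1e-12)
  expect_gt(mine$A, 0)
  expect_lt(mine$p, 0.05)
  # null data: A centred near zero (small-sample bias allowed for)
  set.seed(11)
  anull <- replicate(20, {
    m <- matrix(rpois(16 * 5, 5), 16)
    mrpp(vegan::vegdist(m, "bray"), rep(c("a", "b"), each = 8),
         n_perm = 199, seed = 1)$A
  })
  expect_lt(abs(mean(anull)), 0.05)
  expect_error(mrpp(d, rep("a", 12)), "2 groups")
  expect_error(mrpp(d, c(rep("a", 11), "b")), "at least 2 units")
})

test_that("PCoA reconstructs distances and orders eigenvalues", {
  x <- c(0, 1, 4, 9)
  d <- dist(x)
  p <- pcoa(d)
  expect_true(all(diff(p$eig) <= 1e-9))
  expect_equal(as.matrix(dist(p$points)), as.matrix(d), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(ncol(p$imaginary), 0L)
  # 3-point metric reconstructs via signed squared distances
  dm <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  p3 <- pcoa(dm)
  im2 <- if (ncol(p3$imaginary)) as.matrix(dist(p3$imaginary))^2 else 0
  rec2 <- as.matrix(dist(p3$points))^2 - im2
  expect_equal(sqrt(pmax(rec2, 0)), dm, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("multivariate dispersion matches betadisper and hand ANOVA", {
  set.seed(12)
  mat <- matrix(rpois(14 * 7, 4) + 1, 14, 7,
                dimnames = list(paste0("u", 1:14), paste0("s", 1:7)))
  grp <- rep(c("a", "b"), each = 7)
  d <- vegan::vegdist(mat, "bray")
  mine <- multivariate_dispersion(d, grp)
  ref <- vegan::betadisper(d, grp, type = "centroid")
  expect_equal(as.numeric(mine$distances), as.numeric(ref$distances),
               tolerance = 1e-9)
  expect_equal(mine$F, anova(ref)[["F value"]][1], tolerance = 1e-9)
  # brute-force one-way ANOVA on the distances
  fit <- anova(lm(as.numeric(mine$distances) ~ factor(grp)))
  expect_equal(mine$F, fit[["F value"]][1])
  # translated copies have identical dispersion: group means equal, F = 0
  pts <- rbind(c(0, 0), c(1, 0), c(0, 3), c(4, 4))
  dm <- dist(rbind(pts, pts + 100))
  mir <- multivariate_dispersion(dm, rep(c("a", "b"), each = 4))
  expect_lt(mir$F, 1e-9)
  # invariant to unit reordering
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6, 11, 9, 13, 14, 10, 12)
  mine_p <- multivariate_dispersion(as.matrix(d)[perm, perm], grp[perm])
  expect_equal(sort(round(as.numeric(mine_p$distances), 10)),
               sort(round(as.numeric(mine$distances), 10)))
  expect_equal(mine_p$F, mine$F, tolerance = 1e-9)
})
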