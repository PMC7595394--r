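sim_pair_tables <- function(bee_counts, plant_cover, registry) {
  # one row per event for one bee (b1) and one plant (p1)
  ev <- paste0("s", seq_along(bee_counts))
  bees <- survey_table(data.frame(site = ev, treatment = "strip",
                                  year = 2016, month = "May", taxon = "b1",
                                  value = bee_counts), registry)
  plants <- survey_table(data.frame(site = ev, treatment = "strip",
                                    year = 2016, month = "May", taxon = "p1",
                                    value = plant_cover), registry)
  list(bees = bees, plants = plants)
}

test_that("scalar Pearson screening matches cor.test and flags degeneracy", {
  res <- pearson_r_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$p, 0.2, tolerance = 0.001)
  expect_equal(pearson_r_p(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_r_p(1:3, c(2, 4, 6))$p, 0)
  expect_equal(pearson_r_p(1:3, c(6, 4, 2))$r, -1)
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(length(x))
    res <- pearson_r_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, as.numeric(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
  expect_false(pearson_r_p(c(2, 2, 2), c(1, 2, 3))$defined)
  expect_false(pearson_r_p(c(1, 2), c(3, 4))$defined)
  expect_error(pearson_r_p(1:3, 1:4), "equal length")
})

test_that("network alignment is order-invariant and tracks sample size", {
  reg <- tiny_registry(2, 2)
  tabs <- sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5), reg)
  net <- build_cooccurrence(tabs$bees, tabs$plants, reg)
  expect_equal(net$r["b1", "p1"], 1)           # proportional series
  expect_true(all(net$n == 5))
  expect_false(net$defined["b2", "p2"])        # never observed -> undefined
  # permuted record order changes nothing
  net2 <- build_cooccurrence(tabs$bees[sample(5), ], tabs$plants[c(3, 1, 5, 2, 4), ],
                             reg)
  expect_equal(net2$r, net$r)
  expect_equal(net2$p, net$p)
  # dropping one event reduces every n by one
  net3 <- build_cooccurrence(tabs$bees[tabs$bees$site != "s5", ],
                             tabs$plants[tabs$plants$site != "s5", ], reg)
  expect_true(all(net3$n == 4))
  expect_error(build_cooccurrence(tabs$bees[1:2, ], tabs$plants[1:2, ], reg),
               "fewer than 3 pairing keys")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(as.numeric(bh_adjust(c(0.01, 0.02, 0.04))),
               c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.123), 0.123)             # single p unchanged
  expect_equal(as.numeric(bh_adjust(rep(0.02, 6))), rep(0.02, 6))
  set.seed(6)
  for (n in c(5, 50, 1000)) {
    p <- runif(n)^2
    expect_equal(as.numeric(bh_adjust(p)), bh_oracle(p), tolerance = 1e-14)
  }
  # NA (undefined) cells are excluded from m and stay NA
  p <- matrix(c(0.01, NA, 0.02, 0.04), 2)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2, 1]))
  expect_equal(as.numeric(adj[!is.na(adj)]), bh_oracle(c(0.01, 0.02, 0.04)))
})

test_that("link selection applies the strict sign and alpha rules", {
  reg <- tiny_registry(2, 2)
  net <- build_cooccurrence(
    sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5), reg)$bees,
    sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5), reg)$plants,
    reg)
  # doctor the matrices to exercise the rule exactly
  net$r[] <- NA; net$p[] <- NA; net$defined[] <- FALSE
  net$r[1, 1] <- 0.9;  net$p[1, 1] <- 0.01   # selected
  net$r[1, 2] <- -0.9; net$p[1, 2] <- 0.001  # sign rule
  net$r[2, 1] <- 0.5;  net$p[2, 1] <- 0.05   # boundary: not < alpha
  net$defined[1, 1] <- net$defined[1, 2] <- net$defined[2, 1] <- TRUE
  sel <- select_links(net, alpha = 0.05, use_adjusted = FALSE)
  expect_identical(as.logical(sel$sig),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(sel$p_adj[sel$defined] >= sel$p[sel$defined]))
})

test_that("selection on adjusted p-values is more conservative", {
  reg <- synthetic_registry()
  sim <- generate_dataset(planted_scenario(seed = 21, n_pairs = 6, beta = 30))
  net <- build_cooccurrence(sim$bees, sim$plants, reg)
  raw <- select_links(net, use_adjusted = FALSE)
  adj <- select_links(net, use_adjusted = TRUE)
  expect_lte(sum(adj$sig), sum(raw$sig))
  expect_true(all(which(adj$sig) %in% which(raw$sig)))
})

test_that("validation against visitation behaves under signal and null", {
  reg <- tiny_registry(3, 3)
  set.seed(14)
  bees <- survey_from_matrix(
    matrix(rpois(15, 6), 5, 3, dimnames = list(paste0("s", 1:5),
                                               paste0("b", 1:3))), reg)
  plants <- survey_from_matrix(
    matrix(round(runif(15, 0.01, 0.2), 3), 5, 3,
           dimnames = list(paste0("s", 1:5), paste0("p", 1:3))), reg)
  net <- build_cooccurrence(bees, plants, reg)
  # visits proportional to r (shifted positive) -> perfect match
  v <- round((net$r - min(net$r)) * 1e6)
  visits <- visitation_matrix(v)
  res <- validate_vs_visitation(net, visits)
  expect_equal(res$r, 1, tolerance = 1e-6)
  expect_equal(res$n_cells, sum(net$defined))
  # permuted visits: mean validation r near 0 (null oracle)
  set.seed(15)
  rs <- replicate(300, {
    vp <- v; vp[] <- v[sample(length(v))]
    validate_vs_visitation(net, visitation_matrix(vp))$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(300))
  # constant visitation is undefined, with a warning
  expect_warning(res0 <- validate_vs_visitation(
    net, visitation_matrix(matrix(2L, 3, 3,
                                  dimnames = dimnames(net$r)))),
    "constant")
  expect_true(is.na(res0$r))
})

test_that("family proportions count selected links and total one", {
  reg <- tiny_registry(4, 4)  # families alternate Halictidae/Apidae, Ast/Fab
  sim <- list()
  net <- build_cooccurrence(
    sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5),
                    reg)$bees,
    sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5),
                    reg)$plants, reg)
  net$sig <- matrix(FALSE, 4, 4, dimnames = dimnames(net$r))
  net$sig[1, 1] <- TRUE   # Halictidae x Asteraceae
  fp1 <- family_proportions(net, reg)
  expect_equal(fp1$prop["Asteraceae", "Halictidae"], 1)
  expect_equal(sum(fp1$prop), 1)
  net$sig[2, 1] <- net$sig[3, 1] <- net$sig[2, 2] <- TRUE  # 4 links
  fp <- family_proportions(net, reg)
  expect_equal(fp$n_links, 4)
  expect_equal(fp$prop["Asteraceae", "Halictidae"], 0.5)
  expect_equal(sum(fp$prop), 1)
  expect_equal(sum(fp$row_totals), 1)
  expect_equal(sum(fp$col_totals), 1)
  expect_equal(fp$counts, t(sapply(rownames(fp$counts), function(pf)
    sapply(colnames(fp$counts), function(bf) {
      sum(net$sig & outer(reg$family[match(rownames(net$sig), reg$taxon)] == bf,
                          reg$family[match(colnames(net$sig), reg$taxon)] == pf))
    }))), ignore_attr = TRUE)
  net$sig[] <- FALSE
  expect_warning(family_proportions(net, reg), "no selected links")
})

test_that("origin ratios count native and exotic links exactly", {
  reg <- tiny_registry(4, 4)  # plants alternate native/exotic
  tabs <- sim_pair_tables(c(3, 1, 4, 1, 5), c(0.3, 0.1, 0.4, 0.1, 0.5), reg)
  net <- build_cooccurrence(tabs$bees, tabs$plants, reg)
  net$sig <- matrix(FALSE, 4, 4, dimnames = dimnames(net$r))
  # b1, b3 are Halictidae; p1, p3 native; p2, p4 exotic
  net$sig[1, 1] <- net$sig[1, 3] <- net$sig[3, 1] <- TRUE  # 3 native links
  net$sig[1, 2] <- TRUE                                    # 1 exotic link
  res <- origin_ratio(net, reg, "Halictidae")
  expect_equal(res$n_native, 3)
  expect_equal(res$n_exotic, 1)
  expect_equal(res$ratio, 3)
  expect_equal(res$n_native + res$n_exotic, sum(net$sig))
  net$sig[1, 2] <- FALSE
  expect_identical(origin_ratio(net, reg, "Halictidae")$ratio, Inf)
  expect_true(is.nan(origin_ratio(net, reg, "Apidae")$ratio))
  part <- classify_commonness(tabs$bees, reg)  # b1 is the only (common) bee
  expect_error(origin_ratio(net, reg, "Vespidae"), "unknown bee group")
  expect_error(origin_ratio(net, reg, "common"), "requires")
  expect_equal(origin_ratio(net, reg, "common", part)$n_native,
               sum(net$sig[1, c(1, 3)]))
})

test_that("monthly networks recover month-specific planted structure", {
  reg <- synthetic_registry()
  tr <- planted_scenario(seed = 31, n_pairs = 5, beta = 45,
                         coupling_month = "May")
  sim <- generate_dataset(tr)
  edges <- monthly_networks(sim$bees, sim$plants, reg)
  expect_s3_class(edges, "bipartite_edges")
  expect_true(all(edges$weight >= 1))
  expect_true(all(as.character(edges$month) %in% SURVEY_MONTHS))
  # planted families should be heaviest in May
  planted_fams <- table(reg$family[match(tr$planted$plant, reg$taxon)])
  may_w <- sum(edges$weight[edges$month == "May"])
  other_w <- sum(edges$weight[edges$month != "May"]) / 3
  expect_gt(may_w, other_w)
  # edge weights equal a brute-force recount of the per-month mask
  b <- sim$bees[sim$bees$month == "Jun", ]
  p <- sim$plants[sim$plants$month == "Jun", ]
  net <- select_links(build_cooccurrence(b, p, reg,
                                         pairing = c("site", "year")))
  idx <- which(net$sig, arr.ind = TRUE)
  recount <- table(paste(reg$family[match(colnames(net$sig)[idx[, 2]],
                                          reg$taxon)],
                         reg$family[match(rownames(net$sig)[idx[, 1]],
                                          reg$taxon)]))
  jun <- edges[edges$month == "Jun", ]
  expect_equal(sum(jun$weight), sum(net$sig))
  for (k in seq_len(nrow(jun)))
    expect_equal(jun$weight[k],
                 as.integer(recount[paste(jun$plant_family[k],
                                          jun$bee_family[k])]))
  # a month with too few events is skipped with a warning
  few <- sim$bees[!(sim$bees$month == "Aug" & sim$bees$site != "site1"), ]
  fewp <- sim$plants[!(sim$plants$month == "Aug" & sim$plants$site != "site1"), ]
  expect_warning(monthly_networks(few, fewp, reg), "Aug skipped")
})
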