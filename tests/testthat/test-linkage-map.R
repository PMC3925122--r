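test_that("identical codominant columns give rf = 0 with strong support", {
  col <- rep(c("AA", "AB", "BB", "AB"), 25)
  pl <- estimate_rf(col, col)
  expect_lt(pl$rf, 1e-6)
  expect_gt(pl$lod, 5)
})

test_that("counts matching exact independence give rf = 0.5 and LOD 0", {
  ## 1:2:1 x 1:2:1 product table, n = 16 per smallest cell
  g <- c("BB", "AB", "AB", "AA")
  col1 <- rep(g, each = 4, times = 16)
  col2 <- rep(rep(g, times = 4), times = 16)
  pl <- estimate_rf(col1, col2)
  expect_equal(pl$rf, 0.5, tolerance = 0.02)
  expect_lt(pl$lod, 0.01)
})

test_that("EM estimate matches grid-search maximum likelihood", {
  sim <- oracle_sim_pair(10000, 0.10, seed = 41)
  pl <- estimate_rf(sim$col1, sim$col2)
  grid_hat <- oracle_rf_grid(sim$col1, sim$col2)
  expect_lt(abs(pl$rf - grid_hat), 0.001)
  ## dominant-coded columns keep matching the grid oracle
  col1d <- ifelse(sim$col1 %in% c("AA", "AB"), "AX", "BB")
  pl_d <- estimate_rf(col1d, sim$col2)
  grid_d <- oracle_rf_grid(col1d, sim$col2)
  expect_lt(abs(pl_d$rf - grid_d), 0.001)
})

test_that("rf estimates stay in [0, 0.5] with nonnegative LOD and flag sparse data", {
  set.seed(7)
  for (r in c(0.02, 0.2, 0.45)) {
    sim <- oracle_sim_pair(150, r, seed = round(r * 1000))
    pl <- estimate_rf(sim$col1, sim$col2)
    expect_gte(pl$rf, 0)
    expect_lte(pl$rf, 0.5)
    expect_gte(pl$lod, 0)
  }
  short <- estimate_rf(c("AA", "AB", "BB", rep("NN", 20)),
                       c("AA", "AB", "BB", rep("NN", 20)))
  expect_true(short$low_confidence)
})

test_that("grouping is a partition obeying the LOD/rf thresholds", {
  pairs <- data.frame(
    marker_a = c("m1", "m1", "m2"),
    marker_b = c("m2", "m3", "m3"),
    rf = c(0.1, 0.45, 0.1),
    lod = c(10, 0.2, 10)
  )
  ## chain m1-m2-m3: one group by transitivity
  g <- group_markers(pairs, markers = c("m1", "m2", "m3", "m4"))
  expect_equal(length(g), 2)
  expect_setequal(g[[1]], c("m1", "m2", "m3"))
  expect_equal(g[[2]], "m4")
  ## all unlinked: singletons
  pairs$lod <- 0
  g2 <- group_markers(pairs, markers = c("m1", "m2", "m3"))
  expect_equal(lengths(g2), c(1L, 1L, 1L))
  expect_setequal(unlist(g2), c("m1", "m2", "m3"))
})

test_that("full-scale synthetic cross coalesces into the true 12 groups", {
  sim <- simulate_f2(safflower_cross_design(seed = 4))
  lmap <- build_map(sim$geno)
  s <- summarize_map(lmap)
  expect_equal(s$n_groups, 12)
  expect_equal(s$n_markers, 244)
  ## every recovered group corresponds to exactly one true linkage group
  truth <- sim$map$linkage_group[match(lmap$map$marker, sim$map$marker)]
  tab <- table(lmap$map$linkage_group, truth)
  expect_true(all(rowSums(tab > 0) == 1))
  ## total length near the true 858.2 cM
  expect_lt(abs(s$total_cm - 858.2) / 858.2, 0.15)
})

test_that("two-marker groups return the canonical order", {
  pairs <- data.frame(marker_a = "b", marker_b = "a", rf = 0.1, lod = 10)
  expect_equal(order_group(c("b", "a"), pairs), c("a", "b"))
})

test_that("ordering recovers the true marker order (up to reversal)", {
  d <- cross_design(1000, data.frame(name = "X", n_markers = 4,
                                     length_cm = 30), seed = 19)
  s <- simulate_f2(d)
  ## true positions 0, 10, 20, 30: rebuild with even spacing
  s$map$position_cm <- c(0, 10, 20, 30)
  pr <- rf_matrix(s$geno)
  ord <- order_group(colnames(s$geno), pr)
  expect_true(identical(ord, colnames(s$geno)) ||
                identical(ord, rev(colnames(s$geno))))
})

test_that("ordering is near-optimal against brute-force enumeration", {
  set.seed(3)
  wins <- vapply(1:8, function(k) {
    d <- cross_design(300, data.frame(name = "X", n_markers = 6,
                                      length_cm = 50), seed = 100 + k)
    s <- simulate_f2(d)
    pr <- rf_matrix(s$geno)
    ord <- order_group(colnames(s$geno), pr)
    rf_mat <- matrix(0.5, 6, 6,
                     dimnames = list(colnames(s$geno), colnames(s$geno)))
    rf_mat[cbind(pr$marker_a, pr$marker_b)] <- pr$rf
    rf_mat[cbind(pr$marker_b, pr$marker_a)] <- pr$rf
    adj_sum <- function(o) sum(rf_mat[cbind(o[-length(o)], o[-1])])
    got <- adj_sum(ord)
    perms <- combinat_perms(colnames(s$geno))
    all_sums <- vapply(perms, adj_sum, 0)
    mean(got <= all_sums)
  }, 0)
  expect_true(all(wins >= 0.95))
})

test_that("map positions follow the map function and reverse cleanly", {
  expect_equal(map_positions(numeric(0)), 0)
  expect_equal(map_positions(c(0, 0.1)), c(0, 0, -50 * log(0.8)))
  expect_error(map_positions(0.5))
  ## group length is invariant under order reversal
  rfs <- c(0.05, 0.12, 0.2)
  expect_equal(max(map_positions(rfs)), max(map_positions(rev(rfs))))
})

test_that("distortion chi-square matches direct arithmetic", {
  perfect <- c(rep("BB", 69), rep("AB", 138), rep("AA", 69))
  r0 <- segregation_distortion(perfect)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$direction, "none")

  skewed <- c(rep("AA", 90), rep("AB", 140), rep("BB", 46))
  r1 <- segregation_distortion(skewed)
  expect_equal(r1$chi2, 14.087, tolerance = 1e-3)
  expect_equal(r1$p, 8.74e-4, tolerance = 1e-2)
  expect_equal(r1$direction, "cultivar_excess")

  dom <- c(rep("AX", 207), rep("BB", 69))
  r2 <- segregation_distortion(dom)
  expect_equal(r2$chi2, 0)

  het <- c(rep("AB", 200), rep("AA", 38), rep("BB", 38))
  expect_equal(segregation_distortion(het)$direction, "het_excess")
})

test_that("distortion tiers follow Bonferroni arithmetic", {
  skewed <- c(rep("AA", 90), rep("AB", 140), rep("BB", 46))
  p_raw <- segregation_distortion(skewed)$p
  for (fam in c(1, 50, 244)) {
    tier <- segregation_distortion(skewed, family = fam)$tier
    p_adj <- min(p_raw * fam, 1)
    want <- if (p_adj < 0.001) "0.001" else if (p_adj < 0.01) "0.01" else
      if (p_adj < 0.05) "0.05" else "ns"
    expect_equal(tier, want)
  }
})

test_that("marker distribution test flags extreme clustering only", {
  clustered <- data.frame(
    linkage_group = "X",
    marker = sprintf("m%02d", 1:40),
    position_cm = c(rep(1, 38), 0, 100)
  )
  expect_lt(marker_distribution_test(clustered)$p, 1e-6)

  even <- data.frame(
    linkage_group = rep(c("X", "Y"), each = 30),
    marker = sprintf("m%02d", 1:60),
    position_cm = rep(seq(0, 98, length.out = 30), 2)
  )
  expect_gt(marker_distribution_test(even)$p, 0.05)
  expect_error(marker_distribution_test(even[1:3, ], bin_cm = 100))
})

test_that("map summary reproduces the published spacing arithmetic", {
  s <- summarize_map(simulate_f2(safflower_cross_design())$map)
  expect_equal(s$total_cm, 858.2, tolerance = 1e-9)
  expect_equal(round(s$mean_spacing_cm, 1), 3.7)

  tiny <- data.frame(linkage_group = "X", marker = c("a", "b"),
                     position_cm = c(0, 10))
  s2 <- summarize_map(tiny)
  expect_equal(s2$total_cm, 10)
  expect_equal(s2$mean_spacing_cm, 10)

  singletons <- data.frame(linkage_group = as.character(1:12),
                           marker = sprintf("m%02d", 1:12),
                           position_cm = 0)
  s3 <- summarize_map(singletons)
  expect_equal(s3$total_cm, 0)
  expect_true(is.na(s3$mean_spacing_cm))
})
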