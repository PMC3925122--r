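# shared scan fixture: one full-scale cross and a 20%-PVE trait
scan_sim <- simulate_f2(safflower_cross_design(seed = 3))
scan_arch <- trait_architecture(
  qtl = data.frame(lg = "C", position_cm = 50, a = 1, d = 0.3))
set.seed(10)
scan_trait <- simulate_trait(scan_arch, scan_sim, target_pve = 0.2)

test_that("cofactor selection returns nothing for pure-noise phenotypes", {
  set.seed(11)
  n_sel <- vapply(1:10, function(i) {
    length(select_cofactors(scan_sim$geno, rnorm(276)))
  }, 0L)
  expect_gte(mean(n_sel == 0), 0.9)
})

test_that("cofactor selection finds the marker nearest a strong QTL", {
  cof <- select_cofactors(scan_sim$geno, scan_trait$phenotype)
  expect_gte(length(cof), 1)
  pos <- scan_sim$map[match(cof, scan_sim$map$marker), ]
  expect_true(any(pos$linkage_group == "C" &
                    abs(pos$position_cm - 50) < 15))
})

test_that("cofactor count is capped at the configured maximum", {
  d <- cross_design(400, data.frame(name = LETTERS[1:8],
                                    n_markers = rep(3, 8),
                                    length_cm = rep(20, 8)), seed = 21)
  s <- simulate_f2(d)
  arch <- trait_architecture(
    qtl = data.frame(lg = LETTERS[1:8], position_cm = 10,
                     a = rep(2, 8), d = 0))
  set.seed(5)
  tr <- simulate_trait(arch, s, target_pve = 0.9)
  cof <- select_cofactors(s$geno, tr$phenotype, max_cofactors = 5)
  expect_equal(length(cof), 5)
})

test_that("constant phenotype yields a flat zero LOD profile", {
  prof <- cim_scan(scan_sim$geno, rep(1, 276), scan_sim$map,
                   scan_config(), cofactors = character(0))
  expect_true(all(prof$lod < 1e-8))
})

test_that("CIM with zero cofactors equals plain interval mapping", {
  prof <- cim_scan(scan_sim$geno, scan_trait$phenotype, scan_sim$map,
                   scan_config(), cofactors = character(0))
  ## reference: direct per-position interval-mapping fit
  y <- scan_trait$phenotype
  sub <- prof[prof$linkage_group == "C", ][seq(1, 38, by = 7), ]
  msub <- scan_sim$map[scan_sim$map$linkage_group == "C", ]
  msub <- msub[order(msub$position_cm), ]
  for (i in seq_len(nrow(sub))) {
    p <- sub$position_cm[i]
    li <- max(which(msub$position_cm <= p))
    ri <- min(which(msub$position_cm >= p))
    pr <- genotype_probs(scan_sim$geno[, msub$marker[li]],
                         scan_sim$geno[, msub$marker[ri]],
                         p - msub$position_cm[li],
                         msub$position_cm[ri] - p)
    x <- pr[, "p_QQ"] - pr[, "p_qq"]
    z <- pr[, "p_Qq"]
    fit <- lm(y ~ x + z)
    rss1 <- sum(residuals(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    expect_equal(sub$lod[i], 276 / 2 * log10(rss0 / rss1),
                 tolerance = 1e-8)
  }
})

test_that("the scan localises a simulated QTL at its true position", {
  prof <- cim_scan(scan_sim$geno, scan_trait$phenotype, scan_sim$map,
                   scan_config())
  pk <- prof[which.max(prof$lod), ]
  expect_equal(pk$linkage_group, "C")
  expect_lt(abs(pk$position_cm - 50), 10)
})

test_that("permutation thresholds are ordered, deterministic and seeded", {
  cfg <- scan_config(n_permutations = 100, seed = 5)
  thr1 <- permutation_threshold(scan_sim$geno, scan_trait$phenotype,
                                scan_sim$map, cfg)
  thr2 <- permutation_threshold(scan_sim$geno, scan_trait$phenotype,
                                scan_sim$map, cfg)
  expect_identical(thr1, thr2)
  expect_lte(thr1[["0.10"]], thr1[["0.05"]])
  cfg2 <- scan_config(n_permutations = 100, seed = 6)
  thr3 <- permutation_threshold(scan_sim$geno, scan_trait$phenotype,
                                scan_sim$map, cfg2)
  expect_false(identical(thr1, thr3))
})

test_that("batched permutation maxima equal per-scan maxima", {
  d <- cross_design(120, data.frame(name = c("A", "B"),
                                    n_markers = c(6, 6),
                                    length_cm = c(50, 50)), seed = 31)
  s <- simulate_f2(d)
  set.seed(1)
  y <- rnorm(120)
  cfg <- scan_config(n_permutations = 100, max_cofactors = 0, seed = 9)
  thr <- permutation_threshold(s$geno, y, s$map, cfg)
  maxima <- attr(thr, "max_lod")
  set.seed(9)
  for (b in 1:3) {
    yb <- sample(y)
    prof <- cim_scan(s$geno, yb, s$map, cfg, cofactors = character(0))
    expect_equal(max(prof$lod), maxima[b], tolerance = 1e-8)
  }
})

test_that("twin peaks follow the 2-LOD separation rule", {
  mk_profile <- function(dip) {
    pos <- seq(0, 40, by = 2)
    valley <- 5.5 - dip
    lod <- approx(x = c(0, 10, 20, 30, 40),
                  y = c(3, 6, valley, 5.5, 2), xout = pos)$y
    prof <- data.frame(linkage_group = "X", position_cm = pos,
                       lod = lod, a = 1, d = 0, pve = 10)
    class(prof) <- c("cim_scan", "data.frame")
    prof
  }
  thr <- c("0.05" = 3, "0.1" = 2.5)
  one <- call_qtl(mk_profile(1.5), thr)
  expect_equal(nrow(one), 1)
  expect_equal(one$position_cm, 10)
  two <- call_qtl(mk_profile(3), thr)
  expect_equal(nrow(two), 2)
  flat <- data.frame(linkage_group = "X", position_cm = seq(0, 40, 2),
                     lod = 1, a = 0, d = 0, pve = 0)
  expect_equal(nrow(call_qtl(flat, thr)), 0)
})

test_that("1-LOD intervals bracket the peak and stop at the decline", {
  pos <- seq(0, 40, by = 2)
  lod <- 8 - abs(pos - 20) * 0.25
  prof <- data.frame(linkage_group = "X", position_cm = pos, lod = lod,
                     a = 1, d = 0, pve = 10)
  q <- call_qtl(prof, c("0.05" = 3, "0.1" = 2.5))
  expect_equal(q$position_cm, 20)
  expect_lte(q$interval_lo, q$position_cm)
  expect_gte(q$interval_hi, q$position_cm)
  ## all positions inside the interval are within 1 LOD of the peak
  inside <- pos >= q$interval_lo & pos <= q$interval_hi
  expect_true(all(lod[inside] >= max(lod) - 1))
  ## positions just outside fall below
  expect_true(all(lod[!inside] < max(lod) - 1))
})

test_that("the information criterion matches its closed form", {
  expect_equal(mim_ic(-100, 0, 276), 200)
  expect_equal(mim_ic(-100, 2, 276), 200 + 2 * log(276))
  expect_equal(mim_ic(-100, 2, 276), 211.241, tolerance = 1e-3)
})

test_that("MIM drops a spurious QTL injected into a one-QTL model", {
  prof <- cim_scan(scan_sim$geno, scan_trait$phenotype, scan_sim$map,
                   scan_config())
  q <- call_qtl(prof, c("0.05" = 3.3, "0.1" = 3), map = scan_sim$map,
                trait = "t")
  q <- q[q$linkage_group == "C", , drop = FALSE][1, , drop = FALSE]
  spurious <- q
  spurious$linkage_group <- "F"
  spurious$position_cm <- 15
  spurious$lod <- 0.2
  qq <- rbind(q, spurious)
  class(qq) <- c("qtl_table", "data.frame")
  set.seed(33)
  drops <- vapply(1:10, function(i) {
    tr <- simulate_trait(scan_arch, scan_sim, target_pve = 0.2)
    mm <- mim_refine(qq, scan_sim$geno, tr$phenotype, scan_sim$map)
    !("F" %in% mm$qtl$linkage_group) && ("C" %in% mm$qtl$linkage_group)
  }, TRUE)
  expect_gte(mean(drops), 0.9)
})

test_that("gene-action classes follow the printed cutoffs", {
  expect_equal(classify_gene_action(ratio = -0.79), "recessive")
  expect_equal(classify_gene_action(ratio = 7.26), "overdominant")
  expect_equal(classify_gene_action(ratio = -21.68), "underdominant")
  expect_equal(classify_gene_action(ratio = 0), "additive")
  ## boundary behaviour: left-closed / right-open exactly as printed
  expect_equal(classify_gene_action(ratio = -1.25), "underdominant")
  expect_equal(classify_gene_action(ratio = -0.75), "recessive")
  expect_equal(classify_gene_action(ratio = -0.25), "partially_recessive")
  expect_equal(classify_gene_action(ratio = 0.25), "partially_dominant")
  expect_equal(classify_gene_action(ratio = 0.75), "dominant")
  expect_equal(classify_gene_action(ratio = 1.25), "overdominant")
  expect_error(classify_gene_action(a = 0, d = 1))
})

test_that("magnitude classes use strict 10/25 cutoffs", {
  expect_equal(classify_magnitude(63.4), "large")
  expect_equal(classify_magnitude(4.2), "small")
  expect_equal(classify_magnitude(25.0), "intermediate")
  expect_equal(classify_magnitude(10.0), "intermediate")
  expect_error(classify_magnitude(101))
})

test_that("effect direction compares the cultivar allele to the parental gap", {
  expect_equal(effect_direction(5.92, 19.031, 0), "expected")
  expect_equal(effect_direction(0.09, 3.38, 3.63), "wrong")
  expect_true(is.na(effect_direction(1, 2, 2)))
  expect_true(is.na(effect_direction(1, 3, 1, significant = FALSE)))
})

test_that("QTL table statistics handle edge cases", {
  one <- data.frame(trait = "t", interval_lo = 10, interval_hi = 20,
                    pve = 12, dominance_ratio = 0.5)
  s <- qtl_table_stats(one)
  expect_equal(s$mean_width_cm, 10)
  expect_equal(s$n_intermediate, 1)
  s0 <- qtl_table_stats(one[0, ])
  expect_equal(s0$n_qtl, 0)
  expect_true(is.na(s0$mean_width_cm))
})
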