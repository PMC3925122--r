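mk_hits <- function(q, s, e, bits = 200) {
  data.frame(qseqid = q, sseqid = s, pident = 95, length = 300,
             mismatch = 1, gapopen = 0, qstart = 1, qend = 300,
             sstart = 1, send = 300, evalue = e, bitscore = bits)
}

test_that("hit filtering keeps the top two below a strict threshold", {
  h <- mk_hits("q1", c("s1", "s2", "s3"), c(1e-10, 1e-8, 1e-7))
  f <- filter_hits(h)
  expect_equal(f$sseqid, c("s1", "s2"))
  expect_equal(nrow(filter_hits(mk_hits("q1", "s1", 1e-5))), 0)
  expect_equal(nrow(filter_hits(mk_hits("q1", "s1", 1e-6))), 0)
})

test_that("tied e-values break on bit score then subject id", {
  h <- rbind(mk_hits("q1", "s_b", 1e-20, bits = 100),
             mk_hits("q1", "s_a", 1e-20, bits = 300),
             mk_hits("q1", "s_c", 1e-20, bits = 100))
  f <- filter_hits(h)
  expect_equal(f$sseqid, c("s_a", "s_b"))
})

test_that("loci bridge only through shared scaffolds", {
  ha <- filter_hits(mk_hits(c("a1", "a2"), c("S", "S1"), 1e-20))
  hb <- filter_hits(mk_hits(c("b1", "b2"), c("S", "S2"), 1e-20))
  pr <- bridge_loci(ha, hb)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$locus_a, "a1")
  expect_equal(pr$locus_b, "b1")
  expect_equal(pr$scaffold, "S")
})

test_that("synteny blocks need at least three shared loci", {
  mk_maps <- function(k) {
    list(
      a = data.frame(linkage_group = "LA", marker = sprintf("a%d", 1:k),
                     position_cm = seq(0, 30, length.out = k)),
      b = data.frame(linkage_group = "LB", marker = sprintf("b%d", 1:k),
                     position_cm = seq(0, 15, length.out = k))
    )
  }
  mk_pairs <- function(k) data.frame(locus_a = sprintf("a%d", 1:k),
                                     locus_b = sprintf("b%d", 1:k),
                                     scaffold = sprintf("s%d", 1:k))
  m2 <- mk_maps(2)
  expect_equal(length(call_synteny(mk_pairs(2), m2$a, m2$b)), 0)
  m3 <- mk_maps(3)
  bl <- call_synteny(mk_pairs(3), m3$a, m3$b)
  expect_equal(length(bl), 1)
  expect_equal(bl[[1]]$orientation, "same")
  ## reversed order on map B: inverted
  m3$b$position_cm <- rev(m3$b$position_cm)
  bl2 <- call_synteny(mk_pairs(3), m3$a, m3$b)
  expect_equal(bl2[[1]]$orientation, "inverted")
})

test_that("interval projection is exact at loci and proportional beyond", {
  block <- structure(list(
    lg_a = "LA", lg_b = "LB",
    loci = data.frame(locus_a = c("a1", "a2", "a3"),
                      pos_a = c(0, 25, 50),
                      locus_b = c("b1", "b2", "b3"),
                      pos_b = c(10, 22.5, 35),
                      scaffold = c("s1", "s2", "s3")),
    n_loci = 3, orientation = "same"), class = "synteny_block")
  ## endpoints at shared loci project to their partner positions
  expect_equal(project_interval(c(0, 50), block), c(10, 35))
  ## 5 cM beyond the last shared locus: block spans 50 (A) / 25 (B)
  expect_equal(project_interval(c(0, 55), block), c(10, 37.5))
  ## interior round trip A -> B -> A
  iv <- c(12, 40)
  there <- project_interval(iv, block, from = "a")
  back <- project_interval(there, block, from = "b")
  expect_equal(back, iv, tolerance = 1e-9)
  ## clipping and degenerate spans
  expect_equal(project_interval(c(40, 80), block, lg_length = 36)[2], 36)
  degen <- block
  degen$loci$pos_b <- 5
  expect_error(project_interval(c(0, 10), degen))
})

test_that("projection is monotone within a consistently oriented block", {
  block <- structure(list(
    lg_a = "LA", lg_b = "LB",
    loci = data.frame(locus_a = sprintf("a%d", 1:4),
                      pos_a = c(0, 10, 30, 60),
                      locus_b = c(40, 32, 18, 3),
                      locus_b2 = NA, scaffold = sprintf("s%d", 1:4)),
    n_loci = 4, orientation = "inverted"), class = "synteny_block")
  names(block$loci)[3] <- "pos_b"
  block$loci$locus_b <- sprintf("b%d", 1:4)
  xs <- seq(0, 60, by = 5)
  ys <- vapply(xs, function(p) project_interval(c(p, p), block)[1], 0)
  expect_true(all(diff(ys) < 0))
})

test_that("one A-QTL overlapping two projected B-QTL counts once", {
  block <- structure(list(
    lg_a = "LA", lg_b = "LB",
    loci = data.frame(locus_a = c("a1", "a2", "a3"),
                      pos_a = c(0, 25, 50),
                      locus_b = c("b1", "b2", "b3"),
                      pos_b = c(0, 12.5, 25),
                      scaffold = c("s1", "s2", "s3")),
    n_loci = 3, orientation = "same"), class = "synteny_block")
  qtl_a <- data.frame(trait = "t", linkage_group = "LA",
                      interval_lo = 10, interval_hi = 40)
  qtl_b <- data.frame(trait = "t", linkage_group = "LB",
                      interval_lo = c(6, 16), interval_hi = c(9, 19))
  det <- detect_colocalization(qtl_a, qtl_b, list(block))
  expect_equal(nrow(det$matches), 2)
  expect_equal(det$colocalized$n_colocalized_a, 1)
  ## disjoint intervals on the same block: no match
  qtl_b2 <- data.frame(trait = "t", linkage_group = "LB",
                       interval_lo = 24, interval_hi = 25)
  det2 <- detect_colocalization(qtl_a, qtl_b2, list(block))
  expect_equal(nrow(det2$matches), 0)
})

test_that("hypergeometric point probability matches exhaustive enumeration", {
  expect_equal(hypergeom_p(10, 2, 4, 3)$p_point, 0.3, tolerance = 1e-12)
  set.seed(19)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    l <- sample(1:n, 1)
    s <- sample(1:l, 1)
    m <- sample(0:min(l, s), 1)
    got <- hypergeom_p(n, m, l, s)$p_point
    expect_equal(got, oracle_hypergeom_enum(n, m, l, s),
                 tolerance = 1e-10,
                 label = sprintf("n=%d m=%d l=%d s=%d", n, m, l, s))
  }
})

test_that("hypergeometric probability matches Monte Carlo for larger n", {
  set.seed(23)
  for (k in 1:3) {
    n <- sample(20:60, 1)
    l <- sample(5:15, 1)
    s <- sample(2:5, 1)
    m <- sample(0:s, 1)
    got <- hypergeom_p(n, m, l, s)$p_point
    mc <- oracle_hypergeom_mc(n, m, l, s)
    expect_lt(abs(got - mc[["p"]]), 3 * mc[["se"]] + 1e-8)
  }
})

test_that("hypergeometric point probabilities are normalized and bounded", {
  n <- 15; l <- 6; s <- 4
  total <- sum(vapply(0:s, function(m) hypergeom_p(n, m, l, s)$p_point, 0))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_equal(hypergeom_p(8, 3, 8, 3)$p_point, 1)  # l = n, m = s
  expect_error(hypergeom_p(10, 5, 4, 3))
  expect_error(hypergeom_p(10, 1, 11, 3))
})

test_that("Fisher's combined test matches the chi-square survival oracle", {
  one <- fisher_combined(0.05)
  expect_equal(one$p_combined, 0.05, tolerance = 1e-9)
  two <- fisher_combined(c(0.05, 0.05))
  expect_equal(two$X, -4 * log(0.05), tolerance = 1e-9)
  expect_equal(two$X, 11.983, tolerance = 1e-3)
  expect_equal(two$p_combined, 0.0175, tolerance = 1e-2)
  expect_equal(two$p_combined, oracle_chisq_sf(two$X, 4),
               tolerance = 1e-4)
  ## p = 1 contributes nothing
  expect_equal(fisher_combined(c(0.05, 1))$X, -2 * log(0.05))
  expect_error(fisher_combined(c(0, 0.1)))
})

test_that("direction concordance compares cultivar-allele signs", {
  expect_equal(direction_concordance(1, 2), "concordant")
  expect_equal(direction_concordance(1, -2), "discordant")
  expect_true(is.na(direction_concordance(NA, 1)))
  expect_true(is.na(direction_concordance(0, 1)))
})

test_that("bridging recovers planted homology exactly at zero noise", {
  hs <- simulate_homology(homology_spec(n_blocks = 1, loci_per_block = 3,
                                        n_coloc_traits = 1,
                                        n_noncoloc_traits = 0, seed = 2))
  rec <- recover_colocalization(hs$hits_a, hs$hits_b, hs$map_a, hs$map_b,
                                hs$qtl_a, hs$qtl_b)
  expect_equal(nrow(rec$pairs), 3)
  expect_equal(length(rec$blocks), 1)
  ## a 2-locus block is rejected downstream
  hs2 <- simulate_homology(homology_spec(n_blocks = 1, loci_per_block = 2,
                                         n_coloc_traits = 1,
                                         n_noncoloc_traits = 0, seed = 3))
  rec2 <- recover_colocalization(hs2$hits_a, hs2$hits_b, hs2$map_a,
                                 hs2$map_b, hs2$qtl_a, hs2$qtl_b)
  expect_equal(length(rec2$blocks), 0)
})

test_that("the homology truth table supports recovery testing under noise", {
  hs <- simulate_homology(homology_spec(n_blocks = 5, noise = 0.1,
                                        seed = 29))
  expect_equal(nrow(hs$truth$blocks), 5)
  expect_equal(nrow(hs$truth$pairs), 20)
  rec <- recover_colocalization(hs$hits_a, hs$hits_b, hs$map_a, hs$map_b,
                                hs$qtl_a, hs$qtl_b)
  found <- merge(hs$truth$pairs, rec$pairs,
                 by = c("locus_a", "locus_b", "scaffold"))
  recall <- nrow(found) / nrow(hs$truth$pairs)
  spurious <- nrow(rec$pairs) - nrow(found)
  expect_gte(recall, 0.95)
  expect_lte(spurious / max(nrow(rec$pairs), 1), 0.25)
})
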