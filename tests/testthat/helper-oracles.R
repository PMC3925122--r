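# Independent oracle implementations (deliberately written as plain
# nested-loop enumerations over the two-gamete model, separate from the
# package's vectorised code paths).

# genotypes compatible with an observed call (count of cultivar alleles)
.compatible_genos <- function(code) {
  switch(code,
         AA = 2L, AB = 1L, BB = 0L,
         AX = c(1L, 2L), BX = c(0L, 1L), NN = 0:2,
         stop("bad code"))
}

# two-locus class probability by explicit enumeration of ordered gamete
# pairs; gametes are (allele1, allele2) with allele 1 = cultivar
oracle_pair_prob <- function(code1, code2, r) {
  gametes <- expand.grid(a1 = 0:1, a2 = 0:1)
  gp <- function(g) 0.5 * if (g[1] != g[2]) r else (1 - r)
  total <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      g1 <- as.integer(gametes[i, ]); g2 <- as.integer(gametes[j, ])
      geno1 <- g1[1] + g2[1]
      geno2 <- g1[2] + g2[2]
      if (geno1 %in% .compatible_genos(code1) &&
          geno2 %in% .compatible_genos(code2)) {
        total <- total + gp(g1) * gp(g2)
      }
    }
  }
  total
}

# grid-search ML estimate of the recombination fraction
oracle_rf_grid <- function(col1, col2, grid = seq(0.001, 0.499, by = 0.001)) {
  keep <- col1 != "NN" & col2 != "NN"
  col1 <- col1[keep]; col2 <- col2[keep]
  classes <- table(paste(col1, col2))
  ll <- vapply(grid, function(r) {
    sum(vapply(names(classes), function(cl) {
      codes <- strsplit(cl, " ")[[1]]
      classes[[cl]] * log(oracle_pair_prob(codes[1], codes[2], r))
    }, 0))
  }, 0)
  grid[which.max(ll)]
}

# conditional QTL genotype probabilities by enumeration of ordered
# three-locus gamete pairs
oracle_flank_probs <- function(code_l, code_r, r1, r2) {
  haps <- expand.grid(l = 0:1, q = 0:1, r = 0:1)
  hp <- function(h) {
    0.5 * (if (h[1] != h[2]) r1 else 1 - r1) *
      (if (h[2] != h[3]) r2 else 1 - r2)
  }
  num <- c(0, 0, 0)
  for (i in 1:8) {
    for (j in 1:8) {
      h1 <- as.integer(haps[i, ]); h2 <- as.integer(haps[j, ])
      gl <- h1[1] + h2[1]; gq <- h1[2] + h2[2]; gr <- h1[3] + h2[3]
      if (gl %in% .compatible_genos(code_l) &&
          gr %in% .compatible_genos(code_r)) {
        num[gq + 1] <- num[gq + 1] + hp(h1) * hp(h2)
      }
    }
  }
  num / sum(num)
}

# hypergeometric point probability by exhaustive enumeration of all
# C(n, s) placements of the smaller QTL sample
oracle_hypergeom_enum <- function(n, m, l, s) {
  stopifnot(n <= 12)
  draws <- utils::combn(n, s)
  mean(apply(draws, 2, function(d) sum(d <= l) == m))
}

# Monte-Carlo hypergeometric point probability
oracle_hypergeom_mc <- function(n, m, l, s, reps = 1e5) {
  hits <- replicate(reps, sum(sample.int(n, s) <= l) == m)
  c(p = mean(hits), se = stats::sd(hits) / sqrt(reps))
}

# chi-square survival by numerical integration of the density
oracle_chisq_sf <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), lower = x,
                   upper = Inf)$value
}

# all permutations of a (short) vector
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# quick two-marker F2 genotype simulator used by rf tests (independent
# of the package simulator)
oracle_sim_pair <- function(n, r, seed) {
  set.seed(seed)
  draw_g <- function() {
    a1 <- stats::rbinom(n, 1, 0.5)
    rec <- stats::rbinom(n, 1, r)
    a2 <- ifelse(rec == 1, 1 - a1, a1)
    cbind(a1, a2)
  }
  g <- draw_g() + draw_g()
  list(col1 = c("BB", "AB", "AA")[g[, 1] + 1],
       col2 = c("BB", "AB", "AA")[g[, 2] + 1])
}
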