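#' Specify an F2 cross design
#'
#' Describes the mapping population to simulate: population size, linkage
#' groups (marker counts and lengths), the fraction of markers scored as
#' dominant, the missing-call rate, and regions of segregation distortion
#' applied through gamete- or zygote-level viability selection.
#'
#' @param n_individuals number of F2 individuals.
#' @param linkage_groups data frame with columns `name`, `n_markers`,
#'   `length_cm`.
#' @param dominant_marker_fraction proportion of markers re-coded to
#'   dominant ambiguity classes (`AX`/`BX`).
#' @param missing_rate proportion of calls masked to `NN`, completely at
#'   random.
#' @param distorted_regions `NULL` or a data frame with columns `lg`,
#'   `start_cm`, `end_cm`, `favored` (`"cultivar"`, `"wild"` or
#'   `"het_excess"`) and `s` (selection coefficient in `[0, 1]`).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return an object of class `cross_design`.
#' @seealso [safflower_cross_design()] for the default design emulating a
#'   crop x wild-progenitor safflower cross, [simulate_f2()].
#' @export
cross_design <- function(n_individuals,
                         linkage_groups,
                         dominant_marker_fraction = 0,
                         missing_rate = 0,
                         distorted_regions = NULL,
                         seed = 1L,
                         map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stopifnot(
    is.numeric(n_individuals), length(n_individuals) == 1, n_individuals > 0,
    is.data.frame(linkage_groups),
    all(c("name", "n_markers", "length_cm") %in% names(linkage_groups)),
    all(linkage_groups$n_markers >= 1),
    all(linkage_groups$length_cm >= 0),
    dominant_marker_fraction >= 0, dominant_marker_fraction <= 1,
    missing_rate >= 0, missing_rate <= 1
  )
  if (anyDuplicated(linkage_groups$name)) stop("duplicate linkage group names")
  if (!is.null(distorted_regions)) {
    stopifnot(
      is.data.frame(distorted_regions),
      all(c("lg", "start_cm", "end_cm", "favored", "s") %in%
            names(distorted_regions)),
      all(distorted_regions$lg %in% linkage_groups$name),
      all(distorted_regions$favored %in% c("cultivar", "wild", "het_excess")),
      all(distorted_regions$s >= 0), all(distorted_regions$s <= 1)
    )
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      linkage_groups = linkage_groups,
      dominant_marker_fraction = dominant_marker_fraction,
      missing_rate = missing_rate,
      distorted_regions = distorted_regions,
      seed = as.integer(seed),
      map_function = map_function
    ),
    class = "cross_design"
  )
}

#' Default cross design emulating the safflower domestication cross
#'
#' A 276-individual F2 design with 244 markers on 12 linkage groups
#' totalling 858.2 cM (group sizes 6-40 markers, lengths 30.7-105.3 cM),
#' 26/244 of markers dominant-scored, 2% missing calls, and three
#' distorted regions: one skewed toward the wild allele (LG K), one more
#' strongly toward the cultivar allele (LG L), and one narrow
#' heterozygote-excess region (LG E).
#'
#' @param seed integer seed.
#' @param n_individuals population size (default 276).
#' @return a [cross_design()] object.
#' @export
safflower_cross_design <- function(seed = 1L, n_individuals = 276L) {
  lgs <- data.frame(
    name = LETTERS[1:12],
    n_markers = c(20L, 18L, 25L, 24L, 22L, 6L, 15L, 40L, 25L, 10L, 14L, 25L),
    length_cm = c(71, 65, 75, 82, 70, 30.7, 62, 105.3, 80, 45.9, 66, 105.3)
  )
  distorted <- data.frame(
    lg = c("K", "L", "E"),
    start_cm = c(25, 40, 30),
    end_cm = c(38, 52, 34),
    favored = c("wild", "cultivar", "het_excess"),
    s = c(0.3, 0.4, 0.4)
  )
  cross_design(
    n_individuals = n_individuals,
    linkage_groups = lgs,
    dominant_marker_fraction = 26 / 244,
    missing_rate = 0.02,
    distorted_regions = distorted,
    seed = seed
  )
}

## simulate one LG worth of gametes for `n` individuals: matrix n x m of
## alleles (0 = wild, 1 = cultivar), Markov along the chromosome
.sim_gametes <- function(n, rf_adj) {
  m <- length(rf_adj) + 1L
  g <- matrix(0L, nrow = n, ncol = m)
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) {
    for (j in seq_along(rf_adj)) {
      rec <- stats::rbinom(n, 1L, rf_adj[j])
      g[, j + 1L] <- ifelse(rec == 1L, 1L - g[, j], g[, j])
    }
  }
  g
}

#' Simulate an F2 population
#'
#' Draws genotypes by simulating two independent gametes per individual
#' with crossover probabilities obtained from inter-marker cM distances
#' through the inverse map function (no interference). Distorted regions
#' are applied as viability selection at the marker nearest the region
#' midpoint: gametes carrying the disfavored allele are rejected and
#' redrawn with probability `s` (for `"het_excess"`, homozygous zygotes
#' are rejected with probability `s`). A `dominant_marker_fraction` of
#' markers is then re-coded to ambiguity classes (merge direction random
#' per marker) and calls are masked to `NN` at `missing_rate`.
#'
#' @param design a [cross_design()].
#' @return a list of class `f2_sim` with elements
#'   \describe{
#'     \item{geno}{[genotype_matrix()] of observed calls}
#'     \item{map}{data frame `linkage_group`, `marker`, `position_cm`
#'       (the true simulated map)}
#'     \item{truth}{list with the true codominant genotypes
#'       (`genotypes`, integer 0/1/2 copies of the cultivar allele), the
#'       phased gametes per LG (`gametes`), the dominant-marker merge
#'       directions (`dominant`), the distortion loci (`distortion`), and
#'       the design.}
#'   }
#' @export
simulate_f2 <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(design$seed)
  lgs <- design$linkage_groups
  to_r <- .map_fun_r(design$map_function)
  n <- design$n_individuals

  maps <- list()
  gametes <- list()
  geno_true <- NULL
  distortion_truth <- NULL

  for (i in seq_len(nrow(lgs))) {
    lg <- lgs$name[i]
    m <- lgs$n_markers[i]
    len <- lgs$length_cm[i]
    pos <- if (m == 1L) 0 else if (m == 2L) c(0, len) else {
      sort(c(0, stats::runif(m - 2L, 0, len), len))
    }
    marker <- sprintf("%s%02d", lg, seq_len(m))
    rf_adj <- if (m > 1L) to_r(diff(pos)) else numeric(0)

    regions <- design$distorted_regions
    regions <- if (is.null(regions)) NULL else regions[regions$lg == lg, , drop = FALSE]
    sel_idx <- integer(0)
    sel_type <- character(0)
    sel_s <- numeric(0)
    if (!is.null(regions) && nrow(regions) > 0) {
      for (k in seq_len(nrow(regions))) {
        mid <- (regions$start_cm[k] + regions$end_cm[k]) / 2
        sel_idx <- c(sel_idx, which.min(abs(pos - mid)))
        sel_type <- c(sel_type, regions$favored[k])
        sel_s <- c(sel_s, regions$s[k])
      }
      distortion_truth <- rbind(
        distortion_truth,
        data.frame(lg = lg, marker = marker[sel_idx], position_cm = pos[sel_idx],
                   favored = sel_type, s = sel_s)
      )
    }

    draw_selected_gametes <- function(n_draw) {
      ## gamete-level viability selection: a gamete carrying the
      ## disfavored allele is rejected (and redrawn) with probability s;
      ## each draw is tested exactly once
      g <- .sim_gametes(n_draw, rf_adj)
      for (k in seq_along(sel_idx)) {
        if (sel_type[k] == "het_excess") next
        disfavored <- if (sel_type[k] == "cultivar") 0L else 1L
        todo <- which(g[, sel_idx[k]] == disfavored &
                        stats::runif(n_draw) < sel_s[k])
        while (length(todo)) {
          g[todo, ] <- .sim_gametes(length(todo), rf_adj)
          todo <- todo[g[todo, sel_idx[k]] == disfavored &
                         stats::runif(length(todo)) < sel_s[k]]
        }
      }
      g
    }

    g1 <- draw_selected_gametes(n)
    g2 <- draw_selected_gametes(n)
    ## zygote-level selection for heterozygote excess: homozygous
    ## zygotes rejected with probability s, both gametes redrawn
    for (k in seq_along(sel_idx)) {
      if (sel_type[k] != "het_excess") next
      todo <- which(g1[, sel_idx[k]] == g2[, sel_idx[k]] &
                      stats::runif(n) < sel_s[k])
      while (length(todo)) {
        g1[todo, ] <- draw_selected_gametes(length(todo))
        g2[todo, ] <- draw_selected_gametes(length(todo))
        todo <- todo[g1[todo, sel_idx[k]] == g2[todo, sel_idx[k]] &
                       stats::runif(length(todo)) < sel_s[k]]
      }
    }

    colnames(g1) <- colnames(g2) <- marker
    gametes[[lg]] <- list(g1 = g1, g2 = g2)
    geno_true <- cbind(geno_true, g1 + g2)
    maps[[lg]] <- data.frame(linkage_group = lg, marker = marker,
                             position_cm = pos)
  }

  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  rownames(geno_true) <- sprintf("F2_%04d", seq_len(n))

  ## observed calls: codominant by default
  calls <- matrix(c("BB", "AB", "AA")[geno_true + 1L],
                  nrow = n, dimnames = dimnames(geno_true))

  ## dominant-scored markers: merge one homozygote class into the het
  n_mark <- ncol(calls)
  n_dom <- round(design$dominant_marker_fraction * n_mark)
  dominant <- NULL
  if (n_dom > 0) {
    dom_idx <- sort(sample.int(n_mark, n_dom))
    merged <- sample(c("AA", "BB"), n_dom, replace = TRUE)
    for (k in seq_along(dom_idx)) {
      j <- dom_idx[k]
      if (merged[k] == "AA") {
        calls[calls[, j] %in% c("AA", "AB"), j] <- "AX"
      } else {
        calls[calls[, j] %in% c("BB", "AB"), j] <- "BX"
      }
    }
    dominant <- data.frame(marker = colnames(calls)[dom_idx],
                           merged_class = merged)
  }

  if (design$missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < design$missing_rate,
                   nrow = n)
    calls[miss] <- "NN"
  }

  structure(
    list(
      geno = genotype_matrix(calls),
      map = map,
      truth = list(
        genotypes = geno_true,
        gametes = gametes,
        dominant = dominant,
        distortion = distortion_truth,
        design = design
      )
    ),
    class = "f2_sim"
  )
}

#' Specify a quantitative trait architecture
#'
#' @param qtl data frame with columns `lg`, `position_cm`, `a` (additive
#'   effect of the cultivar allele) and `d` (dominance effect).
#' @param epistasis `NULL` or a data frame with columns `q1`, `q2` (row
#'   indices into `qtl`), `type` (`"aa"`, `"ad"`, `"da"`, `"dd"`) and
#'   `coef`.
#' @param env_var environmental (residual) variance; ignored when a
#'   target PVE is given to [simulate_trait()].
#' @param parent_means optional numeric `c(cultivar, wild)` trait means.
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(qtl, epistasis = NULL, env_var = 1,
                               parent_means = NULL) {
  stopifnot(
    is.data.frame(qtl),
    all(c("lg", "position_cm", "a", "d") %in% names(qtl)),
    env_var >= 0
  )
  if (!is.null(epistasis)) {
    stopifnot(
      is.data.frame(epistasis),
      all(c("q1", "q2", "type", "coef") %in% names(epistasis)),
      all(epistasis$type %in% c("aa", "ad", "da", "dd")),
      all(epistasis$q1 %in% seq_len(nrow(qtl))),
      all(epistasis$q2 %in% seq_len(nrow(qtl)))
    )
  }
  structure(list(qtl = qtl, epistasis = epistasis, env_var = env_var,
                 parent_means = parent_means),
            class = "trait_architecture")
}

## sample true QTL genotypes (0/1/2) at arbitrary map positions, phase-
## exact: per gamete, each QTL allele is drawn conditional on its nearest
## sampled/observed locus to the left and nearest marker to the right
.sample_qtl_genotypes <- function(sim, qtl) {
  stopifnot(inherits(sim, "f2_sim"))
  design <- sim$truth$design
  to_r <- .map_fun_r(design$map_function)
  n <- nrow(sim$geno)
  out <- matrix(0L, nrow = n, ncol = nrow(qtl))

  for (lg in unique(qtl$lg)) {
    qrows <- which(qtl$lg == lg)
    gam <- sim$truth$gametes[[lg]]
    if (is.null(gam)) stop("QTL on unknown linkage group: ", lg)
    mpos <- sim$map$position_cm[sim$map$linkage_group == lg]
    ord <- order(qtl$position_cm[qrows])
    for (gname in c("g1", "g2")) {
      g <- gam[[gname]]
      left_pos <- rep(-Inf, n); left_allele <- rep(NA_integer_, n)
      prev_qpos <- -Inf; prev_alleles <- NULL
      for (q in qrows[ord]) {
        qpos <- qtl$position_cm[q]
        li <- if (any(mpos <= qpos)) max(which(mpos <= qpos)) else NA_integer_
        ri <- if (any(mpos >= qpos)) min(which(mpos >= qpos)) else NA_integer_
        ## left anchor: nearest of (left marker, previously sampled QTL)
        if (!is.na(li) && mpos[li] >= prev_qpos) {
          lpos <- mpos[li]; lall <- g[, li]
        } else if (is.finite(prev_qpos)) {
          lpos <- prev_qpos; lall <- prev_alleles
        } else {
          lpos <- NA_real_; lall <- NULL
        }
        r1 <- if (is.na(lpos)) 0.5 else to_r(qpos - lpos)
        r2 <- if (is.na(ri)) 0.5 else to_r(mpos[ri] - qpos)
        rall <- if (is.na(ri)) rep(0L, n) else g[, ri]
        if (is.null(lall)) lall <- rep(0L, n)
        if (is.na(lpos) && is.na(ri)) {
          p1 <- rep(0.5, n)
        } else if (is.na(lpos)) {
          p1 <- ifelse(rall == 1L, 1 - r2, r2)
        } else if (is.na(ri)) {
          p1 <- ifelse(lall == 1L, 1 - r1, r1)
        } else {
          t1 <- ifelse(lall == 1L, 1 - r1, r1)       # P(q = 1 | left)
          t2q1 <- ifelse(rall == 1L, 1 - r2, r2)     # P(right | q = 1)
          t2q0 <- ifelse(rall == 1L, r2, 1 - r2)     # P(right | q = 0)
          p1 <- t1 * t2q1 / (t1 * t2q1 + (1 - t1) * t2q0)
        }
        allele <- as.integer(stats::runif(n) < p1)
        out[, match(q, seq_len(nrow(qtl)))] <-
          out[, match(q, seq_len(nrow(qtl)))] + allele
        prev_qpos <- qpos; prev_alleles <- allele
      }
    }
  }
  out
}

#' Simulate a quantitative trait on an F2 population
#'
#' Phenotype = sum of per-QTL effects (`a * x + d * z` with
#' `x in {-1, 0, 1}` counting cultivar alleles and `z in {0, 1, 0}` the
#' heterozygote indicator) + epistatic interaction terms + Gaussian noise.
#' If `target_pve` is given, the noise variance is solved so that the
#' genetic variance fraction matches it in expectation; otherwise
#' `arch$env_var` is used.
#'
#' @param arch a [trait_architecture()].
#' @param sim an `f2_sim` from [simulate_f2()].
#' @param target_pve optional proportion in `[0, 1)`.
#' @return list with `phenotype` (numeric vector), `realized_pve`
#'   (realised genetic variance fraction), `qtl_genotypes` (matrix of true
#'   0/1/2 genotypes at the QTL) and `sigma` (noise SD used).
#' @export
simulate_trait <- function(arch, sim, target_pve = NULL) {
  stopifnot(inherits(arch, "trait_architecture"), inherits(sim, "f2_sim"))
  if (!is.null(target_pve) && target_pve >= 1) {
    stop("target_pve must be < 1")
  }
  n <- nrow(sim$geno)
  if (nrow(arch$qtl) > 0) {
    qg <- .sample_qtl_genotypes(sim, arch$qtl)
    x <- qg - 1L
    z <- (qg == 1L) * 1
    g <- drop(x %*% arch$qtl$a + z %*% arch$qtl$d)
    if (!is.null(arch$epistasis)) {
      for (k in seq_len(nrow(arch$epistasis))) {
        e <- arch$epistasis[k, ]
        w1 <- if (substr(e$type, 1, 1) == "a") x[, e$q1] else z[, e$q1]
        w2 <- if (substr(e$type, 2, 2) == "a") x[, e$q2] else z[, e$q2]
        g <- g + e$coef * w1 * w2
      }
    }
  } else {
    qg <- matrix(integer(0), nrow = n, ncol = 0)
    g <- rep(0, n)
  }
  var_g <- stats::var(g)
  sigma2 <- if (is.null(target_pve)) {
    arch$env_var
  } else if (target_pve == 0 || var_g == 0) {
    if (var_g > 0) stop("target_pve = 0 with nonzero genetic variance")
    arch$env_var
  } else {
    var_g * (1 - target_pve) / target_pve
  }
  y <- g + stats::rnorm(n, 0, sqrt(sigma2))
  list(
    phenotype = as.numeric(y),
    realized_pve = if (stats::var(y) > 0) var_g / stats::var(y) else 0,
    qtl_genotypes = qg,
    sigma = sqrt(sigma2)
  )
}
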