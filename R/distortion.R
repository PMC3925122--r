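## Segregation-distortion and marker-distribution diagnostics.

## exact multinomial goodness-of-fit p (point-probability ordering),
## used as a flagged fallback when expected counts drop below 1
.exact_multinomial_p <- function(obs, prob) {
  n <- sum(obs)
  p_obs <- stats::dmultinom(obs, prob = prob)
  if (length(obs) == 2L) {
    px <- stats::dbinom(0:n, n, prob[1])
    return(sum(px[px <= p_obs + 1e-12]))
  }
  ## 3 classes: enumerate
  total <- 0
  for (i in 0:n) {
    j <- 0:(n - i)
    pj <- exp(lgamma(n + 1) - lgamma(i + 1) - lgamma(j + 1) -
                lgamma(n - i - j + 1) +
                i * log(prob[1]) + j * log(prob[2]) +
                (n - i - j) * log(prob[3]))
    total <- total + sum(pj[pj <= p_obs + 1e-12])
  }
  min(total, 1)
}

#' Test a marker for segregation distortion
#'
#' Chi-square goodness of fit of the observed genotype-class counts
#' against the Mendelian F2 expectation: 1:2:1 for codominant markers
#' (df = 2) and 3:1 for dominant-scored markers (df = 1). The direction
#' is called from the signed deviations (heterozygote excess when both
#' homozygote classes fall below expectation), and a significance tier
#' (`ns`, `0.05`, `0.01`, `0.001`) is assigned after Bonferroni
#' correction over `family` markers. When any expected count is below 1
#' the p-value comes from an exact multinomial test and the result is
#' flagged.
#'
#' @param calls character call vector for one marker.
#' @param type `"auto"` (default; dominant if any `AX`/`BX` call),
#'   `"codominant"` or `"dominant"`.
#' @param family Bonferroni family size (number of mapped markers);
#'   default 1 (no correction).
#' @return a one-row data frame: `n`, `chi2`, `df`, `p`, `direction`
#'   (`wild_excess`, `cultivar_excess`, `het_excess`, `none`), `tier`,
#'   `exact` (fallback flag).
#' @export
segregation_distortion <- function(calls,
                                   type = c("auto", "codominant", "dominant"),
                                   family = 1L) {
  type <- match.arg(type)
  calls <- calls[calls != "NN"]
  if (length(calls) < 10) stop("fewer than 10 non-missing calls")
  if (type == "auto") {
    type <- if (any(calls %in% c("AX", "BX"))) "dominant" else "codominant"
  }
  if (type == "codominant") {
    obs <- c(BB = sum(calls == "BB"), AB = sum(calls == "AB"),
             AA = sum(calls == "AA"))
    prob <- c(0.25, 0.5, 0.25)
  } else {
    if (any(calls == "AX")) {
      obs <- c(dom = sum(calls == "AX"), rec = sum(calls == "BB"))
    } else {
      obs <- c(dom = sum(calls == "BX"), rec = sum(calls == "AA"))
    }
    prob <- c(0.75, 0.25)
  }
  n <- sum(obs)
  expected <- n * prob
  chi2 <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  exact <- any(expected < 1)
  p <- if (exact) {
    .exact_multinomial_p(obs, prob)
  } else {
    stats::pchisq(chi2, df, lower.tail = FALSE)
  }

  dev <- obs - expected
  if (max(abs(dev)) < 1e-9) {
    direction <- "none"
  } else if (type == "codominant") {
    if (dev[["BB"]] < 0 && dev[["AA"]] < 0) {
      direction <- "het_excess"
    } else if (dev[["AA"]] >= dev[["BB"]]) {
      direction <- "cultivar_excess"
    } else {
      direction <- "wild_excess"
    }
  } else {
    ## dominant: which allele's phenotypic class is over-represented
    dom_is_A <- any(calls == "AX")
    over_dom <- dev[["dom"]] > 0
    direction <- if (xor(dom_is_A, over_dom)) "wild_excess" else "cultivar_excess"
  }

  p_adj <- min(p * family, 1)
  tier <- if (p_adj < 0.001) "0.001" else if (p_adj < 0.01) "0.01" else
    if (p_adj < 0.05) "0.05" else "ns"

  data.frame(n = n, chi2 = chi2, df = df, p = p, direction = direction,
             tier = tier, exact = exact)
}

#' Segregation-distortion scan over all markers
#'
#' Applies [segregation_distortion()] to every marker of a genotype
#' matrix, with the Bonferroni family set to the number of markers
#' tested.
#'
#' @param geno a [genotype_matrix()].
#' @param family Bonferroni family size; defaults to `ncol(geno)`.
#' @return data frame with one row per marker.
#' @export
distortion_scan <- function(geno, family = ncol(geno)) {
  out <- lapply(colnames(geno), function(m) {
    res <- segregation_distortion(geno[, m], family = family)
    cbind(marker = m, res)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Poisson goodness-of-fit test of marker distribution along a map
#'
#' Bins markers into fixed-width bins along each linkage group and
#' tests the bin counts against a Poisson distribution with mean equal
#' to the overall markers-per-bin rate, using Fisher's index of
#' dispersion: `chi2 = sum((obs - lambda)^2) / lambda` on
#' `n_bins - 1` degrees of freedom, upper tail. Marker clustering
#' inflates the dispersion index; regularly spaced markers deflate it
#' and are not flagged.
#'
#' @param map a `linkage_map` or map data frame
#'   (`linkage_group`, `marker`, `position_cm`).
#' @param bin_cm bin width in cM (default 10).
#' @return list with `chi2`, `df`, `p` (upper tail, sensitive to
#'   clustering), `n_bins`, `lambda`.
#' @export
marker_distribution_test <- function(map, bin_cm = 10) {
  df <- if (inherits(map, "linkage_map")) map$map else map
  by_lg <- split(df$position_cm, df$linkage_group)
  bin_counts <- unlist(lapply(by_lg, function(p) {
    len <- max(p) - min(p)
    nb <- max(1L, ceiling(len / bin_cm))
    breaks <- min(p) + seq(0, nb) * bin_cm
    breaks[nb + 1L] <- max(breaks[nb + 1L], max(p))
    tabulate(findInterval(p, breaks, rightmost.closed = TRUE), nbins = nb)
  }))
  n_bins <- length(bin_counts)
  if (n_bins < 5) stop("fewer than 5 bins; decrease bin_cm")
  lambda <- sum(bin_counts) / n_bins
  chi2 <- sum((bin_counts - lambda)^2) / lambda
  dof <- n_bins - 1L
  list(chi2 = chi2, df = dof,
       p = stats::pchisq(chi2, dof, lower.tail = FALSE),
       n_bins = n_bins, lambda = lambda)
}
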