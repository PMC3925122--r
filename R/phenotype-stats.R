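## Trait-level statistics: spine index, floret color change, parental
## comparisons, Spearman correlations with sequential Bonferroni,
## transgressive segregation, and genotype-ratio tests.

#' Standardized spine index
#'
#' Per leaf, the index is (number of spines per cm of leaf margin)
#' multiplied by the length of the longest spine; the plant value is the
#' mean across the sampled leaves.
#'
#' @param leaves data frame with columns `spine_count`, `margin_cm`,
#'   `longest_spine_cm` (one row per leaf).
#' @return the plant-level spine index.
#' @examples
#' spine_index(data.frame(spine_count = 10, margin_cm = 20,
#'                        longest_spine_cm = 0.5))  # 0.25
#' @export
spine_index <- function(leaves) {
  stopifnot(is.data.frame(leaves), nrow(leaves) >= 1,
            all(c("spine_count", "margin_cm", "longest_spine_cm") %in%
                  names(leaves)),
            all(leaves$spine_count >= 0),
            all(leaves$longest_spine_cm >= 0))
  if (any(leaves$margin_cm <= 0 & leaves$spine_count > 0)) {
    stop("leaf with spines but zero margin length")
  }
  idx <- ifelse(leaves$spine_count == 0, 0,
                leaves$spine_count / leaves$margin_cm *
                  leaves$longest_spine_cm)
  mean(idx)
}

#' Floret color change between flowering and maturity
#'
#' The difference in the CIE L*a*b* `a*` (red/green) coordinate between
#' maturity and flowering; positive values mean redder florets at
#' maturity.
#'
#' @param flowering,maturity lists or data frames with fields `a_star`
#'   and `stage` (`"flowering"` / `"maturity"`).
#' @return the signed change in `a*`.
#' @export
color_change <- function(flowering, maturity) {
  if (is.null(flowering$a_star) || is.null(maturity$a_star) ||
      is.na(flowering$a_star) || is.na(maturity$a_star)) {
    stop("both stages must carry an a* measurement")
  }
  if (!is.null(flowering$stage) && flowering$stage != "flowering") {
    stop("first argument must be the flowering-stage measurement")
  }
  if (!is.null(maturity$stage) && maturity$stage != "maturity") {
    stop("second argument must be the maturity-stage measurement")
  }
  maturity$a_star - flowering$a_star
}

#' Compare parental trait samples
#'
#' Screens both samples for normality (Shapiro-Wilk at 0.05); if both
#' pass, Welch's t-test, otherwise a two-sample Wilcoxon rank-sum test.
#' (The rank-sum test is the appropriate unpaired analogue of the
#' signed-rank test for independent parental samples.)
#'
#' @param cultivar,wild numeric trait samples.
#' @param alpha significance level for the difference (default 0.05).
#' @return one-row data frame: means, SDs, ns, `test`
#'   (`"welch_t"`/`"rank"`), `p`, `significant`.
#' @export
compare_parents <- function(cultivar, wild, alpha = 0.05) {
  cultivar <- cultivar[is.finite(cultivar)]
  wild <- wild[is.finite(wild)]
  stopifnot(length(cultivar) >= 3, length(wild) >= 3)
  zero_var <- stats::sd(cultivar) == 0 && stats::sd(wild) == 0
  if (zero_var) {
    p <- if (mean(cultivar) == mean(wild)) 1 else 0
    test <- "welch_t"
  } else {
    sw_ok <- function(x) {
      if (stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value >= 0.05
    }
    if (sw_ok(cultivar) && sw_ok(wild)) {
      test <- "welch_t"
      p <- stats::t.test(cultivar, wild, var.equal = FALSE)$p.value
    } else {
      test <- "rank"
      p <- stats::wilcox.test(cultivar, wild, exact = FALSE)$p.value
    }
  }
  data.frame(
    cultivar_mean = mean(cultivar), cultivar_sd = stats::sd(cultivar),
    cultivar_n = length(cultivar),
    wild_mean = mean(wild), wild_sd = stats::sd(wild),
    wild_n = length(wild),
    test = test, p = p, significant = p < alpha
  )
}

#' Spearman correlations with sequential Bonferroni (Holm) flags
#'
#' Pairwise Spearman rank correlations over all trait columns
#' (pairwise-complete observations), with Holm-adjusted significance
#' flags over the full family of trait pairs.
#'
#' @param traits numeric data frame or matrix (individuals x traits).
#' @param alpha family-wise level (default 0.05).
#' @param min_pairs minimum complete pairs per trait pair (default 3).
#' @return list with matrices `rho`, `p`, `p_holm` and logical
#'   `significant`; constant traits yield `NA` entries.
#' @export
spearman_holm <- function(traits, alpha = 0.05, min_pairs = 3) {
  traits <- as.data.frame(traits)
  k <- ncol(traits)
  rho <- p <- matrix(NA_real_, k, k,
                     dimnames = list(names(traits), names(traits)))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- traits[[i]]; y <- traits[[j]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 ||
          stats::sd(y[ok]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  upper <- upper.tri(p)
  p_adj_vec <- stats::p.adjust(p[upper], method = "holm")
  p_holm <- p
  p_holm[upper] <- p_adj_vec
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  list(rho = rho, p = p, p_holm = p_holm,
       significant = !is.na(p_holm) & p_holm < alpha)
}

#' Transgressive segregation flags
#'
#' Flags F2 individuals whose trait value exceeds the higher parent mean
#' by more than that parent's SD (`high`) or falls below the lower
#' parent mean by more than that parent's SD (`low`); a trait is
#' transgressive when any individual is flagged.
#'
#' @param f2 numeric vector of F2 trait values.
#' @param cultivar_mean,cultivar_sd,wild_mean,wild_sd parental summaries.
#' @return list with `high` and `low` logical vectors, counts
#'   `n_high` / `n_low`, and `transgressive`.
#' @export
transgressive <- function(f2, cultivar_mean, cultivar_sd,
                          wild_mean, wild_sd) {
  if (cultivar_mean >= wild_mean) {
    hi_mean <- cultivar_mean; hi_sd <- cultivar_sd
    lo_mean <- wild_mean; lo_sd <- wild_sd
  } else {
    hi_mean <- wild_mean; hi_sd <- wild_sd
    lo_mean <- cultivar_mean; lo_sd <- cultivar_sd
  }
  high <- !is.na(f2) & f2 > hi_mean + hi_sd
  low <- !is.na(f2) & f2 < lo_mean - lo_sd
  list(high = high, low = low, n_high = sum(high), n_low = sum(low),
       transgressive = any(high) || any(low))
}

#' Chi-square test of class counts against an expected ratio
#'
#' Pearson chi-square of observed class counts against a stated ratio
#' (e.g. 3:1), df = classes - 1; falls back to an exact multinomial
#' test (flagged) when any expected count is below 1.
#'
#' @param counts observed class counts.
#' @param ratio expected ratio, same length as `counts` (e.g.
#'   `c(3, 1)`).
#' @return list with `chi2`, `df`, `p`, `exact`.
#' @examples
#' ratio_test(c(207, 69), c(3, 1))  # chi2 = 0, p = 1
#' @export
ratio_test <- function(counts, ratio) {
  stopifnot(length(counts) == length(ratio), sum(counts) > 0,
            all(ratio > 0))
  prob <- ratio / sum(ratio)
  expected <- sum(counts) * prob
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  if (any(expected < 1)) {
    list(chi2 = chi2, df = df,
         p = .exact_multinomial_p(counts, prob), exact = TRUE)
  } else {
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE), exact = FALSE)
  }
}
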