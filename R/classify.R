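## QTL classification: mode of gene action from the dominance ratio,
## magnitude from the explained variance, and effect direction against
## the parental difference.

#' Classify the mode of gene action from the dominance ratio
#'
#' Applies the cutoffs
#' underdominant <= -1.25 < recessive <= -0.75 < partially recessive
#' <= -0.25 < additive < 0.25 <= partially dominant < 0.75 <= dominant
#' < 1.25 <= overdominant, where the ratio is the dominance effect of
#' the cultivar allele divided by its additive effect (d/a; -1 =
#' completely recessive cultivar allele, +1 = completely dominant).
#'
#' @param a additive effect(s); must be nonzero.
#' @param d dominance effect(s). Alternatively pass the ratio directly
#'   via `ratio`.
#' @param ratio optional d/a ratio(s), overriding `a`/`d`.
#' @return character vector of classes.
#' @examples
#' classify_gene_action(ratio = c(-0.79, 7.26, -21.68, 0))
#' @export
classify_gene_action <- function(a = NULL, d = NULL, ratio = NULL) {
  if (is.null(ratio)) {
    if (any(a == 0)) stop("dominance ratio undefined: additive effect is 0")
    ratio <- d / a
  }
  cut_points <- c(-Inf, -1.25, -0.75, -0.25, 0.25, 0.75, 1.25, Inf)
  labels <- c("underdominant", "recessive", "partially_recessive",
              "additive", "partially_dominant", "dominant", "overdominant")
  ## left-closed on the negative cutoffs, right-open on the positive ones:
  ## (-Inf,-1.25], (-1.25,-0.75], (-0.75,-0.25], (-0.25,0.25),
  ## [0.25,0.75), [0.75,1.25), [1.25,Inf)
  out <- character(length(ratio))
  out[ratio <= -1.25] <- "underdominant"
  out[ratio > -1.25 & ratio <= -0.75] <- "recessive"
  out[ratio > -0.75 & ratio <= -0.25] <- "partially_recessive"
  out[ratio > -0.25 & ratio < 0.25] <- "additive"
  out[ratio >= 0.25 & ratio < 0.75] <- "partially_dominant"
  out[ratio >= 0.75 & ratio < 1.25] <- "dominant"
  out[ratio >= 1.25] <- "overdominant"
  out
}

#' Classify QTL magnitude from the explained variance
#'
#' `"large"` when PVE > 25%, `"small"` when PVE < 10%, `"intermediate"`
#' in between (both boundaries inclusive to intermediate).
#'
#' @param pve percentage of segregating phenotypic variance explained,
#'   in `[0, 100]`.
#' @return character vector in `{"small", "intermediate", "large"}`.
#' @export
classify_magnitude <- function(pve) {
  if (any(pve < 0 | pve > 100)) stop("pve must be in [0, 100]")
  ifelse(pve > 25, "large", ifelse(pve < 10, "small", "intermediate"))
}

#' Direction of a QTL effect relative to the parental difference
#'
#' A QTL effect is in the `"expected"` direction when the sign of the
#' cultivar-allele additive effect matches the sign of
#' (cultivar mean - wild mean); `"wrong"` otherwise; `NA` when the
#' parents do not differ (or not significantly, if `significant` is
#' given).
#'
#' @param a additive effect(s) of the cultivar allele.
#' @param cultivar_mean,wild_mean parental trait means.
#' @param significant optional logical; `FALSE` forces `NA`.
#' @return character vector `"expected"` / `"wrong"` / `NA`.
#' @export
effect_direction <- function(a, cultivar_mean, wild_mean,
                             significant = TRUE) {
  diff_sign <- sign(cultivar_mean - wild_mean)
  out <- ifelse(sign(a) == diff_sign, "expected", "wrong")
  out[diff_sign == 0 | !significant] <- NA_character_
  out
}

#' Summary statistics of a QTL table
#'
#' Counts and interval summaries over a set of QTL records: total QTL,
#' traits with two or more QTL, mean/min/max 1-LOD interval width,
#' counts by magnitude class, and the extremes of the dominance ratio.
#' Arithmetic summaries are rounded to 1 decimal for reporting.
#'
#' @param records a `qtl_table` data frame with columns `trait`,
#'   `interval_lo`, `interval_hi`, `pve`, `dominance_ratio`.
#' @return list with `n_qtl`, `n_traits`, `multi_qtl_traits`,
#'   `mean_width_cm`, `min_width_cm`, `max_width_cm`,
#'   `n_small`, `n_intermediate`, `n_large`,
#'   `dominance_ratio_min`, `dominance_ratio_max` (all-`NA` for empty
#'   input).
#' @export
qtl_table_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(list(n_qtl = 0L, n_traits = 0L, multi_qtl_traits = 0L,
                mean_width_cm = NA_real_, min_width_cm = NA_real_,
                max_width_cm = NA_real_, n_small = NA_integer_,
                n_intermediate = NA_integer_, n_large = NA_integer_,
                dominance_ratio_min = NA_real_,
                dominance_ratio_max = NA_real_))
  }
  widths <- records$interval_hi - records$interval_lo
  per_trait <- table(records$trait)
  mag <- classify_magnitude(records$pve)
  list(
    n_qtl = nrow(records),
    n_traits = length(per_trait),
    multi_qtl_traits = sum(per_trait >= 2),
    mean_width_cm = round(mean(widths), 1),
    min_width_cm = round(min(widths), 1),
    max_width_cm = round(max(widths), 1),
    n_small = sum(mag == "small"),
    n_intermediate = sum(mag == "intermediate"),
    n_large = sum(mag == "large"),
    dominance_ratio_min = round(min(records$dominance_ratio, na.rm = TRUE), 1),
    dominance_ratio_max = round(max(records$dominance_ratio, na.rm = TRUE), 1)
  )
}

#' Annotate a QTL table with classifications
#'
#' Adds `gene_action` ([classify_gene_action()]), `magnitude`
#' ([classify_magnitude()]) and, when a parent summary table is given,
#' `direction` ([effect_direction()]).
#'
#' @param records a `qtl_table` with columns `additive`,
#'   `dominance_ratio`, `pve`, `trait`.
#' @param parents optional data frame with columns `trait`,
#'   `cultivar_mean`, `wild_mean` and (optionally) `significant`.
#' @return the annotated `qtl_table`.
#' @export
annotate_qtl <- function(records, parents = NULL) {
  records$gene_action <- classify_gene_action(ratio = records$dominance_ratio)
  records$magnitude <- classify_magnitude(records$pve)
  if (!is.null(parents)) {
    idx <- match(records$trait, parents$trait)
    signif <- if ("significant" %in% names(parents)) {
      parents$significant[idx]
    } else TRUE
    records$direction <- effect_direction(
      records$additive,
      parents$cultivar_mean[idx],
      parents$wild_mean[idx],
      significant = ifelse(is.na(signif), FALSE, signif)
    )
    records$direction[is.na(idx)] <- NA_character_
  }
  records
}
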