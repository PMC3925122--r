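## Genome-wide two-locus epistasis scan with orthogonal contrasts on the
## nine F2 genotype classes.

#' Epistasis-scan configuration
#'
#' The genome-wide significance threshold divides the comparison-wise
#' error rate by the number of linkage-group pairs, `g(g-1)/2` for `g`
#' haploid linkage groups (`0.05 / 66` for `g = 12`).
#'
#' @param alpha comparison-wise error rate (default 0.05).
#' @param g haploid number of linkage groups (default 12).
#' @param same_lg_min_cm pairs on the same linkage group closer than
#'   this distance are excluded to avoid linkage-driven artifacts
#'   (default 20 cM).
#' @return an object of class `epistasis_config` with the derived
#'   `threshold`.
#' @export
epistasis_config <- function(alpha = 0.05, g = 12, same_lg_min_cm = 20) {
  stopifnot(alpha > 0, alpha < 1, g >= 2)
  structure(
    list(alpha = alpha, g = as.integer(g),
         threshold = alpha / (g * (g - 1) / 2),
         same_lg_min_cm = same_lg_min_cm),
    class = "epistasis_config"
  )
}

#' Collapse markers with identical segregation patterns
#'
#' Markers whose call vectors are identical (including the missing-data
#' pattern) are joined into a single haplotype, represented by the
#' lexicographically smallest member id.
#'
#' @param geno a [genotype_matrix()].
#' @return list with `geno` (the collapsed [genotype_matrix()]) and
#'   `mapping` (data frame `marker`, `haplotype`).
#' @export
collapse_identical <- function(geno) {
  key <- apply(unclass(geno), 2, paste, collapse = "")
  groups <- split(colnames(geno), key)
  reps <- vapply(groups, function(ms) sort(ms)[1], "")
  mapping <- data.frame(
    marker = unlist(groups, use.names = FALSE),
    haplotype = rep(reps, lengths(groups))
  )
  mapping <- mapping[order(mapping$marker), , drop = FALSE]
  rownames(mapping) <- NULL
  keep <- sort(unique(mapping$haplotype))
  list(geno = genotype_matrix(unclass(geno)[, keep, drop = FALSE]),
       mapping = mapping)
}

## per-locus contrast scores: additive (-1, 0, 1), dominance
## (-0.5, 1, -0.5) over (BB, AB, AA); NA for dominant/missing codes
.contrast_scores <- function(calls) {
  xa <- c(AA = 1, AB = 0, BB = -1)[calls]
  xd <- c(AA = -0.5, AB = 1, BB = -0.5)[calls]
  list(a = unname(xa), d = unname(xd))
}

#' Genome-wide two-locus interaction scan
#'
#' For every pair of codominant haplotypes (dominant-scored markers are
#' excluded), fits the two-locus linear model with per-locus additive
#' `(-1, 0, 1)` and dominance `(-0.5, 1, -0.5)` contrasts and their four
#' products (aa, ad, da, dd), and reports each interaction component's
#' estimate and p-value. A pair is significant when any component
#' p-value falls below the genome-wide threshold. Pairs on the same
#' linkage group closer than `config$same_lg_min_cm` are skipped, and a
#' component whose genotype cells are empty is reported `NA`.
#'
#' @param geno a (collapsed) [genotype_matrix()].
#' @param phenotype numeric vector.
#' @param map map data frame assigning markers to linkage groups.
#' @param config an [epistasis_config()].
#' @param markers optional subset of marker ids to scan.
#' @return data frame with columns `hap_a`, `hap_b`, `lg_a`, `lg_b`,
#'   `component`, `estimate`, `p`, `significant` (4 rows per pair).
#' @export
pair_scan <- function(geno, phenotype, map, config = epistasis_config(),
                      markers = NULL) {
  df <- if (inherits(map, "linkage_map")) map$map else map
  calls <- unclass(geno)
  if (is.null(markers)) markers <- colnames(calls)
  ## codominant only
  dominant <- .is_dominant_marker(geno)
  markers <- markers[!dominant[match(markers, colnames(calls))]]
  lg <- df$linkage_group[match(markers, df$marker)]
  pos <- df$position_cm[match(markers, df$marker)]
  out <- list()
  nm <- length(markers)
  for (i in seq_len(nm - 1L)) {
    for (j in (i + 1L):nm) {
      if (!is.na(lg[i]) && !is.na(lg[j]) && lg[i] == lg[j] &&
          abs(pos[i] - pos[j]) < config$same_lg_min_cm) next
      ci <- calls[, markers[i]]
      cj <- calls[, markers[j]]
      keep <- ci != "NN" & cj != "NN" & is.finite(phenotype)
      si <- .contrast_scores(ci[keep])
      sj <- .contrast_scores(cj[keep])
      y <- phenotype[keep]
      X <- cbind(a1 = si$a, d1 = si$d, a2 = sj$a, d2 = sj$d,
                 aa = si$a * sj$a, ad = si$a * sj$d,
                 da = si$d * sj$a, dd = si$d * sj$d)
      fit <- stats::lm(y ~ X)
      cf <- summary(fit)$coefficients
      comp <- c("aa", "ad", "da", "dd")
      rows <- paste0("X", comp)
      est <- p <- rep(NA_real_, 4)
      present <- rows %in% rownames(cf)
      est[present] <- cf[rows[present], "Estimate"]
      p[present] <- cf[rows[present], "Pr(>|t|)"]
      out[[length(out) + 1L]] <- data.frame(
        hap_a = markers[i], hap_b = markers[j],
        lg_a = lg[i], lg_b = lg[j],
        component = comp, estimate = est, p = p,
        significant = !is.na(p) & p < config$threshold
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    hap_a = character(0), hap_b = character(0), lg_a = character(0),
    lg_b = character(0), component = character(0), estimate = numeric(0),
    p = numeric(0), significant = logical(0))
  rownames(res) <- NULL
  res
}

#' Count significant interactions with same-LG-pair collapsing
#'
#' Significant interaction results are grouped by unordered
#' linkage-group pair; each pair is counted once (multiple interactions
#' among loci on the same pair of linkage groups reflect linkage, not
#' independent epistasis).
#'
#' @param results output of [pair_scan()] (one trait).
#' @return list with `n_interactions` (distinct LG pairs with a
#'   significant component), `lg_pairs` (their labels) and
#'   `component_counts` (significant components by type).
#' @export
count_interactions <- function(results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(n_interactions = 0L, lg_pairs = character(0),
                component_counts = c(aa = 0L, ad = 0L, da = 0L, dd = 0L)))
  }
  pair_key <- apply(cbind(sig$lg_a, sig$lg_b), 1,
                    function(x) paste(sort(x), collapse = ":"))
  comp_counts <- vapply(c("aa", "ad", "da", "dd"), function(cc) {
    sum(sig$component == cc)
  }, 0L)
  list(n_interactions = length(unique(pair_key)),
       lg_pairs = sort(unique(pair_key)),
       component_counts = comp_counts)
}
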