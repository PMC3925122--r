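## Comparative QTL colocalization across two species bridged through an
## intermediary genome: BLAST hit filtering, locus bridging, synteny
## blocks, interval projection, and hypergeometric / Fisher combined
## probability tests.

#' Filter BLAST hits: top two per query below an e-value threshold
#'
#' Per query locus, hits with e-value strictly below `max_evalue` are
#' sorted by (e-value ascending, bit score descending, subject id
#' ascending) and the top `top_n` are retained.
#'
#' @param hits data frame of 12-column tabular BLAST hits (see
#'   [read_blast6()]).
#' @param max_evalue e-value cutoff (default `1e-6`, strict).
#' @param top_n hits retained per query (default 2).
#' @return the filtered hit data frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-6, top_n = 2) {
  keep <- hits$evalue < max_evalue
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                     FUN = seq_along)
  out <- hits[rank <= top_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bridge loci of two species through shared intermediary scaffolds
#'
#' A locus pair (a, b) is emitted whenever a retained hit of `a` and a
#' retained hit of `b` share a subject scaffold; one-to-many pairs are
#' permitted.
#'
#' @param hits_a,hits_b filtered hit tables ([filter_hits()]) of the two
#'   species against the intermediary genome.
#' @return data frame `locus_a`, `locus_b`, `scaffold` (unique rows).
#' @export
bridge_loci <- function(hits_a, hits_b) {
  m <- merge(
    unique(data.frame(locus_a = hits_a$qseqid, scaffold = hits_a$sseqid)),
    unique(data.frame(locus_b = hits_b$qseqid, scaffold = hits_b$sseqid)),
    by = "scaffold"
  )
  out <- unique(m[, c("locus_a", "locus_b", "scaffold")])
  out <- out[order(out$locus_a, out$locus_b, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call synteny blocks from bridged locus pairs
#'
#' Bridged pairs are grouped by linkage-group pair; groups with at least
#' `min_loci` distinct locus pairs become synteny blocks. Orientation is
#' the sign of the Spearman correlation of the paired map positions
#' (`same`, `inverted`, or `mixed` for zero/undefined correlation).
#'
#' @param pairs bridged pairs from [bridge_loci()].
#' @param map_a,map_b map data frames (`linkage_group`, `marker`,
#'   `position_cm`) for the two species; loci are matched on `marker`.
#' @param min_loci minimum distinct locus pairs per block (default 3).
#' @return list of `synteny_block` objects, each a list with `lg_a`,
#'   `lg_b`, `loci` (data frame `locus_a`, `pos_a`, `locus_b`, `pos_b`,
#'   `scaffold`), `n_loci`, `orientation`.
#' @export
call_synteny <- function(pairs, map_a, map_b, min_loci = 3) {
  pa <- match(pairs$locus_a, map_a$marker)
  pb <- match(pairs$locus_b, map_b$marker)
  ok <- !is.na(pa) & !is.na(pb)
  df <- data.frame(
    locus_a = pairs$locus_a[ok], locus_b = pairs$locus_b[ok],
    scaffold = pairs$scaffold[ok],
    lg_a = map_a$linkage_group[pa[ok]], pos_a = map_a$position_cm[pa[ok]],
    lg_b = map_b$linkage_group[pb[ok]], pos_b = map_b$position_cm[pb[ok]]
  )
  key <- paste(df$lg_a, df$lg_b, sep = "\r")
  blocks <- lapply(split(df, key), function(sub) {
    loci <- unique(sub[, c("locus_a", "pos_a", "locus_b", "pos_b",
                           "scaffold")])
    n_pairs <- nrow(unique(loci[, c("locus_a", "locus_b")]))
    if (n_pairs < min_loci) return(NULL)
    rho <- suppressWarnings(
      stats::cor(loci$pos_a, loci$pos_b, method = "spearman"))
    orientation <- if (is.na(rho) || rho == 0) "mixed" else
      if (rho > 0) "same" else "inverted"
    structure(
      list(lg_a = sub$lg_a[1], lg_b = sub$lg_b[1], loci = loci,
           n_loci = n_pairs, orientation = orientation),
      class = "synteny_block"
    )
  })
  blocks <- Filter(Negate(is.null), blocks)
  names(blocks) <- NULL
  blocks
}

#' Project a map interval through a synteny block
#'
#' Positions at shared loci project exactly; positions between shared
#' loci by linear interpolation; positions beyond the outermost shared
#' locus extrapolate with the overall slope of the block (the ratio of
#' the block lengths on the two maps, signed by orientation). The
#' result is clipped to `[0, lg_length]` when a target linkage-group
#' length is supplied.
#'
#' @param interval numeric `c(lo, hi)` on the source map.
#' @param block a `synteny_block` from [call_synteny()].
#' @param from `"a"` (default) to project from species A to B, or
#'   `"b"` for the reverse.
#' @param lg_length optional length of the target linkage group for
#'   clipping.
#' @return numeric `c(lo, hi)` on the target map (lo <= hi).
#' @export
project_interval <- function(interval, block, from = c("a", "b"),
                             lg_length = NULL) {
  from <- match.arg(from)
  loci <- block$loci
  if (from == "a") {
    x <- loci$pos_a; yy <- loci$pos_b
  } else {
    x <- loci$pos_b; yy <- loci$pos_a
  }
  ## collapse duplicate source positions
  agg <- stats::aggregate(yy, by = list(x = x), FUN = mean)
  x <- agg$x
  yy <- agg[[2]]
  ord <- order(x)
  x <- x[ord]; yy <- yy[ord]
  span_x <- max(x) - min(x)
  span_y <- max(yy) - min(yy)
  if (span_x <= 0 || span_y <= 0) {
    stop("synteny block has zero span on one of the maps")
  }
  slope <- (yy[length(yy)] - yy[1]) / (x[length(x)] - x[1])
  proj1 <- function(p) {
    if (p < min(x)) return(yy[1] + (p - x[1]) * slope)
    if (p > max(x)) return(yy[length(yy)] + (p - x[length(x)]) * slope)
    stats::approx(x, yy, xout = p, ties = mean)$y
  }
  out <- sort(vapply(interval, proj1, 0))
  if (!is.null(lg_length)) out <- pmin(pmax(out, 0), lg_length)
  out
}

#' Detect colocalized QTL between two species
#'
#' Projects each species-B QTL through the synteny block on its linkage
#' group (when several blocks qualify, the one sharing the most loci and
#' overlapping the interval is used) and declares a colocalization when
#' same-trait intervals overlap on the species-A map within that block's
#' A-side linkage group. Each A-QTL is counted once even when it
#' overlaps several projected B-QTL.
#'
#' @param qtl_a data frame of species-A QTL (`trait`, `linkage_group`,
#'   `interval_lo`, `interval_hi`).
#' @param qtl_b same for species B (B-map coordinates).
#' @param blocks list of `synteny_block`s ([call_synteny()]).
#' @return list with `matches` (data frame `trait`, `lg`, `a_index`,
#'   `b_index`) and `colocalized` (data frame `trait`,
#'   `n_colocalized_a`, the once-per-A-QTL counts).
#' @export
detect_colocalization <- function(qtl_a, qtl_b, blocks) {
  matches <- list()
  for (bi in seq_len(nrow(qtl_b))) {
    qb <- qtl_b[bi, ]
    cand <- Filter(function(bl) bl$lg_b == qb$linkage_group, blocks)
    if (!length(cand)) next
    ## prefer blocks overlapping the interval, then most shared loci
    span_ok <- vapply(cand, function(bl) {
      min(bl$loci$pos_b) <= qb$interval_hi &&
        max(bl$loci$pos_b) >= qb$interval_lo
    }, TRUE)
    if (any(span_ok)) cand <- cand[span_ok]
    cand <- cand[order(-vapply(cand, function(b) as.numeric(b$n_loci), 0))]
    bl <- cand[[1]]
    proj <- project_interval(c(qb$interval_lo, qb$interval_hi), bl,
                             from = "b")
    hits <- which(
      qtl_a$trait == qb$trait &
        qtl_a$linkage_group == bl$lg_a &
        qtl_a$interval_lo <= proj[2] &
        qtl_a$interval_hi >= proj[1]
    )
    for (ai in hits) {
      matches[[length(matches) + 1L]] <- data.frame(
        trait = qb$trait, lg = bl$lg_a, a_index = ai, b_index = bi)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else data.frame(
    trait = character(0), lg = character(0), a_index = integer(0),
    b_index = integer(0))
  coloc <- if (nrow(matches)) {
    agg <- stats::aggregate(a_index ~ trait, matches,
                            function(x) length(unique(x)))
    names(agg)[2] <- "n_colocalized_a"
    agg
  } else data.frame(trait = character(0), n_colocalized_a = integer(0))
  list(matches = matches, colocalized = coloc)
}

#' Hypergeometric probability of QTL colocalization
#'
#' The point probability of observing exactly `m` colocalizing QTL when
#' `l` and `s` QTL (larger and smaller sample) are placed among `n`
#' comparable genomic intervals, sampling without replacement:
#' `C(l, m) * C(n - l, s - m) / C(n, s)`. The upper-tail probability
#' `P(X >= m)` is also returned.
#'
#' @param n number of comparable intervals (genome size divided by the
#'   mean QTL interval size for the trait).
#' @param m number of colocalizing QTL.
#' @param l QTL count in the larger sample.
#' @param s QTL count in the smaller sample.
#' @return list with `p_point` and `p_tail`.
#' @examples
#' hypergeom_p(n = 10, m = 2, l = 4, s = 3)$p_point  # 0.3
#' @export
hypergeom_p <- function(n, m, l, s) {
  stopifnot(n >= 1, l >= 0, s >= 0, m >= 0)
  if (l > n || s > n) stop("l and s must not exceed n")
  if (m > min(l, s)) stop("m must not exceed min(l, s)")
  point <- function(mm) {
    if (s - mm > n - l) return(0)
    exp(lchoose(l, mm) + lchoose(n - l, s - mm) - lchoose(n, s))
  }
  p_point <- point(m)
  p_tail <- sum(vapply(m:min(l, s), point, 0))
  list(p_point = p_point, p_tail = min(p_tail, 1))
}

#' Per-trait colocalization test
#'
#' Builds the (n, m, l, s) counts for a trait and computes the
#' hypergeometric probabilities: `n` is the genome size divided by the
#' mean QTL interval width for the trait (rounded to the nearest
#' integer), `l`/`s` the larger/smaller QTL sample sizes, `m` the
#' colocalizing count.
#'
#' @param n_qtl_a,n_qtl_b QTL counts for the trait in the two species.
#' @param m colocalizing QTL count.
#' @param genome_cm genome (map) size in cM.
#' @param mean_qtl_cm mean QTL interval width for the trait in cM.
#' @return one-row data frame `n`, `m`, `l`, `s`, `p_point`, `p_tail`.
#' @export
colocalization_test <- function(n_qtl_a, n_qtl_b, m, genome_cm,
                                mean_qtl_cm) {
  stopifnot(mean_qtl_cm > 0, genome_cm > 0)
  n <- max(round(genome_cm / mean_qtl_cm), 1)
  l <- max(n_qtl_a, n_qtl_b)
  s <- min(n_qtl_a, n_qtl_b)
  hp <- hypergeom_p(n, m, l, s)
  data.frame(n = n, m = m, l = l, s = s,
             p_point = hp$p_point, p_tail = hp$p_tail)
}

#' Fisher's combined probability test
#'
#' `X = -2 * sum(log(p))` compared to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return list with `X`, `df`, `p_combined`.
#' @examples
#' fisher_combined(c(0.05, 0.05))  # X = 11.98, p ~ 0.0175
#' @export
fisher_combined <- function(p) {
  if (any(p <= 0)) stop("p-values must be > 0 (floor them first)")
  if (any(p > 1)) stop("p-values must be <= 1")
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(X = X, df = df,
       p_combined = stats::pchisq(X, df, lower.tail = FALSE))
}

#' Direction concordance of a colocalized QTL pair
#'
#' `"concordant"` when the cultivar-allele effect signs agree in the two
#' species, `"discordant"` when they differ, `NA` when either sign is
#' missing or zero.
#'
#' @param sign_a,sign_b effect signs (or signed effects) in species A
#'   and B.
#' @return character vector.
#' @export
direction_concordance <- function(sign_a, sign_b) {
  sa <- sign(sign_a); sb <- sign(sign_b)
  out <- ifelse(sa == sb, "concordant", "discordant")
  out[is.na(sa) | is.na(sb) | sa == 0 | sb == 0] <- NA_character_
  out
}
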