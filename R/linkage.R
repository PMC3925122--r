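## Recombination-fraction estimation and linkage-map construction.

## Tabulate 36-class counts for marker pairs. `ci`, `cj`: integer-coded
## call columns (1..6). Pairs with a missing call at either locus are
## dropped (pairwise deletion).
.pair_counts <- function(ci, cj) {
  keep <- ci != 6L & cj != 6L
  tabulate((ci[keep] - 1L) * 6L + cj[keep], nbins = 36L)
}

## EM over many pairs at once. `counts`: 36 x npairs matrix.
## Returns list(rf, lod, n, info) per pair.
.rf_em <- function(counts, max_iter = 200L, tol = 1e-8, start = 0.25) {
  tl <- .two_locus_tables
  npair <- ncol(counts)
  n_pair <- colSums(counts)
  r <- rep(start, npair)
  p16 <- function(r) {
    ## 16 x npairs: 0.25 * r^k * (1-r)^(2-k)
    0.25 * t(outer(r, tl$k, `^`) * outer(1 - r, 2 - tl$k, `^`))
  }
  for (iter in seq_len(max_iter)) {
    p <- p16(r)
    denom <- crossprod(tl$comp, p)     # 36 x npairs: class probs
    numer <- crossprod(tl$comp_k, p)   # expected rec gametes, unnormalised
    ratio <- numer / denom
    ratio[denom == 0] <- 0
    e_rec <- colSums(counts * ratio)
    r_new <- ifelse(n_pair > 0, e_rec / (2 * n_pair), start)
    r_new <- pmin(pmax(r_new, 1e-9), 0.5)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }
  loglik <- function(r) {
    denom <- crossprod(tl$comp, p16(r))
    lp <- log(denom)
    lp[denom == 0] <- 0 # classes with zero prob carry zero counts
    colSums(counts * lp)
  }
  ll_hat <- loglik(r)
  ll_null <- loglik(rep(0.5, npair))
  lod <- pmax((ll_hat - ll_null) / log(10), 0)
  ## observed Fisher information at r-hat (numeric second derivative);
  ## weakly informative configurations (e.g. dominant x dominant in
  ## repulsion) yield small values
  h <- 1e-4
  r0 <- pmin(pmax(r, h), 0.5 - h)
  info <- -(loglik(r0 + h) - 2 * loglik(r0) + loglik(r0 - h)) / h^2
  info[!is.finite(info)] <- 0
  list(rf = r, lod = lod, n = n_pair, info = pmax(info, 0))
}

#' Estimate the recombination fraction between two markers
#'
#' Maximum-likelihood estimation by EM over the F2 two-locus
#' genotype-class likelihood (two independent gametes, phase known from
#' the inbred AA x BB parents). Handles codominant and dominant-scored
#' calls; missing calls are dropped pairwise. The LOD score is
#' `log10 L(r-hat) / L(0.5)`.
#'
#' @param col_a,col_b character call vectors for the two markers (same
#'   individuals, codes from [GENO_CODES]).
#' @param max_iter,tol EM controls (default 200 iterations, `|dr| < 1e-8`,
#'   start at `r = 0.25`).
#' @return a list of class `pair_linkage` with `rf`, `lod`,
#'   `n_informative`, `info` (observed Fisher information at `rf`) and
#'   `low_confidence` (fewer than 10 informative pairs, or information
#'   below 10).
#' @export
estimate_rf <- function(col_a, col_b, max_iter = 200L, tol = 1e-8) {
  stopifnot(length(col_a) == length(col_b))
  ci <- match(col_a, GENO_CODES)
  cj <- match(col_b, GENO_CODES)
  if (anyNA(ci) || anyNA(cj)) stop("invalid genotype code")
  counts <- matrix(.pair_counts(ci, cj), ncol = 1)
  fit <- .rf_em(counts, max_iter = max_iter, tol = tol)
  structure(
    list(rf = fit$rf, lod = fit$lod, n_informative = fit$n,
         info = fit$info,
         low_confidence = fit$n < 10 || fit$info < 10),
    class = "pair_linkage"
  )
}

#' @export
print.pair_linkage <- function(x, ...) {
  cat(sprintf("pair_linkage: rf = %.4f, LOD = %.2f, n = %d%s\n",
              x$rf, x$lod, x$n_informative,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' All pairwise recombination fractions
#'
#' Vectorised EM over every marker pair of a genotype matrix.
#'
#' @param geno a [genotype_matrix()].
#' @inheritParams estimate_rf
#' @return data frame with columns `marker_a`, `marker_b`, `rf`, `lod`,
#'   `n_informative`.
#' @export
rf_matrix <- function(geno, max_iter = 200L, tol = 1e-8) {
  gi <- .geno_int(geno)
  m <- ncol(gi)
  pairs <- utils::combn(m, 2L)
  counts <- matrix(0L, nrow = 36L, ncol = ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    counts[, p] <- .pair_counts(gi[, pairs[1L, p]], gi[, pairs[2L, p]])
  }
  fit <- .rf_em(counts, max_iter = max_iter, tol = tol)
  data.frame(
    marker_a = colnames(gi)[pairs[1L, ]],
    marker_b = colnames(gi)[pairs[2L, ]],
    rf = fit$rf,
    lod = fit$lod,
    n_informative = fit$n
  )
}

#' Partition markers into linkage groups
#'
#' Transitive closure of the pairwise relation
#' `lod >= min_lod & rf <= max_rf`; singleton groups are allowed.
#'
#' @param pairs data frame as returned by [rf_matrix()].
#' @param markers optional character vector of all marker ids (defaults
#'   to those present in `pairs`).
#' @param min_lod,max_rf grouping thresholds (defaults 5.0 and 0.4).
#' @return list of character vectors, one per group, ordered by
#'   decreasing size then first marker id.
#' @export
group_markers <- function(pairs, markers = NULL, min_lod = 5, max_rf = 0.4) {
  if (is.null(markers)) {
    markers <- unique(c(pairs$marker_a, pairs$marker_b))
  }
  parent <- seq_along(markers)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  linked <- pairs$lod >= min_lod & pairs$rf <= max_rf
  ia <- match(pairs$marker_a[linked], markers)
  ib <- match(pairs$marker_b[linked], markers)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  root <- vapply(seq_along(markers), find, integer(1))
  groups <- split(markers, root)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
  unname(groups[ord])
}

## sum of adjacent rf along an order
.adj_rf_sum <- function(order_idx, rf_mat) {
  if (length(order_idx) < 2L) return(0)
  sum(rf_mat[cbind(order_idx[-length(order_idx)], order_idx[-1L])])
}

#' Order the markers of a linkage group
#'
#' Greedy seriation: seed with the marker pair of largest recombination
#' fraction (the putative ends), insert each remaining marker at the slot
#' minimising the sum of adjacent rf, then "ripple" refinement (sliding
#' window of 3, keeping any permutation that lowers the adjacent-rf sum).
#' Deterministic: ties break on lexicographic marker id, and the final
#' order is canonicalised so the lexicographically smaller terminal
#' marker comes first.
#'
#' @param markers character vector of marker ids in the group.
#' @param pairs pairwise rf table ([rf_matrix()]) covering the group.
#' @return character vector: the ordered markers.
#' @export
order_group <- function(markers, pairs) {
  markers <- sort(markers)
  m <- length(markers)
  if (m <= 2L) return(markers)
  rf_mat <- matrix(0.5, m, m, dimnames = list(markers, markers))
  sel <- pairs$marker_a %in% markers & pairs$marker_b %in% markers
  pp <- pairs[sel, , drop = FALSE]
  rf_mat[cbind(pp$marker_a, pp$marker_b)] <- pp$rf
  rf_mat[cbind(pp$marker_b, pp$marker_a)] <- pp$rf
  diag(rf_mat) <- 0

  ## seed: pair with the largest rf (ties -> lexicographically first pair)
  best <- which(rf_mat == max(rf_mat), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  ord <- c(best[[1]], best[[2]])
  remaining <- setdiff(seq_len(m), ord)
  ## place the marker most strongly linked to the current order first
  while (length(remaining) > 0) {
    min_rf <- vapply(remaining, function(i) min(rf_mat[i, ord]), 0)
    nxt <- remaining[order(min_rf, markers[remaining])][1]
    k <- length(ord)
    cost <- numeric(k + 1L)
    cost[1] <- rf_mat[nxt, ord[1]]
    cost[k + 1L] <- rf_mat[ord[k], nxt]
    if (k > 1L) {
      for (s in 2:k) {
        cost[s] <- rf_mat[ord[s - 1L], nxt] + rf_mat[nxt, ord[s]] -
          rf_mat[ord[s - 1L], ord[s]]
      }
    }
    s <- which.min(cost)
    ord <- append(ord, nxt, after = s - 1L)
    remaining <- setdiff(remaining, nxt)
  }

  ## refinement: 2-opt segment reversals (repairs reversed blocks the
  ## greedy insertion can lock in) interleaved with window-of-3 ripple
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  edge <- function(i, j) {
    if (i < 1L || i > m || j < 1L || j > m) 0 else rf_mat[ord[i], ord[j]]
  }
  repeat {
    improved <- FALSE
    ## 2-opt: reverse ord[i..j] when it lowers the adjacent-rf sum
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        delta <- edge(i - 1L, j) + edge(i, j + 1L) -
          edge(i - 1L, i) - edge(j, j + 1L)
        if (delta < -1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    ## ripple: window-of-3 permutations
    for (s in seq_len(m - 2L)) {
      window <- s:(s + 2L)
      base <- ord
      best_sum <- .adj_rf_sum(ord, rf_mat)
      for (p in perms[-1]) {
        cand <- base
        cand[window] <- base[window][p]
        cand_sum <- .adj_rf_sum(cand, rf_mat)
        if (cand_sum < best_sum - 1e-12) {
          ord <- cand
          best_sum <- cand_sum
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  out <- markers[ord]
  if (out[length(out)] < out[1]) out <- rev(out)
  out
}

#' Cumulative map positions from adjacent recombination fractions
#'
#' @param rf_adj adjacent recombination fractions along an ordered group,
#'   each in `[0, 0.5)`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return numeric positions in cM starting at 0.
#' @export
map_positions <- function(rf_adj, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (length(rf_adj) == 0) return(0)
  if (any(rf_adj >= 0.5)) {
    stop("adjacent recombination fraction of 0.5: infinite map distance")
  }
  c(0, cumsum(.map_fun_d(map_function)(rf_adj)))
}

#' Build a linkage map from a genotype matrix
#'
#' Runs pairwise rf estimation, LOD/rf grouping, greedy seriation with
#' ripple refinement per group, and cumulative map-distance calculation.
#' Groups are named `A`, `B`, ... in order of decreasing marker count.
#'
#' @param geno a [genotype_matrix()].
#' @param min_lod,max_rf grouping thresholds (defaults 5.0 / 0.4).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return a list of class `linkage_map` with elements `map` (data frame
#'   `linkage_group`, `marker`, `position_cm`), `pairs` (the pairwise rf
#'   table) and `map_function`.
#' @export
build_map <- function(geno, min_lod = 5, max_rf = 0.4,
                      map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  pairs <- rf_matrix(geno)
  groups <- group_markers(pairs, markers = colnames(geno),
                          min_lod = min_lod, max_rf = max_rf)
  rf_lookup <- new.env(parent = emptyenv())
  assign_rf <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    get0(key, envir = rf_lookup, ifnotfound = 0.5)
  }
  for (i in seq_len(nrow(pairs))) {
    key <- paste(sort(c(pairs$marker_a[i], pairs$marker_b[i])),
                 collapse = "\r")
    assign(key, pairs$rf[i], envir = rf_lookup)
  }
  out <- list()
  for (g in seq_along(groups)) {
    ord <- order_group(groups[[g]], pairs)
    rf_adj <- if (length(ord) > 1) {
      vapply(seq_len(length(ord) - 1L),
             function(i) assign_rf(ord[i], ord[i + 1L]), 0)
    } else numeric(0)
    rf_adj <- pmin(rf_adj, 0.5 - 1e-9)
    pos <- map_positions(rf_adj, map_function)
    lg_name <- if (g <= 26) LETTERS[g] else paste0("LG", g)
    out[[g]] <- data.frame(linkage_group = lg_name, marker = ord,
                           position_cm = pos)
  }
  structure(
    list(map = do.call(rbind, out), pairs = pairs,
         map_function = map_function),
    class = "linkage_map"
  )
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- summarize_map(x)
  cat(sprintf(
    "linkage_map: %d markers in %d groups, %.1f cM total (mean spacing %s cM)\n",
    s$n_markers, s$n_groups, s$total_cm,
    ifelse(is.na(s$mean_spacing_cm), "NA", format(s$mean_spacing_cm))))
  invisible(x)
}

#' Summarize a linkage map
#'
#' Totals for a map: group and marker counts, total length, and mean and
#' maximum inter-marker interval. The mean spacing is
#' `total length / (markers - groups)`, reported as `NA` when every
#' group is a singleton.
#'
#' @param map a `linkage_map` object or a data frame with columns
#'   `linkage_group`, `marker`, `position_cm`.
#' @return list with `n_groups`, `n_markers`, `total_cm`,
#'   `mean_spacing_cm`, `max_spacing_cm`, and per-group lengths
#'   (`group_lengths`).
#' @export
summarize_map <- function(map) {
  df <- if (inherits(map, "linkage_map")) map$map else map
  stopifnot(all(c("linkage_group", "marker", "position_cm") %in% names(df)))
  if (nrow(df) == 0) stop("empty map")
  by_lg <- split(df$position_cm, df$linkage_group)
  lens <- vapply(by_lg, function(p) max(p) - min(p), 0)
  gaps <- unlist(lapply(by_lg, function(p) diff(sort(p))))
  n_groups <- length(by_lg)
  n_markers <- nrow(df)
  total <- sum(lens)
  list(
    n_groups = n_groups,
    n_markers = n_markers,
    total_cm = total,
    mean_spacing_cm = if (n_markers > n_groups) {
      total / (n_markers - n_groups)
    } else NA_real_,
    max_spacing_cm = if (length(gaps)) max(gaps) else NA_real_,
    group_lengths = lens
  )
}
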