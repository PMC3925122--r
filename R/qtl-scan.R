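## Composite interval mapping with background cofactors and
## permutation-based genome-wide significance thresholds.

#' Scan configuration for composite interval mapping
#'
#' @param step_cm test-position spacing in cM (default 2).
#' @param window_cm exclusion window around the test position inside
#'   which cofactors are dropped (default 10).
#' @param max_cofactors maximum number of background cofactors
#'   (default 5).
#' @param n_permutations permutations for the genome-wide threshold
#'   (default 1000).
#' @param alpha significance levels for the threshold (default
#'   `c(0.05, 0.10)`).
#' @param peak_lod_drop LOD decline required between adjacent peaks for
#'   them to be called separate QTL (default 2).
#' @param seed integer seed used for the permutations.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(step_cm = 2, window_cm = 10, max_cofactors = 5,
                        n_permutations = 1000, alpha = c(0.05, 0.10),
                        peak_lod_drop = 2, seed = 1L) {
  stopifnot(step_cm > 0, window_cm >= 0, max_cofactors >= 0,
            n_permutations >= 100, all(alpha > 0), all(alpha < 1),
            peak_lod_drop >= 0)
  structure(
    list(step_cm = step_cm, window_cm = window_cm,
         max_cofactors = max_cofactors,
         n_permutations = as.integer(n_permutations),
         alpha = sort(alpha), peak_lod_drop = peak_lod_drop,
         seed = as.integer(seed)),
    class = "scan_config"
  )
}

## residual sum of squares of y on design X (with intercept prepended)
.rss <- function(X, y) {
  Xi <- if (is.null(X)) {
    matrix(1, length(y), 1L)
  } else {
    cbind(1, X)
  }
  fit <- stats::lm.fit(Xi, y)
  sum(fit$residuals^2)
}

#' Select background cofactor markers by stepwise regression
#'
#' Forward selection followed by backward elimination, scoring each
#' marker by the joint F-test of its additive + dominance codings.
#' Forward entry requires the candidate's p-value to clear
#' `alpha_enter` after Bonferroni adjustment for the number of
#' candidates (so a pure-noise phenotype yields an empty set);
#' backward elimination removes markers whose nominal p-value exceeds
#' `alpha_stay`. At most `max_cofactors` markers are retained.
#'
#' @param geno a [genotype_matrix()].
#' @param phenotype numeric vector (one value per individual).
#' @param max_cofactors cap on the selected set (default 5).
#' @param alpha_enter,alpha_stay entry / stay levels (defaults
#'   0.05 and 0.10).
#' @return character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(geno, phenotype, max_cofactors = 5,
                             alpha_enter = 0.05, alpha_stay = 0.10) {
  stopifnot(length(phenotype) == nrow(geno))
  ok <- is.finite(phenotype)
  if (sum(ok) < 20) stop("fewer than 20 phenotyped individuals")
  gi <- .geno_int(geno[ok, , drop = FALSE])
  y <- phenotype[ok]
  n <- length(y)
  m <- ncol(gi)
  sc <- .marker_scores(gi)
  X <- matrix(c(sc$x, sc$z), nrow = n)  # n x 2m: additive then dominance
  xa <- X[, seq_len(m), drop = FALSE]
  xd <- X[, m + seq_len(m), drop = FALSE]

  marker_cols <- function(j) cbind(xa[, j], xd[, j])
  selected <- integer(0)

  ## forward steps
  repeat {
    if (length(selected) >= max_cofactors) break
    base <- if (length(selected)) {
      do.call(cbind, lapply(selected, marker_cols))
    } else NULL
    rss0 <- .rss(base, y)
    df0 <- n - 1L - 2L * length(selected)
    cand <- setdiff(seq_len(m), selected)
    pvals <- vapply(cand, function(j) {
      Xj <- cbind(base, marker_cols(j))
      rss1 <- .rss(Xj, y)
      df1 <- df0 - 2L
      if (df1 <= 0 || rss1 <= 0) return(1)
      f <- ((rss0 - rss1) / 2) / (rss1 / df1)
      stats::pf(f, 2, df1, lower.tail = FALSE)
    }, 0)
    best <- which.min(pvals)
    if (pvals[best] * length(cand) > alpha_enter) break
    selected <- c(selected, cand[best])
  }

  ## backward elimination
  repeat {
    if (length(selected) <= 1) break
    full <- do.call(cbind, lapply(selected, marker_cols))
    rss_full <- .rss(full, y)
    df_full <- n - 1L - 2L * length(selected)
    pvals <- vapply(seq_along(selected), function(k) {
      Xk <- do.call(cbind, lapply(selected[-k], marker_cols))
      rss_red <- .rss(Xk, y)
      if (df_full <= 0 || rss_full <= 0) return(0)
      f <- ((rss_red - rss_full) / 2) / (rss_full / df_full)
      stats::pf(f, 2, df_full, lower.tail = FALSE)
    }, 0)
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha_stay) break
    selected <- selected[-worst]
  }

  colnames(gi)[selected]
}

## internal: precompute per-LG scan scaffolding shared across scans of
## the same genotype data
.scan_prep <- function(geno, map, step_cm, map_function) {
  gi <- .geno_int(geno)
  lgs <- unique(map$linkage_group)
  prep <- list()
  for (lg in lgs) {
    sub <- map[map$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$position_cm), , drop = FALSE]
    mcols <- match(sub$marker, colnames(gi))
    if (anyNA(mcols)) stop("map marker absent from genotypes: ",
                           paste(sub$marker[is.na(mcols)], collapse = ", "))
    lg_len <- max(sub$position_cm)
    pos <- unique(c(seq(0, lg_len, by = step_cm), lg_len))
    prep[[lg]] <- list(markers = sub$marker, mpos = sub$position_cm,
                       mcols = mcols, pos = pos)
  }
  list(gi = gi, prep = prep, map_function = map_function)
}

## expected additive / dominance codings at one position of one LG
.position_codings <- function(sp, lg, p) {
  pr <- sp$prep[[lg]]
  li <- if (any(pr$mpos <= p)) max(which(pr$mpos <= p)) else
    min(which(pr$mpos >= p))
  ri <- if (any(pr$mpos >= p)) min(which(pr$mpos >= p)) else
    max(which(pr$mpos <= p))
  to_r <- .map_fun_r(sp$map_function)
  r1 <- to_r(abs(p - pr$mpos[li]))
  r2 <- to_r(abs(pr$mpos[ri] - p))
  cl <- sp$gi[, pr$mcols[li]]
  cr <- sp$gi[, pr$mcols[ri]]
  probs <- .flank_class_probs(r1, r2)     # 3 x 36 (qq, Qq, QQ)
  cls <- (cl - 1L) * 6L + cr
  x <- (probs[3, ] - probs[1, ])[cls]
  z <- probs[2, ][cls]
  list(x = x, z = z)
}

#' Composite interval mapping scan
#'
#' At each test position, the phenotype is regressed on the expected
#' additive and dominance codings of the putative QTL genotype
#' (conditional on the flanking marker calls) plus the background
#' cofactors, excluding any cofactor within `window_cm` of the test
#' position on the same linkage group. The LOD score is
#' `n/2 * log10(RSS_reduced / RSS_full)` against the cofactor-only
#' model, and the per-position PVE is `1 - RSS_full / RSS_reduced`
#' (in percent).
#'
#' @param geno a [genotype_matrix()].
#' @param phenotype numeric vector.
#' @param map map data frame (`linkage_group`, `marker`, `position_cm`)
#'   or `linkage_map` object.
#' @param config a [scan_config()].
#' @param cofactors character vector of cofactor marker ids, or `NULL`
#'   to select them with [select_cofactors()].
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return data frame of class `cim_scan` with columns `linkage_group`,
#'   `position_cm`, `lod`, `a`, `d`, `pve`; the cofactors used are in
#'   `attr(, "cofactors")`.
#' @export
cim_scan <- function(geno, phenotype, map, config = scan_config(),
                     cofactors = NULL,
                     map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  df <- if (inherits(map, "linkage_map")) map$map else map
  ok <- is.finite(phenotype)
  geno_ok <- geno[ok, , drop = FALSE]
  y <- phenotype[ok]
  n <- length(y)
  if (is.null(cofactors)) {
    cofactors <- select_cofactors(geno_ok, y,
                                  max_cofactors = config$max_cofactors)
  }
  sp <- .scan_prep(geno_ok, df, config$step_cm, map_function)
  gi <- sp$gi
  sc <- .marker_scores(gi)
  m <- ncol(gi)
  cof_idx <- match(cofactors, colnames(gi))
  cof_X <- if (length(cof_idx)) {
    do.call(cbind, lapply(cof_idx, function(j) {
      cbind(matrix(sc$x, nrow = n)[, j], matrix(sc$z, nrow = n)[, j])
    }))
  } else NULL
  cof_lg <- df$linkage_group[match(cofactors, df$marker)]
  cof_pos <- df$position_cm[match(cofactors, df$marker)]

  red_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(sp$prep))
  for (g in seq_along(sp$prep)) {
    lg <- names(sp$prep)[g]
    pr <- sp$prep[[lg]]
    np <- length(pr$pos)
    lod <- a <- d <- pve <- numeric(np)
    for (i in seq_len(np)) {
      p <- pr$pos[i]
      keep <- if (length(cof_idx)) {
        !(cof_lg == lg & abs(cof_pos - p) < config$window_cm)
      } else logical(0)
      W <- if (any(keep)) {
        cof_X[, rep(which(keep) * 2L, each = 2L) - c(1L, 0L), drop = FALSE]
      } else NULL
      key <- paste0("k", paste(which(keep), collapse = ","))
      rss_red <- get0(key, envir = red_cache, ifnotfound = NULL)
      if (is.null(rss_red)) {
        rss_red <- .rss(W, y)
        assign(key, rss_red, envir = red_cache)
      }
      cz <- .position_codings(sp, lg, p)
      fit <- stats::lm.fit(cbind(1, cz$x, cz$z, W), y)
      rss_full <- sum(fit$residuals^2)
      lod[i] <- if (rss_red <= 1e-12) {
        0
      } else if (rss_full <= 1e-12) {
        Inf
      } else {
        max(n / 2 * log10(rss_red / rss_full), 0)
      }
      a[i] <- fit$coefficients[2]
      d[i] <- fit$coefficients[3]
      pve[i] <- if (rss_red <= 1e-12) 0 else
        100 * max(1 - rss_full / rss_red, 0)
    }
    rows[[g]] <- data.frame(linkage_group = lg, position_cm = pr$pos,
                            lod = lod, a = a, d = d, pve = pve)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cofactors") <- cofactors
  attr(out, "n") <- n
  class(out) <- c("cim_scan", "data.frame")
  out
}

## batched genome-wide maximum LOD for many phenotype columns at once
## (no cofactors): per position, RSS_full via the QR projection of
## [1, x, z], RSS_reduced from the intercept-only model
.batch_max_lod <- function(geno, Y, map, config,
                           map_function = "haldane") {
  sp <- .scan_prep(geno, map, config$step_cm, map_function)
  n <- nrow(Y)
  yss <- colSums(Y^2)
  rss_red <- pmax(yss - n * colMeans(Y)^2, 1e-12)
  max_lod <- rep(0, ncol(Y))
  for (lg in names(sp$prep)) {
    for (p in sp$prep[[lg]]$pos) {
      cz <- .position_codings(sp, lg, p)
      qr_x <- qr(cbind(1, cz$x, cz$z))
      Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
      rss_full <- pmax(yss - colSums(crossprod(Q, Y)^2), 1e-12)
      lod <- n / 2 * log10(rss_red / rss_full)
      max_lod <- pmax(max_lod, lod)
    }
  }
  max_lod
}

#' Genome-wide permutation thresholds for QTL significance
#'
#' Shuffles the phenotype across individuals, rescans the genome,
#' records the genome-wide maximum LOD per permutation, and returns the
#' empirical `1 - alpha` quantiles. With cofactors enabled
#' (`config$max_cofactors > 0`) every permutation repeats the full
#' procedure including stepwise cofactor re-selection; with
#' `max_cofactors = 0` the scan reduces to interval mapping and the
#' permutations run through a fast batched least-squares path (same
#' statistic, vectorised over permutations).
#'
#' @inheritParams cim_scan
#' @return numeric vector of thresholds named by alpha level, with the
#'   permutation maxima in `attr(, "max_lod")`.
#' @export
permutation_threshold <- function(geno, phenotype, map,
                                  config = scan_config(),
                                  map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  df <- if (inherits(map, "linkage_map")) map$map else map
  ok <- is.finite(phenotype)
  geno <- geno[ok, , drop = FALSE]
  y <- phenotype[ok]
  set.seed(config$seed)
  if (config$max_cofactors == 0) {
    Y <- vapply(seq_len(config$n_permutations), function(b) sample(y),
                numeric(length(y)))
    maxima <- .batch_max_lod(geno, Y, df, config, map_function)
  } else {
    maxima <- vapply(seq_len(config$n_permutations), function(b) {
      yb <- sample(y)
      sc_b <- cim_scan(geno, yb, df, config, cofactors = NULL,
                       map_function = map_function)
      max(sc_b$lod)
    }, 0)
  }
  ## empirical (1 - alpha) quantile as the order statistic
  ## X(floor(N(1-alpha)) + 1): exactly floor(N*alpha) permutation maxima
  ## exceed the threshold, so an exchangeable genome scan exceeds it
  ## with probability floor(N*alpha)/(N+1) -- the nominal alpha without
  ## the anti-conservative bias of interpolating quantile estimators
  sorted <- sort(maxima)
  N <- length(sorted)
  k <- pmin(floor(N * (1 - config$alpha)) + 1, N)
  thr <- sorted[k]
  names(thr) <- format(config$alpha)
  attr(thr, "max_lod") <- maxima
  thr
}

#' Call QTL from a scan profile
#'
#' Local maxima above the (largest-alpha) permutation threshold become
#' QTL; two maxima on one linkage group are separate QTL only if the
#' profile dips at least `peak_lod_drop` LOD below the lower of the two
#' peaks between them. The 1-LOD support interval is the contiguous run
#' of positions around the peak with LOD within 1 of the peak, clipped
#' at the linkage-group ends. Records are tiered by the most stringent
#' alpha threshold they exceed.
#'
#' @param profile a `cim_scan` data frame.
#' @param thresholds named thresholds from [permutation_threshold()]
#'   (or a single number).
#' @param map optional map data frame used to attach the nearest marker.
#' @param config a [scan_config()] (for `peak_lod_drop`).
#' @param trait trait name stored in the output.
#' @return data frame of class `qtl_table`, one row per QTL: `trait`,
#'   `linkage_group`, `position_cm`, `nearest_marker`, `interval_lo`,
#'   `interval_hi`, `lod`, `additive`, `dominance`, `dominance_ratio`,
#'   `pve`, `tier`.
#' @export
call_qtl <- function(profile, thresholds, map = NULL,
                     config = scan_config(), trait = "trait") {
  thr <- sort(unlist(thresholds), decreasing = TRUE)
  detect_thr <- min(thr)
  strict_thr <- max(thr)
  mapdf <- if (inherits(map, "linkage_map")) map$map else map
  records <- list()
  for (lg in unique(profile$linkage_group)) {
    sub <- profile[profile$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$position_cm), , drop = FALSE]
    lodv <- sub$lod
    np <- length(lodv)
    if (np == 0) next
    is_peak <- vapply(seq_len(np), function(i) {
      left <- if (i > 1) lodv[i - 1] else -Inf
      right <- if (i < np) lodv[i + 1] else -Inf
      lodv[i] >= left && lodv[i] > right || (i == np && lodv[i] > left)
    }, TRUE)
    cand <- which(is_peak & lodv >= detect_thr)
    if (!length(cand)) next
    cand <- cand[order(-lodv[cand])]
    accepted <- integer(0)
    for (i in cand) {
      sep <- TRUE
      for (jj in accepted) {
        lo <- min(i, jj); hi <- max(i, jj)
        valley <- min(lodv[lo:hi])
        lower_peak <- min(lodv[i], lodv[jj])
        if (valley > lower_peak - config$peak_lod_drop) {
          sep <- FALSE
          break
        }
      }
      if (sep) accepted <- c(accepted, i)
    }
    for (i in sort(accepted)) {
      peak_lod <- lodv[i]
      lo_i <- i
      while (lo_i > 1 && lodv[lo_i - 1] >= peak_lod - 1) lo_i <- lo_i - 1
      hi_i <- i
      while (hi_i < np && lodv[hi_i + 1] >= peak_lod - 1) hi_i <- hi_i + 1
      nearest <- NA_character_
      if (!is.null(mapdf)) {
        msub <- mapdf[mapdf$linkage_group == lg, , drop = FALSE]
        nearest <- msub$marker[which.min(abs(msub$position_cm -
                                               sub$position_cm[i]))]
      }
      records[[length(records) + 1L]] <- data.frame(
        trait = trait,
        linkage_group = lg,
        position_cm = sub$position_cm[i],
        nearest_marker = nearest,
        interval_lo = sub$position_cm[lo_i],
        interval_hi = sub$position_cm[hi_i],
        lod = peak_lod,
        additive = sub$a[i],
        dominance = sub$d[i],
        dominance_ratio = if (sub$a[i] != 0) sub$d[i] / sub$a[i] else NA_real_,
        pve = sub$pve[i],
        tier = if (peak_lod >= strict_thr) min(as.numeric(names(thr))) else
          max(as.numeric(names(thr)))
      )
    }
  }
  out <- if (length(records)) do.call(rbind, records) else data.frame(
    trait = character(0), linkage_group = character(0),
    position_cm = numeric(0), nearest_marker = character(0),
    interval_lo = numeric(0), interval_hi = numeric(0), lod = numeric(0),
    additive = numeric(0), dominance = numeric(0),
    dominance_ratio = numeric(0), pve = numeric(0), tier = numeric(0)
  )
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}
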