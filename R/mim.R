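## Multiple interval mapping: joint multi-QTL fit and backward model
## refinement under the information criterion IC(k) = -2(log L - k log(n)/2).

#' Information criterion for a multiple-QTL model
#'
#' `IC(k) = -2 * (log L - k * log(n) / 2)` with natural logs, where `k`
#' is the number of QTL effect parameters and `n` the sample size.
#'
#' @param logL model log-likelihood (natural log).
#' @param k number of QTL effect parameters.
#' @param n sample size.
#' @return the IC value.
#' @examples
#' mim_ic(-100, 0, 276)  # 200
#' mim_ic(-100, 2, 276)  # 200 + 2 log(276) = 211.241
#' @export
mim_ic <- function(logL, k, n) {
  -2 * (logL - k * log(n) / 2)
}

## gaussian log-likelihood of a least-squares fit
.gauss_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

## expected (x, z) codings for a set of QTL positions
.qtl_codings <- function(geno, map, qtl, map_function) {
  df <- if (inherits(map, "linkage_map")) map$map else map
  sp <- .scan_prep(geno, df, step_cm = 1, map_function = map_function)
  xs <- zs <- matrix(0, nrow = nrow(geno), ncol = nrow(qtl))
  for (q in seq_len(nrow(qtl))) {
    cz <- .position_codings(sp, qtl$linkage_group[q], qtl$position_cm[q])
    xs[, q] <- cz$x
    zs[, q] <- cz$z
  }
  list(x = xs, z = zs)
}

#' Refine a CIM model by multiple interval mapping
#'
#' Jointly fits all called QTL (additive + dominance codings expected
#' from the flanking markers) and performs backward elimination: a QTL
#' is retained only if removing it increases the information criterion.
#' QTL closer than 1 cM on the same linkage group (or with collinear
#' codings) are merged, keeping the higher-LOD member, with a warning.
#'
#' @param qtl a `qtl_table` from [call_qtl()].
#' @param geno a [genotype_matrix()].
#' @param phenotype numeric vector.
#' @param map map data frame or `linkage_map`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return a list of class `mim_model`: `qtl` (the retained records,
#'   with refitted `additive`, `dominance`, `dominance_ratio`), `logL`,
#'   `k`, `n`, `ic`, and `dropped` (trait/LG/position of removed QTL).
#' @export
mim_refine <- function(qtl, geno, phenotype, map,
                       map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  ok <- is.finite(phenotype)
  geno <- geno[ok, , drop = FALSE]
  y <- phenotype[ok]
  n <- length(y)

  ## merge (near-)collinear QTL positions
  if (nrow(qtl) > 1) {
    qtl <- qtl[order(qtl$linkage_group, qtl$position_cm), , drop = FALSE]
    keep <- rep(TRUE, nrow(qtl))
    for (i in seq_len(nrow(qtl) - 1L)) {
      if (!keep[i]) next
      j <- i + 1L
      if (qtl$linkage_group[j] == qtl$linkage_group[i] &&
          abs(qtl$position_cm[j] - qtl$position_cm[i]) < 1) {
        drop_i <- if (qtl$lod[j] >= qtl$lod[i]) i else j
        keep[drop_i] <- FALSE
        warning("merged collinear QTL positions on LG ",
                qtl$linkage_group[i])
      }
    }
    qtl <- qtl[keep, , drop = FALSE]
  }

  fit_model <- function(rows) {
    k <- 2L * length(rows)
    if (length(rows) == 0) {
      rss <- sum((y - mean(y))^2)
      return(list(logL = .gauss_loglik(rss, n), k = 0L,
                  ic = mim_ic(.gauss_loglik(rss, n), 0L, n), coefs = NULL))
    }
    cz <- .qtl_codings(geno, map, qtl[rows, , drop = FALSE], map_function)
    X <- cbind(1, do.call(cbind, lapply(seq_along(rows), function(q) {
      cbind(cz$x[, q], cz$z[, q])
    })))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    logL <- .gauss_loglik(rss, n)
    list(logL = logL, k = k, ic = mim_ic(logL, k, n),
         coefs = fit$coefficients)
  }

  active <- seq_len(nrow(qtl))
  dropped <- integer(0)
  current <- fit_model(active)
  repeat {
    if (length(active) == 0) break
    trials <- lapply(seq_along(active), function(k) fit_model(active[-k]))
    ics <- vapply(trials, `[[`, 0, "ic")
    best <- which.min(ics)
    if (ics[best] < current$ic) {
      dropped <- c(dropped, active[best])
      active <- active[-best]
      current <- trials[[best]]
    } else break
  }

  out_qtl <- qtl[active, , drop = FALSE]
  if (nrow(out_qtl) > 0 && !is.null(current$coefs)) {
    a_hat <- current$coefs[seq(2, by = 2, length.out = nrow(out_qtl))]
    d_hat <- current$coefs[seq(3, by = 2, length.out = nrow(out_qtl))]
    out_qtl$additive <- a_hat
    out_qtl$dominance <- d_hat
    out_qtl$dominance_ratio <- ifelse(a_hat != 0, d_hat / a_hat, NA_real_)
  }
  rownames(out_qtl) <- NULL
  structure(
    list(qtl = out_qtl, logL = current$logL, k = current$k, n = n,
         ic = current$ic,
         dropped = qtl[dropped, c("trait", "linkage_group", "position_cm"),
                       drop = FALSE]),
    class = "mim_model"
  )
}

#' @export
print.mim_model <- function(x, ...) {
  cat(sprintf("mim_model: %d QTL retained (k = %d, n = %d, IC = %.3f)\n",
              nrow(x$qtl), x$k, x$n, x$ic))
  if (nrow(x$dropped) > 0) {
    cat("  dropped:", nrow(x$dropped), "QTL\n")
  }
  invisible(x)
}
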