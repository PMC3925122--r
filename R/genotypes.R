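#' Construct a genotype matrix
#'
#' A `genotype_matrix` is a character matrix of calls (rows = F2
#' individuals, columns = markers) over the alphabet in [GENO_CODES].
#' Markers scored as dominant carry `AX` or `BX` calls; `NN` marks
#' missing data.
#'
#' @param calls character matrix of calls with row names (individuals)
#'   and column names (markers).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    stop("`calls` must be a character matrix")
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("M%03d", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("F2_%04d", seq_len(nrow(calls)))
  }
  if (anyDuplicated(colnames(calls))) {
    stop("duplicate marker ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  }
  bad <- !(calls %in% GENO_CODES)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' at individual '%s', marker '%s'",
                 calls[w[1], w[2]], rownames(calls)[w[1]],
                 colnames(calls)[w[2]]))
  }
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers\n",
              nrow(x), ncol(x)))
  tab <- table(factor(unclass(x), levels = GENO_CODES))
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

## integer codes 1..6 for internal vectorised work
.geno_int <- function(calls) {
  m <- matrix(match(unclass(calls), GENO_CODES),
              nrow = nrow(calls), dimnames = dimnames(calls))
  if (anyNA(m)) stop("invalid genotype code")
  m
}

## is a marker dominant-scored (carries any AX/BX call)?
.is_dominant_marker <- function(calls) {
  apply(unclass(calls), 2, function(col) any(col %in% c("AX", "BX")))
}

## numeric additive (x in [-1,1]) and dominance (z in [0,1]) scores per
## call under the marginal F2 prior; used for cofactor / epistasis designs
.marker_scores <- function(code_int) {
  ## order AA AB BB AX BX NN
  x_tab <- c(1, 0, -1, 1 / 3, -1 / 3, 0)
  z_tab <- c(0, 1, 0, 2 / 3, 2 / 3, 0.5)
  list(x = x_tab[code_int], z = z_tab[code_int])
}
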