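## Core F2 two-gamete transition model shared by the simulator, the
## recombination-fraction EM, and the interval-mapping scanner.
##
## Conventions used throughout the package:
##   * allele A = cultivar allele, allele B = wild allele;
##   * a genotype is the number of A alleles (0 = BB, 1 = AB, 2 = AA);
##   * observed calls come from the 6-letter alphabet AA/AB/BB/AX/BX/NN,
##     where AX = "AA or AB" and BX = "BB or AB" (dominant scoring) and
##     NN = missing.

#' Genotype call alphabet
#'
#' The six call codes accepted in a genotype matrix: the three codominant
#' classes `AA`, `AB`, `BB` (A = cultivar allele), the two dominant
#' ambiguity classes `AX` ("AA or AB") and `BX` ("BB or AB"), and `NN`
#' for missing data.
#'
#' @export
GENO_CODES <- c("AA", "AB", "BB", "AX", "BX", "NN")

## compatibility of true genotype g (rows: 0,1,2 copies of A) with each code
.code_compat <- matrix(
  c(
    ## AA AB BB AX BX NN
    0, 0, 1, 0, 1, 1, # g = 0 (BB)
    0, 1, 0, 1, 1, 1, # g = 1 (AB)
    1, 0, 0, 1, 0, 1  # g = 2 (AA)
  ),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("g0", "g1", "g2"), GENO_CODES)
)

#' Map functions: recombination fraction to centimorgans and back
#'
#' `haldane_d()`/`haldane_r()` implement the Haldane map function
#' (no crossover interference), `kosambi_d()`/`kosambi_r()` the Kosambi
#' function. Distances are in centimorgans.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return `*_d()` return cM distances; `*_r()` recombination fractions.
#' @examples
#' haldane_d(0.1)          # 11.157...
#' haldane_r(haldane_d(0.3))
#' @export
haldane_d <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
}

#' @rdname haldane_d
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-d / 50))
}

#' @rdname haldane_d
#' @export
kosambi_d <- function(r) {
  stopifnot(all(r >= 0), all(r <= 0.5))
  ifelse(r >= 0.5, Inf, 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname haldane_d
#' @export
kosambi_r <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * tanh(d / 50)
}

.map_fun_d <- function(map_function = c("haldane", "kosambi")) {
  switch(match.arg(map_function), haldane = haldane_d, kosambi = kosambi_d)
}

.map_fun_r <- function(map_function = c("haldane", "kosambi")) {
  switch(match.arg(map_function), haldane = haldane_r, kosambi = kosambi_r)
}

## ---------------------------------------------------------------------------
## Two-locus tables (recombination-fraction EM).
##
## A gamete haplotype at two loci is (aL, aR) with alleles in {0, 1}
## (1 = A). An F2 individual is two independent gametes; there are 16
## ordered gamete pairs. Pr(pair) = 0.25 * r^k * (1-r)^(2-k) where k is
## the number of recombinant gametes in the pair.

.two_locus_tables <- local({
  hap <- expand.grid(aL = 0:1, aR = 0:1)
  rec <- as.integer(hap$aL != hap$aR)
  idx <- expand.grid(i = 1:4, j = 1:4)
  k <- rec[idx$i] + rec[idx$j]                   # recombinant gametes (0/1/2)
  gL <- hap$aL[idx$i] + hap$aL[idx$j]
  gR <- hap$aR[idx$i] + hap$aR[idx$j]
  ## 36 observed-class columns: class (cL, cR) -> column (cL-1)*6 + cR
  comp <- matrix(0, nrow = 16, ncol = 36)
  for (cL in 1:6) {
    for (cR in 1:6) {
      comp[, (cL - 1L) * 6L + cR] <-
        .code_compat[gL + 1L, cL] * .code_compat[gR + 1L, cR]
    }
  }
  list(k = k, comp = comp, comp_k = comp * k)
})

## class-pair probabilities (36-vector) at recombination fraction r
.pair_class_probs <- function(r) {
  p16 <- 0.25 * r^.two_locus_tables$k * (1 - r)^(2 - .two_locus_tables$k)
  drop(crossprod(.two_locus_tables$comp, p16))
}

## ---------------------------------------------------------------------------
## Three-locus tables (flanking-marker genotype probabilities at a test
## position). Haplotypes are (aL, aQ, aR); transitions L->Q and Q->R carry
## recombination fractions r1 and r2 with no interference.

.three_locus_tables <- local({
  hap <- expand.grid(aL = 0:1, aQ = 0:1, aR = 0:1)
  recL <- as.integer(hap$aL != hap$aQ)
  recR <- as.integer(hap$aQ != hap$aR)
  idx <- expand.grid(i = 1:8, j = 1:8)
  gL <- hap$aL[idx$i] + hap$aL[idx$j]
  gQ <- hap$aQ[idx$i] + hap$aQ[idx$j]
  gR <- hap$aR[idx$i] + hap$aR[idx$j]
  comp_q <- lapply(0:2, function(g) {
    m <- matrix(0, nrow = 64, ncol = 36)
    for (cL in 1:6) {
      for (cR in 1:6) {
        m[, (cL - 1L) * 6L + cR] <-
          .code_compat[gL + 1L, cL] * .code_compat[gR + 1L, cR] * (gQ == g)
      }
    }
    m
  })
  list(recL = recL, recR = recR, i = idx$i, j = idx$j, comp_q = comp_q)
})

## 3 x 36 matrix of conditional Pr(Q genotype | observed flank class),
## columns indexed by (cL-1)*6 + cR; columns for impossible classes are NaN.
.flank_class_probs <- function(r1, r2) {
  tl <- .three_locus_tables
  ph <- 0.5 *
    r1^tl$recL * (1 - r1)^(1 - tl$recL) *
    r2^tl$recR * (1 - r2)^(1 - tl$recR)
  p64 <- ph[tl$i] * ph[tl$j]
  pr <- rbind(
    drop(crossprod(tl$comp_q[[1]], p64)),
    drop(crossprod(tl$comp_q[[2]], p64)),
    drop(crossprod(tl$comp_q[[3]], p64))
  )
  sweep(pr, 2, colSums(pr), "/")
}

#' Conditional QTL genotype probabilities between flanking markers
#'
#' Computes the F2 conditional probabilities of the three genotype classes
#' (`qq`, `Qq`, `QQ`; `Q` = cultivar allele) at a test position, given the
#' observed calls at the two flanking markers, under the two-gamete
#' transition model with no interference. Ambiguous (`AX`, `BX`) and
#' missing (`NN`) flank calls are handled by summing over the compatible
#' true genotypes.
#'
#' @param code_left,code_right observed calls at the flanking markers
#'   (vectors over individuals, codes from [GENO_CODES]). Use `"NN"` when a
#'   flank does not exist (e.g. beyond the terminal marker).
#' @param d_left,d_right map distances (cM) from the test position to the
#'   left and right flanking markers.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return a numeric matrix with one row per individual and columns
#'   `p_qq`, `p_Qq`, `p_QQ`, each row summing to 1.
#' @examples
#' genotype_probs("AA", "NN", 0, 0)          # collapses to (0, 0, 1)
#' genotype_probs("AA", "BB", 10, 10)        # symmetric midpoint
#' @export
genotype_probs <- function(code_left, code_right, d_left, d_right,
                           map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stopifnot(length(code_left) == length(code_right),
            d_left >= 0, d_right >= 0)
  to_r <- .map_fun_r(map_function)
  cl <- match(code_left, GENO_CODES)
  cr <- match(code_right, GENO_CODES)
  if (anyNA(cl) || anyNA(cr)) {
    stop("unknown genotype code; allowed: ", paste(GENO_CODES, collapse = ", "))
  }
  pr <- .flank_class_probs(to_r(d_left), to_r(d_right))
  out <- t(pr[, (cl - 1L) * 6L + cr, drop = FALSE])
  colnames(out) <- c("p_qq", "p_Qq", "p_QQ")
  out
}
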