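## Synthetic triple-genome homology fixtures: two species' mapped loci
## hitting shared intermediary-genome scaffolds, with planted synteny
## blocks and colocalized QTL of known truth.

#' Specify a synthetic homology / colocalization fixture
#'
#' Each block lives on its own linkage-group pair and carries
#' `loci_per_block` shared loci bridged by unique intermediary
#' scaffolds. For `n_coloc_traits` traits a QTL is planted inside the
#' same block in both species (true colocalization); for
#' `n_noncoloc_traits` traits the two species' QTL sit in the same
#' block but in disjoint regions (no colocalization).
#'
#' @param n_blocks number of synteny blocks (default 5).
#' @param loci_per_block shared loci per block (default 4).
#' @param block_span_cm block span on the species-A map (default 40).
#' @param scale_b species-B span as a fraction of the A span
#'   (default 0.5).
#' @param n_coloc_traits,n_noncoloc_traits planted trait counts
#'   (defaults 3 and 2; they cycle over blocks).
#' @param noise spurious-hit rate: fraction of additional random hits
#'   per table (default 0).
#' @param seed integer seed.
#' @return an object of class `homology_spec`.
#' @export
homology_spec <- function(n_blocks = 5, loci_per_block = 4,
                          block_span_cm = 40, scale_b = 0.5,
                          n_coloc_traits = 3, n_noncoloc_traits = 2,
                          noise = 0, seed = 1L) {
  stopifnot(n_blocks >= 1, loci_per_block >= 1, block_span_cm > 0,
            scale_b > 0, noise >= 0, noise <= 1,
            n_coloc_traits + n_noncoloc_traits <= n_blocks * 2)
  structure(
    list(n_blocks = n_blocks, loci_per_block = loci_per_block,
         block_span_cm = block_span_cm, scale_b = scale_b,
         n_coloc_traits = n_coloc_traits,
         n_noncoloc_traits = n_noncoloc_traits,
         noise = noise, seed = as.integer(seed)),
    class = "homology_spec"
  )
}

#' Simulate BLAST-style hit tables and QTL tables with known homology
#'
#' Emits 12-column tabular hits of both species' loci against shared
#' intermediary scaffolds (true homologs with e-values well below
#' `1e-6`), spurious hits at rate `noise` (e-values straddling the
#' threshold, subjects drawn from other blocks' scaffolds), species
#' maps, QTL interval tables, and the truth needed for recovery
#' testing. Scaffold ids are unique across blocks; reusing one is an
#' error.
#'
#' @param spec a [homology_spec()].
#' @return list of class `homology_sim` with `hits_a`, `hits_b` (data
#'   frames in 12-column tabular layout), `map_a`, `map_b`, `qtl_a`,
#'   `qtl_b`, and `truth` (`blocks` data frame, `pairs` of true locus
#'   pairs, `traits` with the planted colocalization flag).
#' @export
simulate_homology <- function(spec) {
  stopifnot(inherits(spec, "homology_spec"))
  set.seed(spec$seed)
  nb <- spec$n_blocks
  npl <- spec$loci_per_block
  inverted <- rep(c(FALSE, TRUE), length.out = nb)

  maps_a <- maps_b <- list()
  pairs_truth <- list()
  blocks_truth <- list()
  scaffolds <- list()
  hit_row <- function(q, s, evalue) {
    len <- 300L
    data.frame(qseqid = q, sseqid = s,
               pident = round(stats::runif(1, 85, 99), 2),
               length = len, mismatch = sample(0:20, 1), gapopen = 0L,
               qstart = 1L, qend = len,
               sstart = 1000L, send = 1000L + len,
               evalue = evalue, bitscore = round(2 * len - evalue * 0, 1))
  }
  hits_a <- hits_b <- list()
  scaf_id <- 0L
  for (b in seq_len(nb)) {
    lg_a <- sprintf("A%02d", b)
    lg_b <- sprintf("B%02d", b)
    pos_a <- seq(0, spec$block_span_cm, length.out = npl)
    pos_b <- pos_a * spec$scale_b
    if (inverted[b]) pos_b <- rev(pos_b)
    loci_a <- sprintf("a%02d_%02d", b, seq_len(npl))
    loci_b <- sprintf("b%02d_%02d", b, seq_len(npl))
    scafs <- sprintf("scf%04d", scaf_id + seq_len(npl))
    scaf_id <- scaf_id + npl
    if (any(scafs %in% unlist(scaffolds))) {
      stop("scaffold id reused across blocks")
    }
    scaffolds[[b]] <- scafs
    maps_a[[b]] <- data.frame(linkage_group = lg_a, marker = loci_a,
                              position_cm = pos_a)
    maps_b[[b]] <- data.frame(linkage_group = lg_b, marker = loci_b,
                              position_cm = pos_b)
    for (i in seq_len(npl)) {
      hits_a[[length(hits_a) + 1L]] <-
        hit_row(loci_a[i], scafs[i], 10^-stats::runif(1, 20, 50))
      hits_b[[length(hits_b) + 1L]] <-
        hit_row(loci_b[i], scafs[i], 10^-stats::runif(1, 20, 50))
    }
    pairs_truth[[b]] <- data.frame(locus_a = loci_a, locus_b = loci_b,
                                   scaffold = scafs, block = b)
    blocks_truth[[b]] <- data.frame(
      block = b, lg_a = lg_a, lg_b = lg_b, n_loci = npl,
      orientation = if (inverted[b]) "inverted" else "same")
  }
  map_a <- do.call(rbind, maps_a)
  map_b <- do.call(rbind, maps_b)

  ## spurious hits: random queries against other blocks' scaffolds,
  ## e-values straddling the filtering threshold
  n_true <- nb * npl
  n_noise <- round(spec$noise * n_true)
  add_noise <- function(hits, map) {
    for (k in seq_len(n_noise)) {
      q <- sample(map$marker, 1)
      q_block <- as.integer(substr(q, 2, 3))
      other <- setdiff(seq_len(nb), q_block)
      if (!length(other)) next
      s <- sample(unlist(scaffolds[other]), 1)
      hits[[length(hits) + 1L]] <- hit_row(q, s, 10^-stats::runif(1, 2, 12))
    }
    hits
  }
  hits_a <- add_noise(hits_a, map_a)
  hits_b <- add_noise(hits_b, map_b)

  ## planted QTL
  qtl_a <- qtl_b <- list()
  traits_truth <- list()
  n_traits <- spec$n_coloc_traits + spec$n_noncoloc_traits
  blk_cycle <- rep(seq_len(nb), length.out = n_traits)
  for (t in seq_len(n_traits)) {
    b <- blk_cycle[t]
    trait <- sprintf("trait%02d", t)
    coloc <- t <= spec$n_coloc_traits
    span <- spec$block_span_cm
    if (coloc) {
      lo_a <- span * 0.25; hi_a <- span * 0.55
      ## same region on B (accounting for scale/orientation)
      lo_b <- lo_a * spec$scale_b; hi_b <- hi_a * spec$scale_b
    } else {
      lo_a <- span * 0.02; hi_a <- span * 0.18
      lo_b <- span * 0.70 * spec$scale_b; hi_b <- span * 0.95 * spec$scale_b
    }
    if (inverted[b]) {
      bspan <- span * spec$scale_b
      tmp <- c(bspan - hi_b, bspan - lo_b)
      lo_b <- tmp[1]; hi_b <- tmp[2]
    }
    qtl_a[[t]] <- data.frame(
      trait = trait, linkage_group = sprintf("A%02d", b),
      interval_lo = lo_a, interval_hi = hi_a,
      additive = stats::runif(1, 0.5, 2) * sample(c(-1, 1), 1))
    qtl_b[[t]] <- data.frame(
      trait = trait, linkage_group = sprintf("B%02d", b),
      interval_lo = lo_b, interval_hi = hi_b,
      additive = stats::runif(1, 0.5, 2) * sample(c(-1, 1), 1))
    traits_truth[[t]] <- data.frame(trait = trait, block = b,
                                    colocalized = coloc)
  }

  structure(
    list(
      hits_a = do.call(rbind, hits_a),
      hits_b = do.call(rbind, hits_b),
      map_a = map_a, map_b = map_b,
      qtl_a = do.call(rbind, qtl_a),
      qtl_b = do.call(rbind, qtl_b),
      truth = list(blocks = do.call(rbind, blocks_truth),
                   pairs = do.call(rbind, pairs_truth),
                   traits = do.call(rbind, traits_truth))
    ),
    class = "homology_sim"
  )
}

#' End-to-end colocalization recovery
#'
#' Runs the full comparative pipeline on hit tables, maps and QTL
#' tables: hit filtering, scaffold bridging, synteny-block calling,
#' interval projection, and colocalization detection.
#'
#' @param hits_a,hits_b raw 12-column hit tables.
#' @param map_a,map_b species maps.
#' @param qtl_a,qtl_b QTL interval tables (`trait`, `linkage_group`,
#'   `interval_lo`, `interval_hi`).
#' @param min_loci minimum loci per synteny block (default 3).
#' @param max_evalue e-value cutoff (default 1e-6).
#' @return list with `blocks`, `pairs` (bridged locus pairs), `matches`
#'   and `colocalized` (from [detect_colocalization()]).
#' @export
recover_colocalization <- function(hits_a, hits_b, map_a, map_b,
                                   qtl_a, qtl_b, min_loci = 3,
                                   max_evalue = 1e-6) {
  fa <- filter_hits(hits_a, max_evalue = max_evalue)
  fb <- filter_hits(hits_b, max_evalue = max_evalue)
  pairs <- bridge_loci(fa, fb)
  blocks <- call_synteny(pairs, map_a, map_b, min_loci = min_loci)
  det <- detect_colocalization(qtl_a, qtl_b, blocks)
  list(blocks = blocks, pairs = pairs, matches = det$matches,
       colocalized = det$colocalized)
}
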