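## Readers and writers for the interchange formats: genotype CSV, map
## TSV, QTL CSV, 12-column tabular BLAST hits, and flat key=value
## configuration files.

#' Read a genotype matrix from CSV
#'
#' Expects a header of marker ids with the first column holding
#' individual ids. Calls are validated against [GENO_CODES]; markers
#' with only missing calls are dropped with a warning.
#'
#' @param path CSV file path.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("genotype CSV needs an id column plus markers")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  bad <- !(m %in% GENO_CODES)
  if (any(bad)) {
    w <- which(matrix(bad, nrow = nrow(m)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid genotype code '%s' at row %d (individual '%s'), column '%s'",
      m[w[1], w[2]], w[1], ids[w[1]], colnames(m)[w[2]]))
  }
  all_missing <- apply(m, 2, function(col) all(col == "NN"))
  if (any(all_missing)) {
    warning("dropping marker(s) with only missing calls: ",
            paste(colnames(m)[all_missing], collapse = ", "))
    m <- m[, !all_missing, drop = FALSE]
  }
  genotype_matrix(m)
}

#' Write a genotype matrix to CSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(individual = rownames(geno), unclass(geno),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a genetic map as TSV
#'
#' The map format has columns `linkage_group`, `marker`, `position_cm`.
#'
#' @param path TSV file path.
#' @return `read_map()`: the map data frame; `write_map()`: `path`,
#'   invisibly.
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("linkage_group", "marker", "position_cm")
  if (!all(need %in% names(df))) {
    stop("map TSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_map
#' @param map map data frame (or `linkage_map` object).
#' @export
write_map <- function(map, path) {
  df <- if (inherits(map, "linkage_map")) map$map else map
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read 12-column tabular BLAST hits
#'
#' Standard tabular format (`-outfmt 6`): qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore. Records are kept in file order; a row with the wrong field
#' count raises an error naming the line.
#'
#' @param path file path.
#' @return data frame of hits.
#' @export
read_blast6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop(sprintf("line %d has %d fields (12 expected)", bad, nf[bad]))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$evalue)) stop("unparseable e-value in BLAST table")
  df
}

#' Write hits in 12-column tabular layout
#'
#' @param hits hit data frame ([read_blast6()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  utils::write.table(hits[, cols], path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write QTL tables as CSV
#'
#' @param path CSV path.
#' @return `read_qtl()`: a `qtl_table` data frame.
#' @export
read_qtl <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("qtl_table", "data.frame")
  df
}

#' @rdname read_qtl
#' @param qtl a `qtl_table`.
#' @export
write_qtl <- function(qtl, path) {
  utils::write.csv(qtl, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (comments start with `#`); values
#' are parsed as numeric, logical, or kept as strings.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else val
  }
  out
}
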