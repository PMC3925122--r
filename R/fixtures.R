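## Published reference tables shipped as plain-text fixtures.

#' Published safflower domestication QTL table
#'
#' The 61 QTL mapped in the safflower (cultivar x wild progenitor) F2
#' study: trait, linkage group, peak position, nearest marker, 1-LOD
#' support interval, additive effect of the cultivar allele, dominance
#' ratio (d/a), PVE (%), and confidence tier (0.05, or 0.10 for the
#' eight marginally significant QTL). Peak positions printed as a
#' range are stored as the range midpoint.
#'
#' @return a `qtl_table` data frame with 61 rows.
#' @export
qtl_table_fixture <- function() {
  path <- system.file("extdata", "published_qtl_table.csv",
                      package = "crossqtl", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("qtl_table", "data.frame")
  df
}

#' Published parental trait means
#'
#' Mean trait values of the cultivated safflower and wild progenitor
#' mapping parents for the 24 phenotyped traits, with a flag marking
#' the 15 traits whose parental means differed significantly.
#'
#' @return data frame `trait`, `wild_mean`, `cultivar_mean`,
#'   `significant`.
#' @export
parent_table_fixture <- function() {
  path <- system.file("extdata", "published_parent_means.csv",
                      package = "crossqtl", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
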