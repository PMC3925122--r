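## End-to-end pipeline driver: simulate -> map -> scan -> MIM ->
## epistasis -> trait stats -> colocalization, writing versioned
## outputs and a run log.

#' Run the full analysis pipeline on a synthetic cross
#'
#' Executes the enabled stages in order on a simulated F2 population
#' and writes all result tables under `out_dir`: the genotype CSV,
#' phenotype CSV, true and re-estimated map TSVs, distortion report,
#' scan profile, permutation thresholds (JSON), QTL table, epistasis
#' report, and colocalization summaries, plus a run log recording the
#' seed and configuration.
#'
#' @param out_dir output directory (created if absent).
#' @param design a [cross_design()]; default
#'   [safflower_cross_design()].
#' @param arch a [trait_architecture()] for the scanned trait, or
#'   `NULL` for a default two-QTL trait.
#' @param config a [scan_config()]; for pipeline runs the permutation
#'   count may be reduced.
#' @param epi_config an [epistasis_config()].
#' @param stages character vector out of `"map"`, `"scan"`, `"mim"`,
#'   `"epistasis"`, `"stats"`, `"coloc"`.
#' @param seed integer seed governing all stages.
#' @return named list of written file paths and headline results,
#'   invisibly.
#' @export
run_pipeline <- function(out_dir,
                         design = safflower_cross_design(),
                         arch = NULL,
                         config = scan_config(n_permutations = 100),
                         epi_config = epistasis_config(),
                         stages = c("map", "scan", "mim", "epistasis",
                                    "stats", "coloc"),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  paths <- list()
  log_lines <- c(
    sprintf("crossqtl pipeline run, seed = %d", seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("design: n = %d, markers = %d, LGs = %d",
            design$n_individuals, sum(design$linkage_groups$n_markers),
            nrow(design$linkage_groups)),
    sprintf("scan: step %.1f cM, window %.1f cM, %d cofactors max, %d perms",
            config$step_cm, config$window_cm, config$max_cofactors,
            config$n_permutations)
  )

  sim <- simulate_f2(design)
  paths$genotypes <- file.path(out_dir, "genotypes.csv")
  write_genotypes(sim$geno, paths$genotypes)
  paths$true_map <- file.path(out_dir, "map_true.tsv")
  write_map(sim$map, paths$true_map)

  if (is.null(arch)) {
    ## default two-QTL trait placed on the first and last LG of the design
    lgs_avail <- design$linkage_groups
    lg1 <- lgs_avail$name[1]
    lg2 <- lgs_avail$name[nrow(lgs_avail)]
    arch <- trait_architecture(
      qtl = data.frame(
        lg = c(lg1, lg2),
        position_cm = 0.4 * c(lgs_avail$length_cm[1],
                              lgs_avail$length_cm[nrow(lgs_avail)]),
        a = c(1, 0.6), d = c(0.3, 0)),
      parent_means = c(cultivar = 1.6, wild = -1.6)
    )
  }
  set.seed(seed + 1L)
  trait <- simulate_trait(arch, sim, target_pve = 0.3)
  paths$phenotypes <- file.path(out_dir, "phenotypes.csv")
  utils::write.csv(
    data.frame(individual = rownames(sim$geno),
               trait1 = trait$phenotype),
    paths$phenotypes, row.names = FALSE)

  results <- list()

  if ("map" %in% stages) {
    lmap <- build_map(sim$geno, map_function = design$map_function)
    paths$map <- file.path(out_dir, "map_estimated.tsv")
    write_map(lmap, paths$map)
    dist <- distortion_scan(sim$geno)
    paths$distortion <- file.path(out_dir, "distortion.tsv")
    utils::write.table(dist, paths$distortion, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    results$map_summary <- summarize_map(lmap)
    log_lines <- c(log_lines, sprintf(
      "map: %d groups, %d markers, %.1f cM",
      results$map_summary$n_groups, results$map_summary$n_markers,
      results$map_summary$total_cm))
  }

  qtl <- NULL
  if ("scan" %in% stages) {
    profile <- cim_scan(sim$geno, trait$phenotype, sim$map, config,
                        map_function = design$map_function)
    paths$profile <- file.path(out_dir, "scan_profile.tsv")
    utils::write.table(profile, paths$profile, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    thr <- permutation_threshold(sim$geno, trait$phenotype, sim$map,
                                 config,
                                 map_function = design$map_function)
    paths$thresholds <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(as.list(thr), paths$thresholds,
                         auto_unbox = TRUE, digits = NA)
    qtl <- call_qtl(profile, thr, map = sim$map, config = config,
                    trait = "trait1")
    paths$qtl <- file.path(out_dir, "qtl.csv")
    write_qtl(qtl, paths$qtl)
    results$qtl <- qtl
    log_lines <- c(log_lines,
                   sprintf("scan: thresholds %s; %d QTL called",
                           paste(sprintf("%.2f", thr), collapse = "/"),
                           nrow(qtl)))
  }

  if ("mim" %in% stages && !is.null(qtl) && nrow(qtl) > 0) {
    mim <- mim_refine(qtl, sim$geno, trait$phenotype, sim$map,
                      map_function = design$map_function)
    paths$mim <- file.path(out_dir, "qtl_mim.csv")
    write_qtl(mim$qtl, paths$mim)
    results$mim <- mim
    log_lines <- c(log_lines,
                   sprintf("mim: %d QTL retained, IC = %.2f",
                           nrow(mim$qtl), mim$ic))
  }

  if ("epistasis" %in% stages) {
    collapsed <- collapse_identical(sim$geno)
    ## scan a tractable subset: every 8th haplotype
    subset <- colnames(collapsed$geno)[
      seq(1, ncol(collapsed$geno), by = 8)]
    epi <- pair_scan(collapsed$geno, trait$phenotype, sim$map,
                     config = epi_config, markers = subset)
    paths$epistasis <- file.path(out_dir, "epistasis.tsv")
    utils::write.table(epi, paths$epistasis, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    results$epistasis <- count_interactions(epi)
  }

  if ("stats" %in% stages) {
    parents <- parent_table_fixture()
    tbl <- qtl_table_fixture()
    stats_out <- qtl_table_stats(tbl)
    paths$table_stats <- file.path(out_dir, "qtl_table_stats.json")
    jsonlite::write_json(stats_out, paths$table_stats,
                         auto_unbox = TRUE, digits = NA)
    results$table_stats <- stats_out
    results$parents <- parents
  }

  if ("coloc" %in% stages) {
    hspec <- homology_spec(noise = 0.1, seed = seed)
    hsim <- simulate_homology(hspec)
    rec <- recover_colocalization(hsim$hits_a, hsim$hits_b,
                                  hsim$map_a, hsim$map_b,
                                  hsim$qtl_a, hsim$qtl_b)
    truth <- hsim$truth$traits
    recovered <- truth$trait %in% rec$colocalized$trait
    coloc_out <- list(
      n_blocks = length(rec$blocks),
      recall = if (any(truth$colocalized)) {
        mean(recovered[truth$colocalized])
      } else NA,
      false_positives = sum(recovered & !truth$colocalized)
    )
    paths$coloc <- file.path(out_dir, "colocalization.json")
    jsonlite::write_json(coloc_out, paths$coloc, auto_unbox = TRUE,
                         digits = NA)
    results$coloc <- coloc_out
  }

  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  invisible(c(paths, list(results = results)))
}
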