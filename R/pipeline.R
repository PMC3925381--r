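#' Run the full community-assembly analysis on an archipelago
#'
#' End-to-end driver: fit per-ecomorph niche-model ensembles with the
#' archipelago-wide union extent as background, build each island's ECC
#' surface, cross-fit every island's ensembles onto the union extent and
#' compute Schoener's D overlap (ECC level and per ecomorph), run the
#' ECC-elevation correlations (raster level plus decorrelated-subsample
#' Spearman with permutation p), re-check the correlations without the
#' ecomorphs missing from the reduced-complement island, compete the
#' AICc candidate models per island, compare BioPCs across islands with
#' Kruskal-Wallis, and correlate each ecomorph's elevational constraint with
#' its body-mass rank.
#'
#' @param stacks Named list of `env_stack` by island id.
#' @param occurrences Named list of `occurrence_set` (`"<island>/<ecomorph>"`).
#' @param config A [run_config()].
#' @param trait_exclude Optional data frame (`ecomorph`, `island`) of
#'   constraint rows excluded from the trait correlation.
#' @param sensitivity_drop Ecomorphs dropped in the shared-complement
#'   re-analysis (only applied on islands that have them all); default
#'   `c("grass-bush", "trunk")`.
#' @return A nested list with elements `ensembles`, `ecc`, `overlap`,
#'   `correlations`, `sensitivity`, `model_selection`, `kruskal`, `traits`,
#'   `summary` (flat, JSON-friendly numbers).
#' @export
run_pipeline <- function(stacks, occurrences, config = run_config(),
                         trait_exclude = NULL,
                         sensitivity_drop = c("grass-bush", "trunk")) {
  union <- stack_union(stacks)

  ensembles <- lapply(occurrences, function(occ) {
    fit_ensemble(occ, stacks[[occ$island_id]], background_stack = union,
                 config = config)
  })

  islands <- names(stacks)
  eco_of <- function(key) sub("^[^/]+/", "", key)
  isl_of <- function(key) sub("/.*$", "", key)

  # per-island ECC from the ensemble mean maps
  ecc_maps <- lapply(islands, function(isl) {
    keys <- names(ensembles)[isl_of(names(ensembles)) == isl]
    maps <- lapply(ensembles[keys], `[[`, "mean_map")
    names(maps) <- eco_of(keys)
    ecc(maps, config$ecc_weights)
  })
  names(ecc_maps) <- islands

  # cross-fitted ECC on the union extent, per source island
  proj <- lapply(ensembles, project_ensemble, stack = union)
  ecc_union <- lapply(islands, function(isl) {
    keys <- names(proj)[isl_of(names(proj)) == isl]
    mm <- proj[keys]; names(mm) <- eco_of(keys)
    ecc(mm, config$ecc_weights)$raster
  })
  names(ecc_union) <- islands
  overlap <- list(ECC = overlap_table(ecc_union, "ECC"))
  for (eco in unique(eco_of(names(ensembles)))) {
    mm <- lapply(islands, function(isl) {
      key <- paste(isl, eco, sep = "/")
      if (key %in% names(proj)) proj[[key]] else NULL
    })
    names(mm) <- islands
    overlap[[eco]] <- overlap_table(mm, eco)
  }

  # pooled PCA, per-island correlations and model selection
  points <- lapply(islands, function(isl) extract_points(stacks[[isl]], ecc_maps[[isl]]))
  names(points) <- islands
  pooled <- do.call(rbind, points)
  biopc <- pca_bioclim(pooled)
  isl_col <- pooled$island_id
  correlations <- list(); selection <- list(); sensitivity <- list()
  for (isl in islands) {
    sub <- list(scores = biopc$scores[isl_col == isl, , drop = FALSE])
    correlations[[isl]] <- correlate_island(points[[isl]], sub, config)
    bp_isl <- structure(list(scores = sub$scores), class = "biopc_result")
    selection[[isl]] <- select_models(points[[isl]], bp_isl,
                                      config$elevation_dependence_threshold)
    keys <- names(ensembles)[isl_of(names(ensembles)) == isl]
    maps <- lapply(ensembles[keys], `[[`, "mean_map")
    names(maps) <- eco_of(keys)
    drop_here <- intersect(sensitivity_drop, names(maps))
    if (length(drop_here) == length(sensitivity_drop)) {
      sensitivity[[isl]] <- ecc_sensitivity(maps, drop_here, stacks[[isl]],
                                            config, config$ecc_weights)
    }
  }

  kw <- lapply(colnames(biopc$scores), function(pc) {
    kruskal_wallis(split(biopc$scores[, pc], isl_col))
  })
  names(kw) <- colnames(biopc$scores)

  ctab <- constraint_table(ensembles, stacks)
  traits <- trait_correlation(ctab, exclude = trait_exclude,
                              n_permutations = min(config$n_permutations, 10000L),
                              seed = config$seed)

  summary <- list(
    n_islands = length(islands),
    n_ensembles = length(ensembles),
    mean_test_auc = mean(vapply(ensembles, `[[`, 1, "mean_test_auc")),
    ecc_max = max(vapply(ecc_maps, function(e) max(e$raster$values[e$raster$mask]), 1)),
    ecc_bound = sum(rep_len(config$ecc_weights,
                            max(table(isl_of(names(ensembles)))))),
    overlap_ecc = overlap$ECC$pairs[, c("island_a", "island_b", "D")],
    pearson_R = vapply(correlations, function(cr) cr$raster$R, 1),
    spearman_r = vapply(correlations, function(cr) cr$reduced$r, 1),
    spearman_p = vapply(correlations, function(cr) cr$reduced$p, 1),
    top_model = vapply(selection, function(s) s$table$name[1], ""),
    trait_r = traits$r, trait_p = traits$p
  )

  list(ensembles = ensembles, ecc = ecc_maps, ecc_union = ecc_union,
       overlap = overlap, points = points, biopc = biopc,
       correlations = correlations, sensitivity = sensitivity,
       model_selection = selection, kruskal = kw, traits = traits,
       summary = summary)
}

#' Write pipeline outputs to a directory
#'
#' Rasters as ESRI ASCII grids, tables as CSV, the flat summary as JSON.
#'
#' @param result List from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (isl in names(result$ecc)) {
    write_raster(result$ecc[[isl]]$raster,
                 file.path(out_dir, sprintf("ecc_%s.asc", isl)))
  }
  ov <- do.call(rbind, lapply(result$overlap, `[[`, "pairs"))
  utils::write.csv(ov, file.path(out_dir, "overlap.csv"), row.names = FALSE)
  cors <- do.call(rbind, lapply(names(result$correlations), function(isl) {
    cr <- result$correlations[[isl]]
    data.frame(island = isl, R = cr$raster$R, slope = cr$raster$slope,
               intercept = cr$raster$intercept,
               spearman_r = cr$reduced$r, p = cr$reduced$p,
               n_reduced = cr$reduced$n)
  }))
  utils::write.csv(cors, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(island_report(result$model_selection),
                   file.path(out_dir, "model_selection.csv"), row.names = FALSE)
  utils::write.csv(result$traits$table, file.path(out_dir, "constraints.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
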