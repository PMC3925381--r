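#' Per-cell point table of environment and community completeness
#'
#' One row per valid cell: elevation, every climate layer, the ECC value,
#' island id and a cell id (plus row/col indices). Column order: `island_id`,
#' `cell`, `row`, `col`, `elevation`, climate layers in stack order, `ecc`.
#'
#' @param stack An `env_stack`.
#' @param ecc An `ecc_map` (or `grid_raster`) sharing the stack's mask.
#' @return A data frame.
#' @export
extract_points <- function(stack, ecc) {
  eccr <- if (inherits(ecc, "ecc_map")) ecc$raster else ecc
  if (!identical(eccr$mask, stack_mask(stack))) {
    stop("ECC raster and stack do not share the same mask")
  }
  cells <- valid_cells(stack$layers[[1]])
  out <- data.frame(island_id = stack$island_id,
                    cell = seq_len(nrow(cells)),
                    row = cells[, 1], col = cells[, 2],
                    stringsAsFactors = FALSE)
  for (nm in names(stack$layers)) {
    out[[nm]] <- stack$layers[[nm]]$values[cells]
  }
  out$ecc <- eccr$values[cells]
  stopifnot(!anyNA(out))
  out
}

#' Climate-layer names of a point table
#' @param points Data frame from [extract_points()].
#' @return Character vector (everything between `col`/`elevation` and `ecc`).
#' @export
climate_columns <- function(points) {
  setdiff(names(points), c("island_id", "cell", "row", "col", "elevation", "ecc"))
}

#' Principal components of the bioclimatic variables (BioPCs)
#'
#' Correlation-matrix PCA (variables standardized) of the climate columns;
#' components with eigenvalue above one are retained (Kaiser criterion).
#' Eigenvalues sum to the number of variables.
#'
#' @param points Data frame from [extract_points()] (one or several islands
#'   pooled; pooling keeps the BioPC axes comparable across islands).
#' @param climate_cols Climate column names; default [climate_columns()].
#' @return An object of class `biopc_result`: `loadings`, `eigenvalues`,
#'   `retained`, `scores` (points x retained, columns `BioPC1..`), and
#'   `scores_all`.
#' @export
pca_bioclim <- function(points, climate_cols = climate_columns(points)) {
  if (length(climate_cols) < 2L) stop("need at least two climate variables")
  X <- as.matrix(points[, climate_cols, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least three points")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant climate variable(s): %s",
                 paste(climate_cols[sds == 0], collapse = ", ")))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  retained <- sum(ev > 1)
  scores_all <- pc$x
  colnames(scores_all) <- paste0("BioPC", seq_len(ncol(scores_all)))
  loadings <- pc$rotation
  colnames(loadings) <- colnames(scores_all)
  structure(list(loadings = loadings, eigenvalues = ev, retained = retained,
                 scores = scores_all[, seq_len(max(retained, 1L)), drop = FALSE],
                 scores_all = scores_all,
                 center = pc$center, scale = pc$scale),
            class = "biopc_result")
}

#' @export
print.biopc_result <- function(x, ...) {
  cat(sprintf("<biopc_result> %d variables, %d retained (eigenvalue > 1)\n",
              length(x$eigenvalues), x$retained))
  cat("  eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Decorrelated subsample via k-means on BioPC scores
#'
#' Clusters the points by bioclimatic similarity (seeded k-means, Lloyd
#' iterations to assignment stability) and draws `per_cluster` points
#' uniformly without replacement from each cluster (all points when a cluster
#' is smaller, with a warning). With k = 100 and 1 or 10 points per cluster
#' this yields the 100- and 1000-point decorrelated datasets used for the
#' reduced correlation tests.
#'
#' @param scores Numeric matrix of BioPC scores (points x components).
#' @param k Number of clusters (at most the number of points).
#' @param per_cluster Points kept per cluster.
#' @param seed Integer seed.
#' @return Sorted integer vector of row indices into `scores`.
#' @export
kmeans_subsample <- function(scores, k, per_cluster, seed) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k > n) stop(sprintf("k = %d exceeds the %d available points", k, n))
  if (per_cluster < 1) stop("'per_cluster' must be positive")
  set.seed(sub_seed(seed, 41))
  cl <- if (k == n) seq_len(n) else
    stats::kmeans(scores, centers = k, iter.max = 100, nstart = 3)$cluster
  idx <- integer(0)
  short <- 0L
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) <= per_cluster) {
      if (length(members) < per_cluster) short <- short + 1L
      take <- members
    } else {
      take <- members[sample.int(length(members), per_cluster)]
    }
    idx <- c(idx, take)
  }
  if (short > 0L) {
    warning(sprintf("%d cluster(s) smaller than per_cluster = %d; all their points kept",
                    short, per_cluster))
  }
  sort(idx)
}

#' Raster-level Pearson correlation and regression of ECC on elevation
#'
#' @param ecc An `ecc_map` or `grid_raster`.
#' @param elevation A `grid_raster` sharing the mask.
#' @return List with `R` (Pearson), `slope`, `intercept`, `n`.
#' @export
raster_correlation <- function(ecc, elevation) {
  eccr <- if (inherits(ecc, "ecc_map")) ecc$raster else ecc
  if (!identical(eccr$mask, elevation$mask)) stop("mask mismatch")
  y <- eccr$values[eccr$mask]
  x <- elevation$values[elevation$mask]
  if (length(x) < 3L) stop("need at least 3 shared cells")
  if (stats::sd(x) == 0) stop("elevation has zero variance on the mask")
  fit <- stats::lm(y ~ x)
  list(R = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' Spearman rank correlation with a seeded permutation p-value
#'
#' `r` is the Pearson correlation of average ranks (ties averaged). The
#' two-sided p-value permutes `y` `n_permutations` times:
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_permutations)`.
#'
#' @param x,y Numeric vectors of equal length >= 5, neither constant.
#' @param n_permutations Number of permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n`.
#' @export
spearman_perm <- function(x, y, n_permutations = 100000L, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 5L) stop("need at least 5 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  rx <- rank(x); ry <- rank(y)
  r_obs <- stats::cor(rx, ry)
  set.seed(sub_seed(seed, 53))
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    rp <- sum(rxc * ryc[sample.int(n)]) / denom
    if (abs(rp) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_permutations), n = n)
}

#' ECC-elevation correlation on a decorrelated subsample
#'
#' Convenience wrapper running the raster-level correlation plus the
#' reduced-dataset Spearman permutation test on a k-means subsample of the
#' BioPC scores.
#'
#' @param points Point table for one island ([extract_points()]).
#' @param biopc `biopc_result` whose `scores` rows align with `points`
#'   (compute it on this island's rows, or subset pooled scores).
#' @param config A [run_config()].
#' @return List with `raster` (R, slope, intercept, n), `reduced`
#'   (r, p, n) and `subsample` (row indices).
#' @export
correlate_island <- function(points, biopc, config = run_config()) {
  idx <- kmeans_subsample(biopc$scores, min(config$kmeans_k, nrow(points)),
                          config$points_per_cluster, config$seed)
  red <- spearman_perm(points$elevation[idx], points$ecc[idx],
                       config$n_permutations, config$seed)
  fit <- stats::lm(ecc ~ elevation, data = points)
  list(raster = list(R = stats::cor(points$elevation, points$ecc),
                     slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     n = nrow(points)),
       reduced = red, subsample = idx)
}

#' Sensitivity of the ECC-elevation correlation to ecomorph removal
#'
#' Rebuilds the ECC surface without the named ecomorphs and re-runs the
#' correlation pipeline, so islands can be compared on an identical ecomorph
#' complement (the check that a shared-complement ECC still tracks
#' elevation).
#'
#' @param maps Named list of per-ecomorph suitability `grid_raster`.
#' @param drop Character vector of ecomorph names to remove (may be empty).
#' @param stack The island's `env_stack`.
#' @param config A [run_config()].
#' @param weights ECC weights for the full map set.
#' @return List with `full` and `reduced`, each as from [correlate_island()],
#'   plus `dropped`.
#' @export
ecc_sensitivity <- function(maps, drop, stack, config = run_config(),
                            weights = 1) {
  missing_drop <- setdiff(drop, names(maps))
  if (length(missing_drop)) {
    stop(sprintf("cannot drop ecomorph(s) absent from the island: %s",
                 paste(missing_drop, collapse = ", ")))
  }
  if (length(drop) >= length(maps)) stop("cannot drop every ecomorph")
  weights <- rep_len(weights, length(maps))
  run <- function(keep) {
    e <- ecc(maps[keep], weights[match(keep, names(maps))])
    pts <- extract_points(stack, e)
    correlate_island(pts, pca_bioclim(pts), config)
  }
  full <- run(names(maps))
  reduced <- if (length(drop)) run(setdiff(names(maps), drop)) else full
  list(full = full, reduced = reduced, dropped = drop)
}

#' Kruskal-Wallis comparison of a variable across islands
#'
#' Tie-corrected H statistic with a chi-square p-value on (groups - 1)
#' degrees of freedom.
#'
#' @param groups Named list of numeric vectors (one per island), each with at
#'   least two values.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two values")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Partition BioPCs into elevation-dependent and -independent sets
#'
#' A BioPC counts as elevation-dependent when the absolute Pearson
#' correlation of its scores with elevation meets the threshold. When every
#' BioPC is dependent the `all_dependent` flag is set, which switches the
#' candidate model set to the single-BioPC variant.
#'
#' @param biopc A `biopc_result`.
#' @param elevation Numeric vector of elevations aligned with the score rows.
#' @param threshold Absolute-correlation cutoff in (0, 1); default 0.5.
#' @return List with `dependent`, `independent` (BioPC names), `r` (named
#'   correlations) and `all_dependent` flag.
#' @export
classify_elevation_dependence <- function(biopc, elevation, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  sc <- biopc$scores
  r <- apply(sc, 2, stats::cor, y = elevation)
  dep <- names(r)[abs(r) >= threshold]
  indep <- setdiff(colnames(sc), dep)
  list(dependent = dep, independent = indep, r = r,
       all_dependent = length(indep) == 0L)
}
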