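#' Pipeline run configuration
#'
#' Bundles the knobs shared across stages. Defaults mirror the study design
#' this package operationalises: 100 replicate models per ecomorph per
#' island, 5000 background points, a random 25% test split, k-means with
#' k = 100 for the decorrelated subsamples, and unit ECC weights.
#'
#' @param seed Integer master seed.
#' @param n_replicates Replicate models per ensemble.
#' @param n_background Background points per replicate.
#' @param test_fraction Fraction of presences held out per replicate, in (0,1).
#' @param regularization Base L1 penalty scale (beta0) for the niche model.
#' @param ecc_weights Per-ecomorph weights for the ECC sum; a single value is
#'   recycled. Default 1.
#' @param kmeans_k Number of k-means clusters for subsampling.
#' @param points_per_cluster Points drawn from each cluster (1 or 10 in the
#'   study design; any positive integer accepted).
#' @param n_permutations Permutations for rank-correlation p-values.
#' @param elevation_dependence_threshold Absolute Pearson r at or above which
#'   a BioPC counts as elevation-dependent, in [0, 1].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_replicates = 100L,
                       n_background = 5000L,
                       test_fraction = 0.25,
                       regularization = 1.0,
                       ecc_weights = 1,
                       kmeans_k = 100L,
                       points_per_cluster = 1L,
                       n_permutations = 100000L,
                       elevation_dependence_threshold = 0.5) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            regularization > 0,
            elevation_dependence_threshold >= 0,
            elevation_dependence_threshold <= 1,
            n_replicates >= 1, n_background >= 1,
            kmeans_k >= 1, points_per_cluster >= 1,
            n_permutations >= 1)
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 n_background = as.integer(n_background),
                 test_fraction = test_fraction,
                 regularization = regularization,
                 ecc_weights = ecc_weights,
                 kmeans_k = as.integer(kmeans_k),
                 points_per_cluster = as.integer(points_per_cluster),
                 n_permutations = as.integer(n_permutations),
                 elevation_dependence_threshold = elevation_dependence_threshold),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown config key(s): %s", paste(extra, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(run_config, vals)
}

# Deterministic sub-seed derivation: fold the master seed and stream indices
# through an LCG-style mix kept below 2^31 so set.seed() always gets a valid
# 32-bit integer. Pure double arithmetic stays exact (< 2^53).
sub_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (x in c(...)) {
    s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(s)
}
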