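#' Canonical ecomorph body-mass ranking
#'
#' Ordinal body-mass positions of the six ecomorphs, fixed as
#' twig (1) < grass-bush (2) < trunk (3) < trunk-crown (4) <
#' trunk-ground (5) < crown-giant (6).
#'
#' @return Named integer vector, names = ecomorph, values = rank.
#' @export
mass_ranking <- function() {
  c("twig" = 1L, "grass-bush" = 2L, "trunk" = 3L, "trunk-crown" = 4L,
    "trunk-ground" = 5L, "crown-giant" = 6L)
}

#' Elevational constraint of one suitability surface
#'
#' Spearman rank correlation between an ecomorph's suitability and elevation
#' over the island's valid cells (or a supplied subset). High positive values
#' mean the ecomorph is restricted to high elevations. Being a rank
#' statistic, the result is identical for the raw logistic map and any
#' monotone rescale of it.
#'
#' @param suitability A `grid_raster` (e.g. an ensemble mean map).
#' @param elevation A `grid_raster` sharing the mask.
#' @param cells Optional (row, col) matrix restricting the point set;
#'   default all valid cells.
#' @return List with `r` (Spearman) and `n`.
#' @export
elevational_constraint <- function(suitability, elevation, cells = NULL) {
  if (!identical(suitability$mask, elevation$mask)) stop("mask mismatch")
  if (is.null(cells)) cells <- valid_cells(suitability)
  s <- suitability$values[cells]
  e <- elevation$values[cells]
  if (length(s) < 5L) stop("need at least 5 points")
  if (stats::sd(s) == 0) stop("constant suitability: constraint undefined")
  list(r = stats::cor(rank(s), rank(e)), n = length(s))
}

#' Build the (ecomorph, island) constraint table
#'
#' @param ensembles Named list (`"<island>/<ecomorph>"`) of
#'   `suitability_ensemble` or plain suitability `grid_raster`s.
#' @param stacks Named list of `env_stack` by island id.
#' @return Data frame: ecomorph, island, r, n, excluded (all `FALSE`).
#' @export
constraint_table <- function(ensembles, stacks) {
  rows <- lapply(names(ensembles), function(key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    isl <- parts[1]; eco <- paste(parts[-1], collapse = "/")
    obj <- ensembles[[key]]
    suit <- if (inherits(obj, "suitability_ensemble")) obj$mean_map else obj
    ct <- elevational_constraint(suit, stacks[[isl]]$layers$elevation)
    data.frame(ecomorph = eco, island = isl, r = ct$r, n = ct$n,
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate elevational constraint with body-mass rank
#'
#' Spearman correlation (seeded two-sided permutation p) between each
#' (ecomorph, island) row's constraint `r` and the ecomorph's body-mass
#' rank. Rows named in `exclude` stay in the returned table, flagged, but do
#' not enter the statistic. A negative correlation means smaller ecomorphs
#' are restricted to higher elevations.
#'
#' @param table Data frame from [constraint_table()].
#' @param ranking Named rank vector, default [mass_ranking()].
#' @param exclude Data frame with columns `ecomorph`, `island` (or `NULL`).
#' @param n_permutations,seed Permutation test controls.
#' @return List with `r`, `p`, `n`, `table` (with `excluded` and `mass_rank`
#'   columns) and `excluded` (the flagged rows).
#' @export
trait_correlation <- function(table, ranking = mass_ranking(), exclude = NULL,
                              n_permutations = 10000L, seed = 1L) {
  unknown <- setdiff(unique(table$ecomorph), names(ranking))
  if (length(unknown)) {
    stop(sprintf("unknown ecomorph name(s): %s", paste(unknown, collapse = ", ")))
  }
  table$mass_rank <- unname(ranking[table$ecomorph])
  table$excluded <- FALSE
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(table$island, table$ecomorph)
    table$excluded <- key %in% paste(exclude$island, exclude$ecomorph)
  }
  keep <- !table$excluded
  if (sum(keep) < 5L) stop("fewer than 5 non-excluded rows")
  st <- spearman_perm(table$mass_rank[keep], table$r[keep],
                      n_permutations, seed)
  list(r = st$r, p = st$p, n = st$n, table = table,
       excluded = table[table$excluded, , drop = FALSE])
}

#' Flag candidate outliers in a constraint table
#'
#' Optional assistance only: with `method = "iqr"`, rows whose residual from
#' a resistant (Theil-Sen) constraint-vs-rank trend sits more than 1.5 IQRs
#' from the residual median are flagged for review (a least-squares trend
#' would be dragged by the very point being screened). Nothing is excluded
#' automatically; exclusion is always an explicit user action via
#' `trait_correlation()`.
#'
#' @param table Data frame from [constraint_table()] (>= 5 rows).
#' @param ranking Named rank vector.
#' @param method `"none"` or `"iqr"`.
#' @return The table with a logical `flagged` column.
#' @export
flag_outliers <- function(table, ranking = mass_ranking(),
                          method = c("none", "iqr")) {
  method <- match.arg(method)
  if (nrow(table) < 5L) stop("need at least 5 rows")
  table$flagged <- FALSE
  if (method == "iqr") {
    mr <- unname(ranking[table$ecomorph])
    pairs <- utils::combn(length(mr), 2)
    dx <- mr[pairs[2, ]] - mr[pairs[1, ]]
    dy <- table$r[pairs[2, ]] - table$r[pairs[1, ]]
    slope <- stats::median(dy[dx != 0] / dx[dx != 0])
    intercept <- stats::median(table$r - slope * mr)
    res <- table$r - (intercept + slope * mr)
    iqr <- stats::IQR(res)
    if (iqr > 0) {
      table$flagged <- abs(res - stats::median(res)) > 1.5 * iqr + 1e-12
    }
  }
  table
}
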