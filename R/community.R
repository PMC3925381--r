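#' Min-max rescale a raster to [0, 1] over its valid cells
#'
#' Rescaling is the "equal scaling between ecomorphs" step applied to every
#' suitability map before summation into the community-completeness surface.
#'
#' @param r A `grid_raster` with at least one valid cell.
#' @return A `grid_raster` whose valid values span exactly [0, 1].
#' @export
minmax_scale <- function(r) {
  v <- r$values[r$mask]
  if (!length(v)) stop("raster has no valid cells")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop(sprintf("raster '%s' is constant (value %g): min-max scaling is undefined",
                 r$name, rng[1]))
  }
  raster_with_values(r, (v - rng[1]) / (rng[2] - rng[1]), name = r$name)
}

#' Ecomorph community completeness surface
#'
#' Cellwise weighted sum of the per-ecomorph suitability maps, each min-max
#' rescaled to [0, 1] first (disable with `rescale = FALSE` if maps are
#' already scaled). With unit weights and six ecomorphs the surface ranges
#' over [0, 6], 6 meaning every ecomorph finds the cell fully suitable.
#'
#' @param maps Named list of `grid_raster` (names = ecomorphs), sharing mask.
#' @param weights Non-negative weights, one per map or a single recycled
#'   value; default 1.
#' @param rescale Min-max scale each map before summing.
#' @return An object of class `ecc_map`: `raster`, `ecomorphs`, `weights`.
#' @export
ecc <- function(maps, weights = 1, rescale = TRUE) {
  if (!length(maps)) stop("need at least one suitability map")
  if (is.null(names(maps))) names(maps) <- paste0("ecomorph", seq_along(maps))
  weights <- rep_len(weights, length(maps))
  if (any(weights < 0)) stop("weights must be non-negative")
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(m$mask, ref$mask)) stop("all maps must share the same mask")
  }
  if (rescale) maps <- lapply(maps, minmax_scale)
  acc <- numeric(sum(ref$mask))
  for (i in seq_along(maps)) {
    acc <- acc + weights[i] * maps[[i]]$values[maps[[i]]$mask]
  }
  structure(list(raster = raster_with_values(ref, acc, name = "ECC"),
                 ecomorphs = names(maps), weights = weights),
            class = "ecc_map")
}

#' @export
print.ecc_map <- function(x, ...) {
  v <- x$raster$values[x$raster$mask]
  cat(sprintf("<ecc_map> %d ecomorphs (max attainable %g), range [%.3f, %.3f]\n",
              length(x$ecomorphs), sum(x$weights), min(v), max(v)))
  invisible(x)
}

#' Schoener's D niche overlap between two surfaces
#'
#' Both rasters are normalized to sum to one over the shared valid cells
#' (their intersection mask), then `D = 1 - 0.5 * sum |p_a - p_b|`. D is 1
#' for identical surfaces, 0 for surfaces with disjoint support, and
#' invariant to positive rescaling of either input.
#'
#' @param a,b `grid_raster` objects (or `ecc_map`s) on the same grid shape.
#' @return D in [0, 1].
#' @export
schoener_d <- function(a, b) {
  if (inherits(a, "ecc_map")) a <- a$raster
  if (inherits(b, "ecc_map")) b <- b$raster
  if (!identical(dim(a$values), dim(b$values))) {
    stop("rasters must share grid shape")
  }
  shared <- a$mask & b$mask
  n_excl <- sum(xor(a$mask, b$mask))
  if (!any(shared)) stop("rasters share no valid cells")
  if (n_excl > 0) {
    message(sprintf("schoener_d: %d cells valid in only one raster excluded", n_excl))
  }
  va <- a$values[shared]; vb <- b$values[shared]
  if (any(va < 0) || any(vb < 0)) stop("negative suitabilities are not allowed")
  if (sum(va) <= 0 || sum(vb) <= 0) {
    stop("a raster with zero total suitability cannot be normalized")
  }
  1 - 0.5 * sum(abs(va / sum(va) - vb / sum(vb)))
}

#' Pairwise niche-overlap table across islands
#'
#' Computes Schoener's D for every unordered island pair from maps projected
#' onto a common extent, at the ECC level or for one ecomorph. Islands
#' lacking the ecomorph are flagged `"Ecomorph absent"`.
#'
#' @param maps Named list (names = source island ids) of `grid_raster` on the
#'   common extent; `NULL` entries mark the ecomorph as absent there.
#' @param level `"ECC"` or an ecomorph name (metadata only).
#' @return An object of class `overlap_matrix`: a symmetric numeric matrix
#'   `D` (diagonal 1, `NA` where absent), `level`, and a long-format data
#'   frame `pairs` with a `note` column.
#' @export
overlap_table <- function(maps, level = "ECC") {
  isl <- names(maps)
  if (length(isl) < 2L) stop("need at least two islands")
  D <- matrix(NA_real_, length(isl), length(isl), dimnames = list(isl, isl))
  pairs <- NULL
  for (i in seq_along(isl)) {
    if (!is.null(maps[[i]])) D[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      absent <- is.null(maps[[i]]) || is.null(maps[[j]])
      d <- if (absent) NA_real_ else schoener_d(maps[[i]], maps[[j]])
      D[i, j] <- D[j, i] <- d
      pairs <- rbind(pairs, data.frame(
        island_a = isl[j], island_b = isl[i], level = level, D = d,
        note = if (absent) "Ecomorph absent" else "",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(D = D, level = level, pairs = pairs),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> level %s\n", x$level))
  print(round(x$D, 3))
  invisible(x)
}
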