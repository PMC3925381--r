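#' Deduplicated presence cells for one ecomorph on one island
#'
#' @param ecomorph Ecomorph name.
#' @param island_id Island identifier.
#' @param cells Two-column integer matrix of (row, col) pairs, 1-based,
#'   row 1 = northernmost. Duplicates are collapsed.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(ecomorph, island_id, cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 2L) stop("'cells' must be a two-column (row, col) matrix")
  storage.mode(cells) <- "integer"
  cells <- unique(cells)
  colnames(cells) <- c("row", "col")
  structure(list(ecomorph = as.character(ecomorph),
                 island_id = as.character(island_id),
                 cells = cells),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s on %s: %d unique cells\n",
              x$ecomorph, x$island_id, nrow(x$cells)))
  invisible(x)
}

#' Map a point to its grid cell
#'
#' Point-to-cell uses `floor((x - x0) / cell_size)` columns from the west and
#' the analogous count from the south, then flips to row-1-north indexing.
#'
#' @param r A `grid_raster` giving the geometry.
#' @param x,y Map coordinates.
#' @return Two-column integer matrix of (row, col), 1-based; indices outside
#'   the grid are returned as `NA`.
#' @export
point_to_cell <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row_s <- floor((y - r$origin[2]) / r$cell_size)   # rows up from the south
  row <- nr - row_s                                  # 1-based from the north
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an occurrence CSV into per-(ecomorph, island) presence sets
#'
#' The CSV must have columns `ecomorph, island, x, y` in map coordinates.
#' Records falling outside the grid or on masked (ocean) cells are dropped
#' with a logged count, mirroring the removal of obviously incorrect records;
#' duplicate records within one (ecomorph, island, cell) collapse to a single
#' presence cell.
#'
#' @param path CSV path.
#' @param stacks Named list of `env_stack` objects, names = island ids.
#' @return Named list of `occurrence_set` (names `"<island>/<ecomorph>"`),
#'   with attribute `"n_dropped"` = count of off-mask/off-grid records.
#' @export
read_occurrences <- function(path, stacks) {
  if (!file.exists(path)) stop(sprintf("occurrence file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ecomorph", "island", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("occurrence CSV missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (is.null(names(stacks))) {
    names(stacks) <- vapply(stacks, function(s) s$island_id, "")
  }
  if (nrow(df) == 0L) {
    warning("occurrence file is empty")
    out <- list(); attr(out, "n_dropped") <- 0L
    return(out)
  }
  unknown <- setdiff(unique(df$island), names(stacks))
  if (length(unknown)) {
    stop(sprintf("island id(s) not matching any stack: %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- list()
  dropped <- 0L
  for (isl in unique(df$island)) {
    st <- stacks[[isl]]
    ref <- st$layers[[1]]
    sub <- df[df$island == isl, , drop = FALSE]
    cells <- point_to_cell(ref, sub$x, sub$y)
    on_grid <- !is.na(cells[, 1])
    on_mask <- on_grid
    on_mask[on_grid] <- ref$mask[cells[on_grid, , drop = FALSE]]
    dropped <- dropped + sum(!on_mask)
    for (eco in unique(sub$ecomorph)) {
      keep <- on_mask & sub$ecomorph == eco
      if (!any(keep)) next
      out[[paste(isl, eco, sep = "/")]] <-
        occurrence_set(eco, isl, cells[keep, , drop = FALSE])
    }
  }
  if (dropped > 0L) {
    message(sprintf("read_occurrences: dropped %d off-mask/off-grid record(s)", dropped))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Write occurrence sets back to CSV (cell-centre coordinates)
#' @param occs List of `occurrence_set`.
#' @param stacks Named list of `env_stack` by island id.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occs, stacks, path) {
  rows <- lapply(occs, function(o) {
    ref <- stacks[[o$island_id]]$layers[[1]]
    nr <- nrow(ref$values)
    data.frame(
      ecomorph = o$ecomorph, island = o$island_id,
      x = ref$origin[1] + (o$cells[, "col"] - 0.5) * ref$cell_size,
      y = ref$origin[2] + (nr - o$cells[, "row"] + 0.5) * ref$cell_size)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
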