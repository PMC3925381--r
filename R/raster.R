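#' Single-band raster grid with a validity mask
#'
#' A `grid_raster` is the package's basic spatial container: one co-registered
#' layer of cell values plus a logical mask separating island cells from
#' nodata/ocean. Row 1 is the northernmost row; `origin` is the lower-left
#' corner `(x0, y0)` in map units.
#'
#' @param values Numeric matrix of cell values (may contain `NA` off-mask).
#' @param mask Logical matrix, `TRUE` for valid island cells. Defaults to
#'   `!is.na(values)`.
#' @param cell_size Positive cell edge length in map units.
#' @param origin Numeric length-2 vector, lower-left corner `(x0, y0)`.
#' @param name Layer name.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, mask = NULL, cell_size = 1,
                        origin = c(0, 0), name = "layer") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.matrix(mask) || !is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("'mask' must be a logical matrix with the same shape as 'values'")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("'cell_size' must be a single positive number")
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("'origin' must be a numeric (x0, y0) pair")
  }
  bad <- mask & !is.finite(values)
  if (any(bad)) {
    stop(sprintf("%d masked-valid cells carry non-finite values", sum(bad)))
  }
  structure(list(values = values, mask = mask, cell_size = cell_size,
                 origin = as.numeric(origin), name = as.character(name)),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster '%s'> %d x %d cells, %d valid, cell_size %g\n",
              x$name, nrow(x$values), ncol(x$values), sum(x$mask), x$cell_size))
  v <- x$values[x$mask]
  if (length(v)) cat(sprintf("  range on mask: [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

#' Values at the valid cells of a raster
#'
#' @param r A `grid_raster`.
#' @param cells Optional integer matrix of (row, col) pairs; default all
#'   valid cells in column-major order.
#' @return Numeric vector.
#' @export
raster_values <- function(r, cells = NULL) {
  if (is.null(cells)) return(r$values[r$mask])
  r$values[cells]
}

#' Replace values on a raster, keeping its geometry
#' @param r A `grid_raster`.
#' @param values Either a full matrix or a vector of length `sum(r$mask)`
#'   assigned to valid cells in column-major order.
#' @param name Optional new layer name.
#' @return A `grid_raster`.
#' @export
raster_with_values <- function(r, values, name = r$name) {
  if (is.matrix(values)) {
    m <- values
  } else {
    if (length(values) != sum(r$mask)) {
      stop("vector 'values' must have one entry per valid cell")
    }
    m <- matrix(NA_real_, nrow(r$values), ncol(r$values))
    m[r$mask] <- values
  }
  grid_raster(m, r$mask, r$cell_size, r$origin, name)
}

#' List the valid cells of a raster
#' @param r A `grid_raster`.
#' @return Two-column integer matrix of (row, col) pairs, 1-based.
#' @export
valid_cells <- function(r) {
  which(r$mask, arr.ind = TRUE)[, c("row", "col"), drop = FALSE]
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE
#' header followed by the value matrix (first data row = northernmost row).
#' Cells equal to the nodata value become masked.
#'
#' @param path Path to a `.asc` file.
#' @param name Layer name; defaults to the file stem.
#' @return A `grid_raster`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L) {
      stop(sprintf("unparseable header line %d: '%s'", i, lines[i]))
    }
    hdr[[tolower(tok[1])]] <- suppressWarnings(as.numeric(tok[2]))
    i <- i + 1L
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[f]]) || is.na(hdr[[f]])) {
      stop(sprintf("ESRI ASCII header missing or invalid field: %s", f))
    }
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values (%d x %d), found %d",
                 nr * nc, nr, nc, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m != nodata
  m[!mask] <- NA_real_
  if (!any(mask)) warning(sprintf("raster '%s' has no valid cells", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid_raster(m, mask, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner), name)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r A `grid_raster`.
#' @param path Output path.
#' @param nodata Nodata sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  m <- r$values
  m[!r$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", r$origin[1]),
    sprintf("YLLCORNER %.10g", r$origin[2]),
    sprintf("CELLSIZE %.10g", r$cell_size),
    sprintf("NODATA_VALUE %.10g", nodata)
  ), con)
  writeLines(apply(m, 1L, function(row) paste(format(row, digits = 15, trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " ")), con)
  invisible(path)
}

#' Ordered stack of co-registered environmental layers
#'
#' An `env_stack` holds one island's co-registered layers (must include one
#' named `"elevation"`, in metres) sharing shape, mask, cell size and origin.
#'
#' @param layers Named list of `grid_raster` objects.
#' @param island_id Island identifier.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, island_id) {
  if (!length(layers) || is.null(names(layers)) || anyDuplicated(names(layers))) {
    stop("'layers' must be a non-empty uniquely named list")
  }
  if (!"elevation" %in% names(layers)) {
    stop("an env_stack must contain a layer named 'elevation'")
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "grid_raster")) stop(sprintf("layer '%s' is not a grid_raster", nm))
    if (!identical(dim(l$values), dim(ref$values)) ||
        !identical(l$mask, ref$mask) ||
        l$cell_size != ref$cell_size ||
        !identical(l$origin, ref$origin)) {
      stop(sprintf("layer '%s' is not co-registered with the first layer", nm))
    }
    layers[[nm]]$name <- nm
  }
  structure(list(layers = layers, island_id = as.character(island_id)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack '%s'> %d layers (%s), %d x %d cells, %d valid\n",
              x$island_id, length(x$layers),
              paste(names(x$layers), collapse = ", "),
              nrow(stack_mask(x)), ncol(stack_mask(x)), sum(stack_mask(x))))
  invisible(x)
}

#' Shared validity mask of a stack
#' @param stack An `env_stack`.
#' @return Logical matrix.
#' @export
stack_mask <- function(stack) stack$layers[[1]]$mask

#' Tile island stacks side-by-side into one common-extent stack
#'
#' Builds the archipelago-wide background/projection extent by placing the
#' islands' grids next to each other (one masked separator column between
#' islands) on a shared grid. All stacks must share cell size and layer names.
#'
#' @param stacks List of `env_stack` objects.
#' @param island_id Identifier for the combined stack.
#' @return An `env_stack` with attribute `"offsets"`: named list per island of
#'   `(row_offset, col_offset)` to add to that island's 1-based cell indices.
#' @export
stack_union <- function(stacks, island_id = "union") {
  if (length(stacks) < 1L) stop("need at least one stack")
  nms <- names(stacks[[1]]$layers)
  cs <- stacks[[1]]$layers[[1]]$cell_size
  for (s in stacks) {
    if (!identical(names(s$layers), nms)) stop("stacks must share layer names and order")
    if (s$layers[[1]]$cell_size != cs) stop("stacks must share cell size")
  }
  nrows <- max(vapply(stacks, function(s) nrow(stack_mask(s)), 1L))
  widths <- vapply(stacks, function(s) ncol(stack_mask(s)), 1L)
  ncols <- sum(widths) + length(stacks) - 1L
  offsets <- list()
  layers <- lapply(nms, function(nm) matrix(NA_real_, nrows, ncols))
  names(layers) <- nms
  mask <- matrix(FALSE, nrows, ncols)
  col0 <- 0L
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    nr <- nrow(stack_mask(s)); nc <- ncol(stack_mask(s))
    offsets[[s$island_id]] <- c(row = 0L, col = col0)
    mask[seq_len(nr), col0 + seq_len(nc)] <- stack_mask(s)
    for (nm in nms) {
      layers[[nm]][seq_len(nr), col0 + seq_len(nc)] <- s$layers[[nm]]$values
    }
    col0 <- col0 + nc + 1L
  }
  gl <- lapply(nms, function(nm) {
    v <- layers[[nm]]
    v[!mask] <- NA_real_
    grid_raster(v, mask, cs, c(0, 0), nm)
  })
  names(gl) <- nms
  out <- env_stack(gl, island_id)
  attr(out, "offsets") <- offsets
  out
}

#' Map one island's cell indices onto a union stack
#' @param union_stack Result of [stack_union()].
#' @param island_id Island whose cells to translate.
#' @param cells Two-column (row, col) matrix on the island grid.
#' @return Two-column (row, col) matrix on the union grid.
#' @export
union_cells <- function(union_stack, island_id, cells) {
  off <- attr(union_stack, "offsets")[[island_id]]
  if (is.null(off)) stop(sprintf("island '%s' not part of this union stack", island_id))
  cbind(row = cells[, 1] + off["row"], col = cells[, 2] + off["col"],
        deparse.level = 0)
}
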