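#' Default ecomorph ground truth for synthetic landscapes
#'
#' Six ecomorphs in the canonical body-mass order (twig < grass-bush < trunk
#' < trunk-crown < trunk-ground < crown-giant), each with a Gaussian
#' elevational suitability optimum. In the mountain setting the optimum
#' decreases strictly with mass rank, so small ecomorphs are restricted to
#' high elevations -- the known-sign target the trait analysis must recover.
#'
#' The optima all sit above the low-elevation bulk of a typical island and the
#' breadth grows with mass rank, so every ecomorph's suitability rises with
#' elevation (community completeness peaks in the mountains) while the
#' strength of that elevational constraint decreases with body mass: small
#' ecomorphs are narrowly restricted to high ground, large ones are
#' widespread.
#'
#' @return Data frame with columns `ecomorph`, `mass_rank`, `mu` (elevational
#'   optimum, m), `sigma` (breadth, m).
#' @export
default_ecomorph_truth <- function() {
  eco <- c("twig", "grass-bush", "trunk", "trunk-crown", "trunk-ground",
           "crown-giant")
  data.frame(ecomorph = eco,
             mass_rank = 1:6,
             mu = 1800 - (0:5) * 150,    # 1800 m down to 1050 m
             sigma = 200 + (0:5) * 80,   # 200 m up to 600 m
             stringsAsFactors = FALSE)
}

#' Default climate-layer specification
#'
#' Mountain islands get two elevation-coupled layers (mean temperature with a
#' standard 6.5 K/km lapse rate, temperature range with a weaker lapse) plus
#' one elevation-independent smoothed random field (precipitation). The
#' flat-climate variant makes the temperature-range layer elevation-
#' independent and low-variance, emulating an island whose temperature ranges
#' are lower and decoupled from relief.
#'
#' @param type `"mountain"` or `"flat-climate"`.
#' @return Named list of per-layer specs.
#' @export
default_climate_spec <- function(type = c("mountain", "flat-climate")) {
  type <- match.arg(type)
  spec <- list(
    temp_mean = list(coupled = TRUE, slope = -0.0065, intercept = 26,
                     noise_sd = 0.4),
    temp_range = list(coupled = TRUE, slope = -0.003, intercept = 14,
                      noise_sd = 0.5),
    precip = list(coupled = FALSE, mean = 1500, sd = 300, smooth = 3),
    precip_seasonality = list(coupled = FALSE, mean = 40, sd = 8, smooth = 3)
  )
  if (type == "flat-climate") {
    spec$temp_range <- list(coupled = FALSE, mean = 8, sd = 1.2, smooth = 3)
  }
  spec
}

# Separable Gaussian smoothing of a matrix via banded row/column operators,
# edge-normalised so borders are not damped.
gaussian_smooth <- function(m, sigma) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > 3 * sigma] <- 0
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate one synthetic island environment
#'
#' Builds an elliptical island mask, an elevation surface as a sum of
#' Gaussian peaks (non-negative, positive maximum), and climate layers that
#' are either linear in elevation plus Gaussian noise (coupled) or smoothed
#' Gaussian random fields independent of elevation (uncoupled).
#'
#' @param seed Integer seed; the same seed reproduces the stack exactly.
#' @param shape `(rows, cols)`, both at least 20.
#' @param n_peaks Number of elevation peaks, at least 1.
#' @param relief Approximate maximum peak amplitude in metres.
#' @param island_id Identifier stored on the stack.
#' @param climate Per-layer spec as from [default_climate_spec()].
#' @param cell_size Cell edge in map units.
#' @return An `env_stack` with layers `elevation` plus the climate layers,
#'   and attribute `"climate_truth"` (data frame: layer, coupled, slope,
#'   noise_sd).
#' @export
make_island <- function(seed, shape = c(60, 80), n_peaks = 3, relief = 1800,
                        island_id = "island", climate = default_climate_spec(),
                        cell_size = 1) {
  if (length(shape) != 2L || any(shape < 20)) {
    stop("'shape' must be (rows, cols) with both dimensions >= 20")
  }
  if (n_peaks < 1) stop("'n_peaks' must be >= 1")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  set.seed(sub_seed(seed, 11))
  # elliptical island mask
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cr <- (nr + 1) / 2; ccn <- (nc + 1) / 2
  mask <- ((rr - cr) / (0.44 * nr))^2 + ((cc - ccn) / (0.44 * nc))^2 <= 1
  # elevation: sum of Gaussian peaks centred inside the island
  elev <- matrix(0, nr, nc)
  for (p in seq_len(n_peaks)) {
    pr <- cr + stats::runif(1, -0.25, 0.25) * nr
    pc <- ccn + stats::runif(1, -0.25, 0.25) * nc
    amp <- relief * stats::runif(1, 0.55, 1)
    wid <- stats::runif(1, 0.10, 0.18) * sqrt(nr * nc)
    elev <- elev + amp * exp(-((rr - pr)^2 + (cc - pc)^2) / (2 * wid^2))
  }
  layers <- list(elevation = NULL)
  truth <- data.frame(layer = character(), coupled = logical(),
                      slope = numeric(), noise_sd = numeric(),
                      stringsAsFactors = FALSE)
  for (nm in names(climate)) {
    sp <- climate[[nm]]
    if (isTRUE(sp$coupled)) {
      v <- sp$intercept + sp$slope * elev +
        stats::rnorm(nr * nc, sd = sp$noise_sd)
      truth <- rbind(truth, data.frame(layer = nm, coupled = TRUE,
                                       slope = sp$slope,
                                       noise_sd = sp$noise_sd))
    } else {
      f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sp$smooth)
      v <- sp$mean + sp$sd * f / stats::sd(as.vector(f))
      truth <- rbind(truth, data.frame(layer = nm, coupled = FALSE,
                                       slope = 0, noise_sd = sp$sd))
    }
    layers[[nm]] <- matrix(v, nr, nc)
  }
  layers$elevation <- elev
  gl <- lapply(names(layers), function(nm) {
    v <- layers[[nm]]
    v[!mask] <- NA_real_
    grid_raster(v, mask, cell_size, c(0, 0), nm)
  })
  names(gl) <- names(layers)
  out <- env_stack(gl[c("elevation", setdiff(names(gl), "elevation"))], island_id)
  attr(out, "climate_truth") <- truth
  out
}

#' Ground-truth suitability of an ecomorph over an island
#'
#' Per-cell suitability is a Gaussian response to elevation,
#' `s(x) = exp(-(elev(x) - mu)^2 / (2 sigma^2))`, in (0, 1], attaining 1
#' where elevation equals the ecomorph's optimum.
#'
#' @param truth Data frame as from [default_ecomorph_truth()] (or the
#'   `$ecomorphs` element of an archipelago truth).
#' @param ecomorph Ecomorph name present in `truth`.
#' @param stack An `env_stack`.
#' @return A `grid_raster` of suitabilities on the island mask.
#' @export
true_suitability <- function(truth, ecomorph, stack) {
  if (!is.data.frame(truth)) truth <- truth$ecomorphs
  row <- truth[truth$ecomorph == ecomorph, , drop = FALSE]
  if (nrow(row) != 1L) stop(sprintf("ecomorph '%s' not in truth", ecomorph))
  elev <- stack$layers$elevation
  s <- exp(-(elev$values - row$mu)^2 / (2 * row$sigma^2))
  raster_with_values(elev, s, name = paste0("suitability_", ecomorph))
}

#' Sample presence cells from the ground-truth suitability
#'
#' Cells are drawn without replacement with probability proportional to
#' [true_suitability()], so presences are unique cells by construction.
#'
#' @inheritParams true_suitability
#' @param n Number of presence cells (at most the valid-cell count).
#' @param seed Integer seed.
#' @return An `occurrence_set`.
#' @export
sample_occurrences <- function(truth, ecomorph, stack, n, seed) {
  s <- true_suitability(truth, ecomorph, stack)
  cells <- valid_cells(s)
  if (n < 1) stop("'n' must be >= 1")
  if (n > nrow(cells)) {
    stop(sprintf("n = %d exceeds the %d valid island cells", n, nrow(cells)))
  }
  set.seed(sub_seed(seed, 23))
  idx <- sample.int(nrow(cells), n, replace = FALSE, prob = s$values[cells])
  occurrence_set(ecomorph, stack$island_id, cells[idx, , drop = FALSE])
}

#' Generate a synthetic archipelago with known ground truth
#'
#' `"mountain"` islands have high relief and elevation-coupled temperature
#' layers; ecomorph occurrences follow elevational optima that decrease with
#' body-mass rank (small ecomorphs high). `"flat-climate"` islands have low
#' relief, an elevation-independent temperature-range layer, and very broad
#' elevational tolerances (occupancy effectively decoupled from elevation),
#' and carry only four ecomorphs (no grass-bush, no trunk). `"mixed"` makes
#' the last island flat-climate and the rest mountain.
#'
#' @param seed Integer master seed.
#' @param n_islands Number of islands (>= 1; `"mixed"` needs >= 2).
#' @param scenario One of `"mountain"`, `"flat-climate"`, `"mixed"`.
#' @param shape Grid shape per island.
#' @param n_occ Presence cells sampled per ecomorph per island.
#' @param sigma_flat Suitability breadth (m) used on flat-climate islands.
#' @return A list with elements `stacks` (named list of `env_stack`),
#'   `occurrences` (named list of `occurrence_set`, `"<island>/<ecomorph>"`),
#'   and `truth` (list: `ecomorphs` data frame, `islands` data frame,
#'   `climate` per-island data frames).
#' @export
make_archipelago <- function(seed, n_islands = 3,
                             scenario = c("mountain", "flat-climate", "mixed"),
                             shape = c(60, 80), n_occ = 150,
                             sigma_flat = 3000) {
  scenario <- match.arg(scenario)
  if (n_islands < 1) stop("'n_islands' must be >= 1")
  if (scenario == "mixed" && n_islands < 2) {
    stop("'mixed' needs at least 2 islands")
  }
  types <- switch(scenario,
    "mountain" = rep("mountain", n_islands),
    "flat-climate" = rep("flat-climate", n_islands),
    "mixed" = c(rep("mountain", n_islands - 1), "flat-climate"))
  eco_truth <- default_ecomorph_truth()
  stacks <- list(); occs <- list(); climates <- list()
  isl_df <- data.frame(island = character(), type = character(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_islands)) {
    ty <- types[i]
    id <- sprintf("island_%d", i)
    st <- make_island(sub_seed(seed, 100, i),
                      shape = shape,
                      n_peaks = if (ty == "mountain") 3 else 2,
                      relief = if (ty == "mountain") 1800 else 250,
                      island_id = id,
                      climate = default_climate_spec(ty))
    stacks[[id]] <- st
    climates[[id]] <- attr(st, "climate_truth")
    isl_df <- rbind(isl_df, data.frame(island = id, type = ty,
                                       stringsAsFactors = FALSE))
    ecos <- eco_truth$ecomorph
    tr <- eco_truth
    if (ty == "flat-climate") {
      ecos <- setdiff(ecos, c("grass-bush", "trunk"))
      tr$sigma <- sigma_flat
    }
    for (eco in ecos) {
      occs[[paste(id, eco, sep = "/")]] <-
        sample_occurrences(tr, eco, st, n_occ, sub_seed(seed, 200, i,
                                                        match(eco, eco_truth$ecomorph)))
    }
  }
  list(stacks = stacks, occurrences = occs,
       truth = list(ecomorphs = eco_truth, islands = isl_df,
                    climate = climates))
}
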