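#' Feature specification for the presence-background niche model
#'
#' Features are linear and quadratic terms of each environmental layer,
#' standardized with mean/sd computed on the background sample. Layers that
#' are constant over the background carry no information and are dropped
#' with a warning.
#'
#' @param stack An `env_stack`.
#' @param background_cells Two-column (row, col) matrix of background cells.
#' @param linear,quadratic Include linear / quadratic terms per layer.
#' @param layers Layer names to use; default all layers of the stack.
#' @return An object of class `feature_spec` with per-layer `mean`, `sd` and
#'   the feature table (`layer`, `degree`, `name`).
#' @export
make_feature_spec <- function(stack, background_cells, linear = TRUE,
                              quadratic = TRUE, layers = names(stack$layers)) {
  if (!linear && !quadratic) stop("at least one feature class must be enabled")
  mu <- sdv <- numeric(0)
  keep <- character(0)
  for (nm in layers) {
    v <- stack$layers[[nm]]$values[background_cells]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("layer '%s' is constant on the background; dropped", nm))
      next
    }
    keep <- c(keep, nm)
    mu[nm] <- mean(v); sdv[nm] <- s
  }
  if (!length(keep)) stop("no usable (non-constant) layers")
  feats <- do.call(rbind, lapply(keep, function(nm) {
    d <- c(if (linear) 1L, if (quadratic) 2L)
    data.frame(layer = nm, degree = d,
               name = paste0(nm, c("", "^2")[d]),
               stringsAsFactors = FALSE)
  }))
  structure(list(layers = keep, mean = mu, sd = sdv, features = feats),
            class = "feature_spec")
}

#' Evaluate the feature matrix at a set of cells
#'
#' @param spec A `feature_spec`.
#' @param stack An `env_stack` containing at least the spec's layers.
#' @param cells Two-column (row, col) matrix.
#' @return Numeric matrix, one column per feature.
#' @export
feature_matrix <- function(spec, stack, cells) {
  miss <- setdiff(spec$layers, names(stack$layers))
  if (length(miss)) {
    stop(sprintf("stack is missing layer(s) required by the model: %s",
                 paste(miss, collapse = ", ")))
  }
  out <- matrix(NA_real_, nrow(cells), nrow(spec$features))
  colnames(out) <- spec$features$name
  for (j in seq_len(nrow(spec$features))) {
    nm <- spec$features$layer[j]
    z <- (stack$layers[[nm]]$values[cells] - spec$mean[nm]) / spec$sd[nm]
    out[, j] <- if (spec$features$degree[j] == 1L) z else z^2
  }
  if (any(!is.finite(out))) stop("non-finite feature values encountered")
  out
}

#' Draw background cells uniformly from an extent
#'
#' @param stack An `env_stack` defining the background extent (an island or a
#'   [stack_union()] of islands).
#' @param n Number of background points; if `n` meets or exceeds the number
#'   of valid cells, all cells are returned with a warning.
#' @param seed Integer seed.
#' @return Two-column (row, col) matrix of unique cells.
#' @export
draw_background <- function(stack, n, seed) {
  cells <- valid_cells(stack$layers[[1]])
  if (nrow(cells) == 0L) stop("background extent has an empty mask")
  if (n >= nrow(cells)) {
    if (n > nrow(cells)) {
      warning(sprintf("requested %d background points but only %d valid cells; using all",
                      n, nrow(cells)))
    }
    return(cells)
  }
  set.seed(sub_seed(seed, 37))
  cells[sample.int(nrow(cells), n), , drop = FALSE]
}

# Penalized presence log-likelihood of the Gibbs model and its gradient.
# F_bg: background feature matrix; fbar: presence feature means.
maxent_objective <- function(lambda, fbar, F_bg, beta) {
  eta <- drop(F_bg %*% lambda)
  m <- max(eta)
  logZ <- m + log(sum(exp(eta - m)))
  sum(lambda * fbar) - logZ - sum(beta * abs(lambda))
}

maxent_smooth_grad <- function(lambda, fbar, F_bg) {
  eta <- drop(F_bg %*% lambda)
  w <- exp(eta - max(eta)); w <- w / sum(w)
  fbar - drop(crossprod(F_bg, w))
}

#' Fit a maximum-entropy presence-background niche model
#'
#' Fits the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over the
#' background cells by maximizing the L1-penalized presence log-likelihood
#' `mean_presence(lambda . f) - log Z - sum_j beta_j |lambda_j|`
#' with proximal gradient ascent (soft-thresholding step, backtracking line
#' search). Per-feature penalties follow the sample-size scaling
#' `beta_j = beta0 * s_j / sqrt(m)` where `s_j` is the presence-sample sd of
#' feature `j` and `m` the presence count. The entropy `H = -sum q log q` of
#' the fitted distribution calibrates the logistic output so that a site with
#' "typical" conditions (raw probability `exp(-H)`) scores exactly 0.5.
#'
#' @param presence_cells Two-column (row, col) matrix, at least 5 rows.
#' @param background_cells Two-column (row, col) matrix.
#' @param stack `env_stack` used to evaluate presence features.
#' @param feature_spec A `feature_spec`; built from the background if `NULL`.
#' @param beta0 Base regularization scale (> 0).
#' @param tol Convergence tolerance on the objective change.
#' @param grad_tol Subgradient optimality tolerance for active features.
#' @param max_iter Iteration cap; exceeding it is an error with diagnostics.
#' @param background_stack Stack used to evaluate background features
#'   (defaults to `stack`; differs when the background is a union extent).
#' @return An object of class `maxent_model` with elements `lambda`, `Z`, `H`,
#'   `feature_spec`, `objective`, `iterations`, plus the background raw
#'   probabilities `q_background` (summing to 1).
#' @export
fit_maxent <- function(presence_cells, background_cells, stack,
                       feature_spec = NULL, beta0 = 1.0, tol = 1e-8,
                       grad_tol = 1e-6, max_iter = 10000L,
                       background_stack = stack) {
  if (nrow(presence_cells) < 5L) {
    stop("need at least 5 presence cells to fit a niche model")
  }
  if (is.null(feature_spec)) {
    feature_spec <- make_feature_spec(background_stack, background_cells)
  }
  F_bg <- feature_matrix(feature_spec, background_stack, background_cells)
  F_pr <- feature_matrix(feature_spec, stack, presence_cells)
  fbar <- colMeans(F_pr)
  s_j <- apply(F_pr, 2, stats::sd)
  beta <- beta0 * pmax(s_j, 1e-6) / sqrt(nrow(F_pr))

  J <- ncol(F_bg)
  # Split formulation lambda = u - v with u, v >= 0 turns the L1 penalty into
  # a smooth bound-constrained problem solvable by L-BFGS-B; a proximal
  # polish afterwards enforces the stated KKT tolerance.
  neg_obj_uv <- function(uv) {
    lam <- uv[1:J] - uv[J + 1:J]
    -(maxent_objective(lam, fbar, F_bg, numeric(J)) - sum(beta * uv))
  }
  neg_grad_uv <- function(uv) {
    lam <- uv[1:J] - uv[J + 1:J]
    g <- maxent_smooth_grad(lam, fbar, F_bg)
    -c(g - beta, -g - beta)
  }
  opt <- stats::optim(rep(0, 2 * J), neg_obj_uv, neg_grad_uv,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = max_iter, factr = 10))
  lambda <- opt$par[1:J] - opt$par[J + 1:J]
  lambda[abs(lambda) < 1e-12] <- 0
  obj <- maxent_objective(lambda, fbar, F_bg, beta)
  # proximal-gradient polish until the objective change and subgradient
  # optimality criteria hold
  converged <- FALSE
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- maxent_smooth_grad(lambda, fbar, F_bg)
    active <- lambda != 0
    kkt_active <- !any(active) ||
      max(abs(g[active] - beta[active] * sign(lambda[active]))) <= grad_tol
    kkt_zero <- all(abs(g[!active]) <= beta[!active] + grad_tol)
    if (kkt_active && kkt_zero) { converged <- TRUE; break }
    repeat {
      cand <- sign(lambda + step * g) * pmax(abs(lambda + step * g) - step * beta, 0)
      new_obj <- maxent_objective(cand, fbar, F_bg, beta)
      if (new_obj >= obj - 1e-15 || max(abs(cand - lambda)) == 0) break
      step <- step / 2
    }
    if (max(abs(cand - lambda)) == 0 && new_obj - obj < tol) {
      # fixed point of the proximal map: optimal to numerical precision
      converged <- TRUE; break
    }
    lambda <- cand
    obj <- max(new_obj, obj)
    step <- min(step * 1.5, 1e6)
  }
  if (!converged) {
    g <- maxent_smooth_grad(lambda, fbar, F_bg)
    stop(sprintf(paste0("maxent fit failed to converge in %d iterations ",
                        "(objective %.8g, max |grad| %.3g)"),
                 max_iter, obj, max(abs(g))))
  }
  it <- opt$counts[["function"]] + it
  eta <- drop(F_bg %*% lambda)
  mx <- max(eta)
  Z <- sum(exp(eta - mx)) * exp(mx)
  q <- exp(eta - mx) / sum(exp(eta - mx))
  H <- -sum(q * log(pmax(q, .Machine$double.xmin)))
  structure(list(lambda = stats::setNames(lambda, colnames(F_bg)),
                 Z = Z, H = H, feature_spec = feature_spec,
                 beta = beta, objective = obj, iterations = it,
                 q_background = q, n_presence = nrow(F_pr),
                 n_background = nrow(F_bg)),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features, %d presences vs %d background\n",
              length(x$lambda), x$n_presence, x$n_background))
  cat(sprintf("  H = %.4f nats, converged in %d iterations\n", x$H, x$iterations))
  print(round(x$lambda, 4))
  invisible(x)
}

# Raw Gibbs density q(x) relative to the training background normalizer.
raw_scores <- function(model, stack, cells) {
  F_x <- feature_matrix(model$feature_spec, stack, cells)
  exp(drop(F_x %*% model$lambda)) / model$Z
}

#' Logistic suitability surface of a fitted model
#'
#' Transforms the raw Gibbs density `q(x)` to the logistic scale
#' `p(x) = e^H q(x) / (1 + e^H q(x))`, calibrated so that a cell with typical
#' conditions (`q = e^-H`) scores exactly 0.5.
#'
#' @param model A `maxent_model`.
#' @param stack `env_stack` to evaluate on (its mask defines the output map).
#' @return A `grid_raster` with values in (0, 1) on the mask.
#' @export
logistic_map <- function(model, stack) {
  cells <- valid_cells(stack$layers[[1]])
  q <- raw_scores(model, stack, cells)
  z <- exp(model$H) * q
  p <- z / (1 + z)
  raster_with_values(stack$layers[[1]], p, name = "suitability")
}

# Rank (Mann-Whitney) AUC from score vectors; ties count 0.5.
auc_scores <- function(pos, neg) {
  if (!length(pos)) stop("need at least one positive (presence) score")
  if (!length(neg)) stop("need at least one negative (background) score")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Held-out AUC of a fitted niche model
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of test presences
#' against background cells, ties counted one half.
#'
#' @param model A `maxent_model`.
#' @param test_cells Presence cells held out from fitting.
#' @param background_cells Background cells.
#' @param stack `env_stack` for the test presences.
#' @param background_stack `env_stack` for the background (default `stack`).
#' @return AUC in [0, 1].
#' @export
auc <- function(model, test_cells, background_cells, stack,
                background_stack = stack) {
  if (nrow(test_cells) < 1L) stop("need at least one test presence")
  auc_scores(raw_scores(model, stack, test_cells),
             raw_scores(model, background_stack, background_cells))
}

#' Fit a replicate ensemble of niche models for one ecomorph
#'
#' Each replicate draws a fresh seeded 75/25 train/test split (fraction from
#' the config), a fresh background sample from the designated background
#' extent, fits the penalized Gibbs model, records the held-out AUC, and
#' evaluates the logistic map on the occurrence island. The ensemble map is
#' the cellwise mean of the replicate maps (median available via `combine`).
#'
#' @param occ An `occurrence_set` with at least 8 cells.
#' @param stack The occurrence island's `env_stack`.
#' @param background_stack Extent for background draws and feature
#'   standardization (the island itself, or a [stack_union()] for
#'   archipelago-wide backgrounds). Default: `stack`.
#' @param config A [run_config()]; uses `n_replicates`, `n_background`,
#'   `test_fraction`, `regularization`, `seed`.
#' @param combine `"mean"` or `"median"` cellwise combination.
#' @return An object of class `suitability_ensemble`: `maps` (list of
#'   replicate `grid_raster`), `mean_map`, `models`, `test_auc` vector and
#'   `mean_test_auc`.
#' @export
fit_ensemble <- function(occ, stack, background_stack = stack, config = run_config(),
                         combine = c("mean", "median")) {
  combine <- match.arg(combine)
  m <- nrow(occ$cells)
  if (m < 8L) {
    stop(sprintf("ecomorph '%s' on %s has %d occurrences; at least 8 are needed so the 75/25 split keeps >= 2 test points",
                 occ$ecomorph, occ$island_id, m))
  }
  own_cells <- occ$cells
  maps <- vector("list", config$n_replicates)
  models <- vector("list", config$n_replicates)
  aucs <- numeric(config$n_replicates)
  n_test <- max(1L, round(config$test_fraction * m))
  for (r in seq_len(config$n_replicates)) {
    rs <- sub_seed(config$seed, 300, r, nchar(occ$ecomorph), nrow(own_cells))
    set.seed(rs)
    test_idx <- sample.int(m, n_test)
    bg <- draw_background(background_stack, config$n_background, rs)
    spec <- make_feature_spec(background_stack, bg)
    fit <- fit_maxent(own_cells[-test_idx, , drop = FALSE], bg, stack,
                      feature_spec = spec, beta0 = config$regularization,
                      background_stack = background_stack)
    maps[[r]] <- logistic_map(fit, stack)
    aucs[r] <- auc(fit, own_cells[test_idx, , drop = FALSE], bg, stack,
                   background_stack)
    models[[r]] <- fit
  }
  vals <- vapply(maps, function(mp) mp$values[mp$mask],
                 numeric(sum(stack_mask(stack))))
  comb <- if (combine == "mean") rowMeans(vals) else apply(vals, 1, stats::median)
  mean_map <- raster_with_values(stack$layers[[1]], comb,
                                 name = paste0("suitability_", occ$ecomorph))
  structure(list(ecomorph = occ$ecomorph, island_id = occ$island_id,
                 maps = maps, mean_map = mean_map, models = models,
                 test_auc = aucs, mean_test_auc = mean(aucs),
                 combine = combine),
            class = "suitability_ensemble")
}

#' @export
print.suitability_ensemble <- function(x, ...) {
  cat(sprintf("<suitability_ensemble> %s on %s: %d replicates, mean test AUC %.3f\n",
              x$ecomorph, x$island_id, length(x$maps), x$mean_test_auc))
  invisible(x)
}

#' Project a fitted ensemble onto another extent
#'
#' Evaluates every replicate model's logistic map on the target stack's mask
#' and combines them as in the original fit.
#'
#' @param ens A `suitability_ensemble`.
#' @param stack Target `env_stack` (must carry the model's layers).
#' @return A `grid_raster` on the target mask.
#' @export
project_ensemble <- function(ens, stack) {
  vals <- vapply(ens$models, function(mod) {
    mp <- logistic_map(mod, stack)
    mp$values[mp$mask]
  }, numeric(sum(stack_mask(stack))))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(ens$models))
  comb <- if (ens$combine == "mean") rowMeans(vals) else apply(vals, 1, stats::median)
  raster_with_values(stack$layers[[1]], comb,
                     name = paste0("suitability_", ens$ecomorph, "_on_",
                                   stack$island_id))
}
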