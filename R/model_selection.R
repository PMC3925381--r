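#' Build the per-island candidate model set explaining ECC
#'
#' The standard set holds five models: a global model (elevation plus all
#' BioPCs), elevation only, all BioPCs without elevation, the
#' elevation-dependent BioPCs, and the elevation-independent BioPCs. When the
#' dependence partition flags every BioPC as elevation-dependent, the
#' dependent/independent pair is replaced by one model per single BioPC
#' (the variant used where no climate axis is free of elevation).
#' Degenerate duplicates (identical predictor sets) are removed with a
#' warning; an empty dependent or independent set drops that model with a
#' warning.
#'
#' @param biopcs Character vector of BioPC names (e.g. `"BioPC1"..`).
#' @param partition Result of [classify_elevation_dependence()], or a list
#'   with `dependent`, `independent`, `all_dependent`.
#' @return Named list of model specs, each a list with `name` and
#'   `predictors`.
#' @export
build_candidates <- function(biopcs, partition) {
  if (!length(biopcs)) stop("need at least one BioPC")
  specs <- list(
    global = c("elevation", biopcs),
    `elevation-only` = "elevation",
    `all-biopcs` = biopcs
  )
  if (isTRUE(partition$all_dependent)) {
    for (b in biopcs) specs[[paste0("single-", b)]] <- b
  } else {
    if (length(partition$dependent)) {
      specs[["elev-dependent"]] <- partition$dependent
    } else {
      warning("no elevation-dependent BioPCs; that model omitted")
    }
    if (length(partition$independent)) {
      specs[["elev-independent"]] <- partition$independent
    } else {
      warning("no elevation-independent BioPCs; that model omitted")
    }
  }
  keys <- vapply(specs, function(p) paste(sort(p), collapse = "|"), "")
  dup <- duplicated(keys)
  if (any(dup)) {
    warning(sprintf("dropping duplicate candidate model(s): %s",
                    paste(names(specs)[dup], collapse = ", ")))
    specs <- specs[!dup]
  }
  lapply(stats::setNames(names(specs), names(specs)),
         function(nm) list(name = nm, predictors = specs[[nm]]))
}

#' Ordinary least-squares fit with Gaussian maximum likelihood
#'
#' Fits `y ~ X` by least squares and evaluates the Gaussian log-likelihood at
#' the ML variance (residual sum of squares over n, floored at 1e-12 so an
#' exact fit stays finite). The parameter count `k` includes the intercept
#' and the variance.
#'
#' @param y Response vector (ECC values).
#' @param X Data frame / matrix of predictor columns (may have zero columns
#'   for the intercept-only model).
#' @param name Model name.
#' @return A `candidate_model` list: `name`, `predictors`, `coefficients`,
#'   `se`, `sigma2`, `logLik`, `k`, `n`.
#' @export
fit_linear <- function(y, X, name = "model") {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X) + 2L
  if (n <= k - 1L) stop(sprintf("model '%s': n = %d too small for %d parameters",
                                name, n, k))
  df <- cbind(data.frame(.y = y), X)
  fit <- if (ncol(X) == 0L) stats::lm(.y ~ 1, data = df)
         else stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("model '%s': rank-deficient design; collinear column(s): %s",
                 name, paste(bad, collapse = ", ")))
  }
  res <- stats::residuals(fit)
  sigma2 <- max(sum(res^2) / n, 1e-12)
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1)
  # suppress summary.lm's perfect-fit warning: the variance floor below makes
  # the likelihood finite and the SEs are reported as-is
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(list(name = name, predictors = colnames(X),
                 coefficients = stats::coef(fit),
                 se = sm[, "Std. Error"],
                 sigma2 = sigma2, logLik = ll, k = k, n = n),
            class = "candidate_model")
}

# AICc at the stated small-sample correction.
aicc_value <- function(logLik, k, n) {
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Computes AICc, delta-AICc and Akaike weights. A model with Akaike weight
#' of at least 0.9 is reported as the single most parsimonious model;
#' averaging is indicated when the AICc gap between the two best models is
#' under 3. Models whose parameter count leaves no residual degrees of
#' freedom (`n <= k + 1`) are rejected with a message.
#'
#' @param models List of `candidate_model` objects (same data).
#' @param n Number of observations (defaults to the models' own `n`).
#' @return An object of class `selection_table`: `table` (data frame: name,
#'   predictors, k, logLik, AICc, delta, weight, ranked), `single_best`
#'   (name or `NA`), `averaging_applied`, `models`.
#' @export
aicc_rank <- function(models, n = NULL) {
  if (!length(models)) stop("need at least one model")
  if (is.null(n)) n <- models[[1]]$n
  ok <- vapply(models, function(m) n > m$k + 1, TRUE)
  if (any(!ok)) {
    message(sprintf("rejecting model(s) with n <= k + 1: %s",
                    paste(vapply(models[!ok], `[[`, "", "name"), collapse = ", ")))
    models <- models[ok]
  }
  if (!length(models)) stop("no model satisfies n > k + 1")
  tab <- data.frame(
    name = vapply(models, `[[`, "", "name"),
    predictors = vapply(models, function(m) paste(m$predictors, collapse = "+"), ""),
    k = vapply(models, function(m) as.numeric(m$k), 1),
    logLik = vapply(models, `[[`, 1, "logLik"),
    stringsAsFactors = FALSE)
  tab$AICc <- aicc_value(tab$logLik, tab$k, n)
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  models <- models[ord]
  single_best <- if (tab$weight[1] >= 0.9) tab$name[1] else NA_character_
  averaging <- nrow(tab) >= 2 && (tab$AICc[2] - tab$AICc[1]) < 3
  structure(list(table = tab, single_best = single_best,
                 averaging_applied = averaging, models = models, n = n),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("<selection_table> n = %d, single best: %s, averaging: %s\n",
              x$n, ifelse(is.na(x$single_best), "none", x$single_best),
              x$averaging_applied))
  print(transform(x$table, AICc = round(AICc, 2), delta = round(delta, 2),
                  weight = round(weight, 4), logLik = round(logLik, 2)))
  invisible(x)
}

#' Model-averaged coefficients with unconditional errors
#'
#' Full-set ("shrinkage") averaging across all ranked candidates: a
#' variable's estimate is the weight-sum of its coefficients with zero
#' substituted where it is absent; the unconditional standard error combines
#' within-model variance and between-model spread,
#' `SE_v = sqrt(sum_i w_i (se_iv^2 + (b_iv - est_v)^2))`; the 95% CI is
#' `estimate +/- 1.96 SE`. Relative importance of a variable is the summed
#' weight of the models containing it. Conditional averaging (over models
#' containing the variable only) is returned alongside.
#'
#' @param table A `selection_table` with `averaging_applied = TRUE` (call the
#'   single best model's coefficients directly otherwise).
#' @return Data frame: variable, estimate, se, ci_lower, ci_upper, z,
#'   importance, estimate_conditional.
#' @export
model_average <- function(table) {
  if (!inherits(table, "selection_table")) stop("expected a selection_table")
  if (!is.na(table$single_best) && !table$averaging_applied) {
    stop(sprintf("a single most parsimonious model ('%s') was identified; use its coefficients directly",
                 table$single_best))
  }
  w <- table$table$weight
  vars <- unique(c("(Intercept)",
                   unlist(lapply(table$models, `[[`, "predictors"))))
  out <- data.frame(variable = vars, estimate = 0, se = 0, importance = 0,
                    estimate_conditional = NA_real_, stringsAsFactors = FALSE)
  for (vi in seq_along(vars)) {
    v <- vars[vi]
    b <- se <- has <- numeric(length(w))
    for (i in seq_along(table$models)) {
      cf <- table$models[[i]]$coefficients
      if (v %in% names(cf)) {
        b[i] <- cf[[v]]
        se[i] <- table$models[[i]]$se[[v]]
        has[i] <- 1
      }
    }
    est <- sum(w * b)
    out$estimate[vi] <- est
    out$se[vi] <- sqrt(sum(w * (se^2 + (b - est)^2)))
    out$importance[vi] <- if (v == "(Intercept)") NA_real_ else sum(w[has == 1])
    if (any(has == 1)) {
      wc <- w[has == 1] / sum(w[has == 1])
      out$estimate_conditional[vi] <- sum(wc * b[has == 1])
    } else {
      out$estimate_conditional[vi] <- 0
    }
  }
  out$ci_lower <- out$estimate - 1.96 * out$se
  out$ci_upper <- out$estimate + 1.96 * out$se
  out$z <- ifelse(out$se > 0, out$estimate / out$se, NA_real_)
  out[, c("variable", "estimate", "se", "ci_lower", "ci_upper", "z",
          "importance", "estimate_conditional")]
}

#' Fit and rank the candidate set for one island
#'
#' @param points Point table ([extract_points()]) for the island.
#' @param biopc `biopc_result` aligned with `points` rows.
#' @param threshold Elevation-dependence cutoff (see
#'   [classify_elevation_dependence()]).
#' @return A `selection_table`; the dependence partition is attached as
#'   attribute `"partition"`.
#' @export
select_models <- function(points, biopc, threshold = 0.5) {
  part <- classify_elevation_dependence(biopc, points$elevation, threshold)
  cands <- build_candidates(colnames(biopc$scores), part)
  dat <- cbind(data.frame(elevation = points$elevation), as.data.frame(biopc$scores))
  fits <- lapply(cands, function(cm) {
    fit_linear(points$ecc, dat[, cm$predictors, drop = FALSE], cm$name)
  })
  out <- aicc_rank(fits, n = nrow(points))
  attr(out, "partition") <- part
  out
}

#' Cross-island model-ranking summary
#'
#' One row per candidate model, one column pair per island carrying delta
#' AICc and Akaike weight; models absent on an island are `NA`.
#'
#' @param tables Named list of `selection_table` (names = island ids).
#' @return Data frame in long format: island, model, predictors, delta,
#'   weight.
#' @export
island_report <- function(tables) {
  if (!length(tables)) stop("need at least one island")
  do.call(rbind, lapply(names(tables), function(isl) {
    t <- tables[[isl]]$table
    data.frame(island = isl, model = t$name, predictors = t$predictors,
               delta = t$delta, weight = t$weight, stringsAsFactors = FALSE)
  }))
}
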