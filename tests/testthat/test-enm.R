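test_that("background draws are uniform, unique and seeded", {
  st <- make_island(4, shape = c(40, 50))
  n_valid <- sum(stack_mask(st))
  bg <- draw_background(st, 500, seed = 3)
  expect_equal(nrow(bg), 500L)
  expect_equal(nrow(unique(bg)), 500L)
  expect_identical(bg, draw_background(st, 500, seed = 3))
  expect_warning(all_bg <- draw_background(st, n_valid + 10, seed = 1),
                 "using all")
  expect_equal(nrow(all_bg), n_valid)
})

test_that("strong regularization with no signal shrinks to the uniform model", {
  st <- ten_cell_stack()
  bg <- valid_cells(st$layers$elevation)
  fit <- fit_maxent(bg, bg, st, beta0 = 50)   # presences = background exactly
  expect_true(all(fit$lambda == 0))
  expect_lt(max(abs(fit$q_background - 1 / nrow(bg))), 1e-3)
})

test_that("single-feature fit matches a brute-force grid search", {
  st <- ten_cell_stack()
  bg <- valid_cells(st$layers$elevation)
  pres <- bg[c(7, 8, 9, 10, 9), , drop = FALSE]   # high-elevation presences
  spec <- make_feature_spec(st, bg, quadratic = FALSE)
  fit <- fit_maxent(pres, bg, st, feature_spec = spec, beta0 = 1)

  f_bg <- feature_matrix(spec, st, bg)[, 1]
  f_pr <- feature_matrix(spec, st, pres)[, 1]
  beta <- 1 * max(sd(f_pr), 1e-6) / sqrt(length(f_pr))
  grid <- seq(-10, 10, by = 1e-3)
  obj <- grid * mean(f_pr) -
    log(colSums(exp(outer(f_bg, grid)))) - beta * abs(grid)
  expect_lt(abs(unname(fit$lambda[1]) - grid[which.max(obj)]), 1e-3 + 1e-9)
})

test_that("the fitted Gibbs distribution is normalized and beats the null", {
  st <- make_island(6, shape = c(30, 40))
  truth <- default_ecomorph_truth()
  occ <- sample_occurrences(truth, "grass-bush", st, 80, seed = 2)
  bg <- draw_background(st, 400, seed = 5)
  fit <- fit_maxent(occ$cells, bg, st)
  expect_lt(abs(sum(fit$q_background) - 1), 1e-9)
  expect_lte(fit$H, log(nrow(bg)) + 1e-12)
  # objective at the solution is no worse than at lambda = 0 (uniform null)
  spec <- fit$feature_spec
  f_pr <- feature_matrix(spec, st, occ$cells)
  null_obj <- -log(nrow(bg))
  expect_gte(fit$objective, null_obj)
  # perturbing any single weight by +/- 0.01 never improves the objective
  f_bg <- feature_matrix(spec, st, bg)
  pen_obj <- function(lam) {
    sum(lam * colMeans(f_pr)) - log(sum(exp(f_bg %*% lam))) -
      sum(fit$beta * abs(lam))
  }
  base <- pen_obj(fit$lambda)
  for (j in seq_along(fit$lambda)) {
    for (d in c(-0.01, 0.01)) {
      lam <- fit$lambda; lam[j] <- lam[j] + d
      expect_lte(pen_obj(lam), base + 1e-10)
    }
  }
})

test_that("the fit is invariant to duplicating the background sample", {
  st <- ten_cell_stack()
  bg <- valid_cells(st$layers$elevation)
  pres <- bg[c(6, 7, 8, 9, 10), , drop = FALSE]
  spec <- make_feature_spec(st, bg, quadratic = FALSE)
  f1 <- fit_maxent(pres, bg, st, feature_spec = spec)
  f2 <- fit_maxent(pres, rbind(bg, bg), st, feature_spec = spec)
  expect_equal(unname(f1$lambda), unname(f2$lambda), tolerance = 1e-5)
})

test_that("logistic output is calibrated, bounded and monotone in q", {
  st <- make_island(9, shape = c(25, 30))
  truth <- default_ecomorph_truth()
  occ <- sample_occurrences(truth, "trunk", st, 60, seed = 3)
  bg <- draw_background(st, 300, seed = 4)
  fit <- fit_maxent(occ$cells, bg, st)
  mp <- logistic_map(fit, st)
  v <- mp$values[mp$mask]
  expect_true(all(v > 0 & v < 1))
  # reconstruct q from the exported pieces and check the transform exactly
  cells <- valid_cells(st$layers$elevation)
  f <- feature_matrix(fit$feature_spec, st, cells)
  q <- exp(drop(f %*% fit$lambda)) / fit$Z
  expect_equal(v, exp(fit$H) * q / (1 + exp(fit$H) * q), tolerance = 1e-12)
  # a typical site (q = e^-H) maps to exactly 0.5; p increases with q
  transform <- function(q) exp(fit$H) * q / (1 + exp(fit$H) * q)
  expect_identical(transform(exp(-fit$H)), 0.5)
  expect_equal(transform(0), 0)
  o <- order(q)
  expect_true(all(diff(v[o]) >= 0))
  # missing layer is reported by name
  st2 <- st; st2$layers$precip <- NULL
  expect_error(logistic_map(fit, st2), "precip")
})

test_that("rank AUC handles separation, ties and the hand-enumerated case", {
  st <- ten_cell_stack()
  expect_equal(oracle_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(oracle_auc(c(0.7, 0.3), c(0.5)), 0.5)
  # brute-force equivalence on random score sets up to 50 points
  set.seed(10)
  for (rep in 1:20) {
    pos <- sample(seq(0, 1, 0.05), sample(2:25, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.05), sample(2:25, 1), replace = TRUE)
    expect_equal(eccniche:::auc_scores(pos, neg), oracle_auc(pos, neg),
                 tolerance = 1e-12)
  }
  expect_equal(eccniche:::auc_scores(c(0.4, 0.4), c(0.4, 0.4)), 0.5)
})

test_that("ensembles split, refit and combine reproducibly", {
  st <- make_island(12, shape = c(30, 40))
  truth <- default_ecomorph_truth()
  occ <- sample_occurrences(truth, "twig", st, 60, seed = 6)
  cfg <- run_config(seed = 2, n_replicates = 1, n_background = 300)
  ens <- fit_ensemble(occ, st, config = cfg)
  expect_equal(ens$mean_map$values, ens$maps[[1]]$values)  # single replicate
  cfg3 <- run_config(seed = 2, n_replicates = 3, n_background = 300)
  e1 <- fit_ensemble(occ, st, config = cfg3)
  e2 <- fit_ensemble(occ, st, config = cfg3)
  expect_identical(e1$mean_map$values, e2$mean_map$values)
  expect_identical(e1$test_auc, e2$test_auc)
  tiny <- occurrence_set("twig", st$island_id, occ$cells[1:5, ])
  expect_error(fit_ensemble(tiny, st, config = cfg), "at least 8")
})

test_that("projection evaluates the fitted models on another island's extent", {
  arch <- make_archipelago(3, n_islands = 2, scenario = "mountain",
                           shape = c(25, 30), n_occ = 60)
  st1 <- arch$stacks[[1]]; st2 <- arch$stacks[[2]]
  occ <- arch$occurrences[[paste0(st1$island_id, "/trunk-ground")]]
  cfg <- run_config(seed = 4, n_replicates = 2, n_background = 300)
  ens <- fit_ensemble(occ, st1, config = cfg)
  proj <- project_ensemble(ens, st2)
  expect_identical(proj$mask, stack_mask(st2))
  v <- proj$values[proj$mask]
  expect_true(all(v > 0 & v < 1))
})
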