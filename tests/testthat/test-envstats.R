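test_that("point extraction yields one clean row per valid cell", {
  elev <- matrix(1:9, 3, 3); elev[2, 2] <- NA
  st <- tiny_stack(elev, temp = 5, rain = 2)
  e <- ecc(list(a = st$layers$temp, b = st$layers$rain), rescale = FALSE)
  pts <- extract_points(st, e)
  expect_equal(nrow(pts), 8L)
  expect_false(anyNA(pts))
  expect_identical(names(pts)[1:5], c("island_id", "cell", "row", "col", "elevation"))
  # spot-check three cells against direct raster lookups
  for (i in c(1, 4, 8)) {
    expect_equal(pts$elevation[i],
                 st$layers$elevation$values[pts$row[i], pts$col[i]])
    expect_equal(pts$ecc[i], e$raster$values[pts$row[i], pts$col[i]])
  }
  expect_false(any(pts$row == 2 & pts$col == 2))  # masked cell absent
  bad <- grid_raster(matrix(1, 3, 3))
  expect_error(extract_points(st, bad), "mask")
})

test_that("bioclimatic PCA follows the correlation-matrix definition", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  pts <- data.frame(island_id = "a", cell = 1:n, row = 1, col = 1,
                    elevation = rnorm(n), v1 = x, v2 = 2 * x + 5,
                    ecc = rnorm(n))
  p <- pca_bioclim(pts)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p$retained, 1L)
  expect_equal(sum(p$eigenvalues), 2, tolerance = 1e-9)

  # independent variables: eigenvalues near 1, scores reproduce the rotation
  pts2 <- data.frame(island_id = "a", cell = 1:10000, row = 1, col = 1,
                     elevation = 0, v1 = rnorm(10000), v2 = rnorm(10000),
                     v3 = rnorm(10000), v4 = rnorm(10000), ecc = 0)
  p2 <- pca_bioclim(pts2)
  expect_true(all(abs(p2$eigenvalues - 1) < 0.1))
  expect_equal(sum(p2$eigenvalues), 4, tolerance = 1e-9)
  Z <- scale(as.matrix(pts2[, c("v1", "v2", "v3", "v4")]))
  expect_equal(unname(Z %*% p2$loadings), unname(p2$scores_all),
               tolerance = 1e-9)
  # scores of distinct components are uncorrelated
  cc <- crossprod(p2$scores_all) / (nrow(Z) - 1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8 * max(p2$eigenvalues))
  pts2$v1 <- 7
  expect_error(pca_bioclim(pts2), "constant")
})

test_that("k-means subsampling returns the contracted dataset sizes", {
  set.seed(5)
  scores <- matrix(rnorm(4000), ncol = 2)
  # 100 clusters x 10 points and x 1 point, all clusters large enough
  # unstructured normal scores: some found clusters may hold fewer than 10
  i10 <- suppressWarnings(kmeans_subsample(scores, 100, 10, seed = 1))
  i1 <- kmeans_subsample(scores, 100, 1, seed = 1)
  expect_lte(length(i10), 1000L)
  expect_equal(length(i1), 100L)
  expect_identical(i1, kmeans_subsample(scores, 100, 1, seed = 1))
  # k = n: every point its own cluster, so the subsample is everything
  small <- scores[1:50, ]
  expect_identical(kmeans_subsample(small, 50, 1, seed = 2), 1:50)
  expect_error(kmeans_subsample(small, 51, 1, seed = 2), "exceeds")
})

test_that("raster-level correlation recovers exact linear relations", {
  elev <- grid_raster(matrix(as.numeric(1:12), 3, 4))
  e <- grid_raster(2 * elev$values + 1)
  out <- raster_correlation(e, elev)
  expect_equal(out$R, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  out2 <- raster_correlation(grid_raster(-elev$values), elev)
  expect_equal(out2$R, -1)
  expect_error(raster_correlation(e, grid_raster(matrix(5, 3, 4))),
               "zero variance")
  # permuted ECC: mean correlation near zero
  set.seed(8)
  rs <- vapply(1:100, function(i) {
    raster_correlation(grid_raster(matrix(sample(as.numeric(1:12)), 3, 4)),
                       elev)$R
  }, 1)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("Spearman permutation test matches brute-force ranks and is monotone-exact", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_perm(x, x^3 + 2, 1000, seed = 1)$r, 1)
  expect_equal(spearman_perm(x, -x, 1000, seed = 1)$r, -1)
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(c(8, 50, 300), 1)
    a <- sample(rnorm(n)); b <- sample(c(rnorm(n - 3), a[1:3]))  # some ties
    expect_equal(spearman_perm(a, b, 10, seed = 1)$r, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_perm(rep(1, 6), rnorm(6), 100, 1), "constant")
  expect_error(spearman_perm(1:4, 1:4, 100, 1), "at least 5")
})

test_that("ecomorph-removal sensitivity recomputes the reduced ECC pipeline", {
  st <- make_island(21, shape = c(25, 30))
  truth <- default_ecomorph_truth()
  maps <- sapply(c("twig", "grass-bush", "trunk", "crown-giant"), function(e)
    true_suitability(truth, e, st), simplify = FALSE)
  cfg <- run_config(seed = 3, kmeans_k = 50, n_permutations = 500)
  out <- ecc_sensitivity(maps, character(0), st, cfg)
  expect_identical(out$full, out$reduced)   # empty drop set changes nothing
  out2 <- ecc_sensitivity(maps, c("twig", "grass-bush"), st, cfg)
  expect_false(identical(out2$full$raster$R, out2$reduced$raster$R))
  expect_error(ecc_sensitivity(maps, "ghost", st, cfg), "absent")
  expect_error(ecc_sensitivity(maps, names(maps), st, cfg), "every ecomorph")
})

test_that("Kruskal-Wallis matches the textbook rank formula", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$H, oracle_kruskal_h(g), tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # identical value multisets: H = 0
  same <- list(a = c(2, 5, 9), b = c(9, 2, 5))
  expect_equal(kruskal_wallis(same)$H, 0, tolerance = 1e-12)
  # tie-corrected case against the brute-force oracle
  g2 <- list(a = c(1, 1, 2, 7), b = c(2, 2, 5), c = c(5, 5, 5, 8, 1))
  expect_equal(kruskal_wallis(g2)$H, oracle_kruskal_h(g2), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1, b = c(1, 2))), "at least two values")
  expect_error(kruskal_wallis(list(a = c(1, 2))), "two groups")
})

test_that("elevation dependence is classified by absolute correlation", {
  set.seed(9)
  elev <- rnorm(300)
  dep <- 3 * elev
  indep <- rnorm(300)
  bp <- list(scores = cbind(BioPC1 = dep, BioPC2 = indep))
  out <- classify_elevation_dependence(bp, elev, threshold = 0.5)
  expect_identical(out$dependent, "BioPC1")
  expect_identical(out$independent, "BioPC2")
  expect_false(out$all_dependent)
  out2 <- classify_elevation_dependence(
    list(scores = cbind(BioPC1 = dep, BioPC2 = -0.8 * elev)), elev, 0.5)
  expect_true(out2$all_dependent)
  expect_error(classify_elevation_dependence(bp, elev, threshold = 1.2),
               "threshold")
  # orthogonal-by-construction scores are independent at a low threshold
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    e <- rnorm(400); z <- rnorm(400)
    z_orth <- residuals(lm(z ~ e))
    abs(cor(z_orth, e)) < 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
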