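test_that("candidate sets follow the dependence partition", {
  b5 <- paste0("BioPC", 1:5)
  part <- list(dependent = "BioPC1", independent = b5[-1], all_dependent = FALSE)
  cands <- build_candidates(b5, part)
  expect_length(cands, 5)
  expect_identical(cands[["elev-dependent"]]$predictors, "BioPC1")
  expect_identical(cands[["elev-independent"]]$predictors, b5[-1])
  expect_identical(cands[["global"]]$predictors, c("elevation", b5))

  # everything elevation-dependent: 3 shared models + one per single BioPC
  all_dep <- list(dependent = b5, independent = character(0),
                  all_dependent = TRUE)
  cands2 <- build_candidates(b5, all_dep)
  expect_length(cands2, 8)
  expect_identical(cands2[["single-BioPC3"]]$predictors, "BioPC3")

  # one BioPC in standard mode degenerates; duplicates removed with warning
  one <- list(dependent = "BioPC1", independent = character(0),
              all_dependent = FALSE)
  w <- capture_warnings(cands3 <- build_candidates("BioPC1", one))
  expect_true(any(grepl("omitted", w)))
  expect_true(any(grepl("duplicate", w)))
  keys <- vapply(cands3, function(m) paste(sort(m$predictors), collapse = "|"), "")
  expect_false(any(duplicated(keys)))
})

test_that("linear fits reproduce the normal equations and handle degeneracy", {
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  X <- data.frame(x1 = 1:5, x2 = c(0.3, -1, 2, 0.5, 1.2))
  fit <- fit_linear(y, X, "hand")
  expect_equal(unname(fit$coefficients), unname(oracle_ols(y, X)),
               tolerance = 1e-9)
  expect_equal(fit$k, 4L)
  # Gaussian ML log-likelihood at the ML variance
  res <- y - cbind(1, as.matrix(X)) %*% oracle_ols(y, X)
  s2 <- sum(res^2) / length(y)
  expect_equal(fit$logLik, -length(y) / 2 * (log(2 * pi) + log(s2) + 1),
               tolerance = 1e-9)

  # intercept-only model estimates the mean
  f0 <- fit_linear(y, data.frame(row.names = seq_along(y)), "null")
  expect_equal(unname(f0$coefficients[1]), mean(y))
  # exact fit: variance floored rather than -Inf likelihood
  fe <- fit_linear(2 * (1:8) + 1, data.frame(x = 1:8), "exact")
  expect_true(is.finite(fe$logLik))
  expect_equal(fe$sigma2, 1e-12)
  # collinear design is rejected with the offending column named
  Xc <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(fit_linear(rnorm(6), Xc, "coll"), "collinear")
})

test_that("AICc ranking reproduces the closed-form deltas and weights", {
  m1 <- structure(list(name = "m1", predictors = "a", coefficients = c(1, 1),
                       se = c(0.1, 0.1), sigma2 = 1, logLik = -10, k = 3L,
                       n = 100L), class = "candidate_model")
  m2 <- m1; m2$name <- "m2"; m2$logLik <- -12
  tab <- aicc_rank(list(m1, m2), n = 100)
  o <- oracle_aicc(c(-10, -12), c(3, 3), 100)
  expect_equal(tab$table$delta, sort(o$delta))
  expect_equal(tab$table$weight, c(0.8808, 0.1192), tolerance = 1e-4)
  expect_equal(sum(tab$table$weight), 1, tolerance = 1e-9)
  expect_equal(min(tab$table$delta), 0)
  expect_false(tab$averaging_applied)     # gap of 4 exceeds the <3 rule
  expect_true(is.na(tab$single_best))     # 0.8808 falls short of 0.9
})

test_that("single-best and averaging flags follow the stated thresholds", {
  mk <- function(name, ll) structure(
    list(name = name, predictors = "a", coefficients = c("(Intercept)" = 1, a = 1),
         se = c("(Intercept)" = 0.1, a = 0.1), sigma2 = 1, logLik = ll,
         k = 3L, n = 50L), class = "candidate_model")
  # equal AICc: equal weights, both deltas zero
  t_eq <- aicc_rank(list(mk("a", -5), mk("b", -5)), n = 50)
  expect_equal(t_eq$table$weight, c(0.5, 0.5))
  expect_equal(t_eq$table$delta, c(0, 0))
  expect_true(t_eq$averaging_applied)
  expect_true(is.na(t_eq$single_best))
  # one model: weight 1 and single best
  t_one <- aicc_rank(list(mk("only", -5)), n = 50)
  expect_equal(t_one$table$weight, 1)
  expect_identical(t_one$single_best, "only")
  # a clearly dominant model suppresses averaging
  t_dom <- aicc_rank(list(mk("good", -5), mk("bad", -30)), n = 50)
  expect_identical(t_dom$single_best, "good")
  expect_false(t_dom$averaging_applied)
  expect_error(model_average(t_dom), "single most parsimonious")
  # models too rich for n are rejected
  rich <- mk("rich", -5); rich$k <- 49L
  expect_message(t_rej <- aicc_rank(list(mk("ok", -6), rich), n = 50), "rejecting")
  expect_equal(nrow(t_rej$table), 1L)
})

test_that("model averaging shrinks absent coefficients toward zero", {
  # craft two models with known weights 0.6 / 0.4
  ll2 <- -10 - (log(0.6 / 0.4))            # delta = 2*log(w1/w2)
  m1 <- structure(list(name = "with_v", predictors = c("v"),
                       coefficients = c("(Intercept)" = 0.5, v = 1.0),
                       se = c("(Intercept)" = 0.05, v = 0.2), sigma2 = 1,
                       logLik = -10, k = 3L, n = 200L),
                  class = "candidate_model")
  m2 <- structure(list(name = "without_v", predictors = "u",
                       coefficients = c("(Intercept)" = 0.1, u = 2.0),
                       se = c("(Intercept)" = 0.05, u = 0.3), sigma2 = 1,
                       logLik = ll2, k = 3L, n = 200L),
                  class = "candidate_model")
  tab <- aicc_rank(list(m1, m2), n = 200)
  expect_equal(tab$table$weight, c(0.6, 0.4), tolerance = 1e-9)
  avg <- model_average(tab)
  v_row <- avg[avg$variable == "v", ]
  expect_equal(v_row$estimate, 0.6 * 1.0, tolerance = 1e-9)
  expect_equal(v_row$importance, 0.6, tolerance = 1e-9)
  expect_equal(v_row$estimate_conditional, 1.0, tolerance = 1e-9)
  # unconditional SE per the multimodel variance formula
  expect_equal(v_row$se,
               sqrt(0.6 * (0.2^2 + (1 - 0.6)^2) + 0.4 * (0 + (0 - 0.6)^2)),
               tolerance = 1e-9)
  expect_equal(v_row$ci_upper - v_row$estimate, 1.96 * v_row$se,
               tolerance = 1e-9)
})

test_that("AICc is invariant to predictor order and penalizes pure noise", {
  set.seed(13)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 2 * x1 - x2 + rnorm(n, sd = 0.5)
  fa <- fit_linear(y, data.frame(x1 = x1, x2 = x2), "a")
  fb <- fit_linear(y, data.frame(x2 = x2, x1 = x1), "b")
  expect_equal(fa$logLik, fb$logLik, tolerance = 1e-9)
  # adding pure noise raises AICc in most replicates
  worse <- vapply(1:100, function(s) {
    set.seed(s + 500)
    noise <- rnorm(n)
    f3 <- fit_linear(y, data.frame(x1 = x1, x2 = x2, noise = noise), "n")
    aicc_3 <- -2 * f3$logLik + 2 * f3$k + 2 * f3$k * (f3$k + 1) / (n - f3$k - 1)
    aicc_2 <- -2 * fa$logLik + 2 * fa$k + 2 * fa$k * (fa$k + 1) / (n - fa$k - 1)
    aicc_3 > aicc_2
  }, TRUE)
  expect_gt(mean(worse), 0.5)
})
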