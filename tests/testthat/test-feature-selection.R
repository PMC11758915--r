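test_that("collinearity screen flags |r| > 0.70 and drops later columns", {
  set.seed(1)
  n <- 200
  a0 <- as.numeric(scale(rnorm(n)))
  # residualizing makes e exactly orthogonal to a0 in-sample, so the mixed
  # columns hit their target sample correlations exactly:
  # duplicate (r = 1), r = 0.69 (below threshold), r = -0.80 (flagged by |r|)
  e1 <- as.numeric(scale(resid(lm(rnorm(n) ~ a0))))
  e2 <- as.numeric(scale(resid(lm(rnorm(n) ~ a0))))
  mix <- function(rho, e) rho * a0 + sqrt(1 - rho^2) * e
  x <- cbind(a = a0, dup = a0, below = mix(0.69, e1), neg = -mix(0.80, e2))
  r <- cor(x)
  expect_equal(unname(r["a", "below"]), 0.69, tolerance = 1e-12)
  expect_equal(unname(r["a", "neg"]), -0.80, tolerance = 1e-12)
  res <- screen_collinearity(x)
  expect_true(any(res$flagged$col1 == "a" & res$flagged$col2 == "dup"))
  expect_true(any(res$flagged$col2 == "neg"))
  expect_false(any(res$flagged$col2 == "below"))
  expect_setequal(res$dropped, c("dup", "neg"))
  expect_setequal(res$retained, c("a", "below"))
})

test_that("duplicate and constant columns are handled deterministically", {
  x <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), dup = c(1, 1, 0, 0),
             const = c(2, 2, 2, 2))
  expect_warning(res <- screen_collinearity(x), "zero-variance")
  expect_equal(res$flagged$col2, "dup")
  expect_true("const" %in% res$dropped)
})

test_that("feature encoding builds one-hot, imputed, 0/1 design matrices", {
  sim <- simulate_cohort(simulation_config(n_pairs = 12, seed = 5))
  model <- list(response = "BLlongum", timepoint = "1m",
                features = c("maternal_abundance:BLlongum",
                             "strain_shared:BLlongum", "feeding_type",
                             "feeding_frequency", "bifido_diversity",
                             "abundance:B.breve", "presence:B.bifidum"))
  enc <- encode_features(sim$cohort, sim$metadata, model)
  expect_equal(nrow(enc$x), 12)
  ft_cols <- grep("^feeding_(breast|formula|mixed)", colnames(enc$x),
                  value = TRUE)
  expect_length(ft_cols, length(unique(sim$metadata$feeding_type)))
  expect_true(all(rowSums(enc$x[, ft_cols, drop = FALSE]) == 1))
  expect_true(all(enc$x[, "shared_BLlongum"] %in% 0:1))
  expect_true(all(enc$x[, "presence_B.bifidum"] %in% 0:1))
  infant <- sim$cohort[sim$cohort$timepoint == "1m", ]
  expect_equal(unname(enc$y), infant$BLlongum)
  expect_error(encode_features(sim$cohort, sim$metadata,
                               list(response = "BLlongum", timepoint = "1m",
                                    features = "abundance:nope")),
               "unknown taxon")
  expect_error(encode_features(sim$cohort, sim$metadata,
                               list(response = "BLlongum", timepoint = "1m",
                                    features = "made_up_feature")),
               "unknown feature")
})

test_that("missing numeric cells are mean-imputed and flagged", {
  sim <- simulate_cohort(simulation_config(n_pairs = 3, seed = 2))
  sim$metadata$feeding_frequency_per_day <- c(1, NA, 3)
  enc <- encode_features(sim$cohort, sim$metadata,
                         list(response = "BLlongum", timepoint = "1m",
                              features = "feeding_frequency"))
  expect_equal(unname(enc$x[2, "feeding_frequency"]), 2)
  expect_identical(unname(which(enc$imputed[, "feeding_frequency"])), 2L)
})

test_that("planted support is recovered with correct signs", {
  recovered <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 200
    x <- matrix(rnorm(n * 9), n, 9,
                dimnames = list(NULL, paste0("x", 1:9)))
    y <- 3 * x[, 1] - 2 * x[, 2] + rnorm(n, 0, 0.1)
    fit <- fit_lasso_cv(x, y, scheme = "repeated_kfold", seed = s)
    sel <- select_features(fit)
    all(c("x1", "x2") %in% sel$feature) &&
      sel$beta[sel$feature == "x1"] > 0 && sel$beta[sel$feature == "x2"] < 0
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  # oracle cross-check: OLS on the true support gives the same signs and
  # near-identical magnitudes at this noise level
  set.seed(1001)
  n <- 200
  x <- matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("x", 1:9)))
  y <- 3 * x[, 1] - 2 * x[, 2] + rnorm(n, 0, 0.1)
  ols <- coef(lm(y ~ x[, 1] + x[, 2]))
  expect_equal(unname(ols[2]), 3, tolerance = 0.05)
  expect_equal(unname(ols[3]), -2, tolerance = 0.05)
})

test_that("the largest penalty shrinks every coefficient to zero", {
  set.seed(3)
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- x[, 1] + rnorm(50)
  fit <- fit_lasso_cv(x, y, seed = 1)
  expect_equal(fit$nzero[1], 0L)
  g <- glmnet::glmnet(x, y)
  expect_equal(g$lambda[1], fit$lambda[1])
  expect_true(all(abs(as.matrix(g$beta)[, 1]) == 0))
})

test_that("sparsity is monotone along the penalty path", {
  set.seed(4)
  x <- matrix(rnorm(100 * 8), 100, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- 2 * x[, 1] - x[, 3] + rnorm(100, 0, 0.5)
  fit <- fit_lasso_cv(x, y, seed = 2)
  expect_true(all(diff(fit$nzero) >= 0))   # lambda decreases along the grid
  expect_equal(fit$lambda_min, fit$lambda[which.min(fit$cvm)])
})

test_that("a constant response returns an intercept-only model", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_lasso_cv(x, rep(7, 20), seed = 1)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, 7)
  expect_equal(nrow(select_features(fit)), 0L)
})

test_that("LOOCV and repeated k-fold runs are deterministic and comparable", {
  set.seed(8)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 2 * x[, 1] + rnorm(n, 0, 0.3)
  loo1 <- fit_lasso_cv(x, y, scheme = "loocv", seed = 5)
  loo2 <- fit_lasso_cv(x, y, scheme = "loocv", seed = 99)
  expect_equal(loo1$cvm, loo2$cvm)   # LOOCV has no fold randomness
  kf <- fit_lasso_cv(x, y, scheme = "repeated_kfold", seed = 5)
  step <- abs(which(kf$lambda == kf$lambda_min) -
                which(loo1$lambda == loo1$lambda_min))
  expect_lte(step, 10)               # selected penalties agree closely
  expect_identical(fit_lasso_cv(x, y, seed = 5)$lambda_min, kf$lambda_min)
  expect_error(fit_lasso_cv(x[1:5, ], y[1:5], nfolds = 10), "n < nfolds")
})

test_that("important features are reported in |beta| order with signs", {
  fake <- structure(list(beta = c(x1 = 0, x2 = 1.2, x3 = -0.4, x4 = 0),
                         lambda_min = 0.1, scheme = "loocv"),
                    class = "lasso_result")
  rep <- select_features(fake)
  expect_equal(rep$feature, c("x2", "x3"))
  expect_equal(rep$beta, c(1.2, -0.4))
  expect_equal(rep$sign, c("positive", "negative"))
  shuffled <- structure(list(beta = c(a = 0.3, b = -2, c = 1, d = -0.1)),
                        class = "lasso_result")
  expect_equal(select_features(shuffled)$feature, c("b", "c", "a", "d"))
})
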