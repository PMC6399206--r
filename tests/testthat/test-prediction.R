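# Age predictors, cross-validation, external validation and the
# accompanying statistics.

test_that("pearson_r and mae follow their definitions", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2), c(2, 4)), 1.5)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("OLS recovers a perfect single-feature predictor", {
  ages <- runif(30, 10, 80)
  m <- train_model(model_spec("ols"), matrix(ages, ncol = 1), ages)
  expect_equal(unname(m$coef), c(0, 1), tolerance = 1e-8)
  expect_lt(mae(ages, predict(m, matrix(ages, ncol = 1))), 1e-8)
  expect_error(train_model(model_spec("ols"), matrix(rnorm(20 * 30), 20, 30),
                           rnorm(20)), "fewer features")
})

test_that("lasso shrinks to the mean above the zero-solution threshold", {
  set.seed(40)
  n <- 60
  X <- scale(matrix(rnorm(n * 5), n, 5))
  ages <- runif(n, 10, 80)
  lam_max <- max(abs(crossprod(X, ages - mean(ages)))) / n
  spec <- model_spec("lasso", lasso_lambda_grid = lam_max * 1.05)
  m <- suppressWarnings(train_model(spec, X, ages))
  cf <- as.numeric(coef(m$fit, s = m$lambda))
  expect_equal(cf[-1], rep(0, 5))
  expect_equal(predict(m, X), rep(mean(ages), n), tolerance = 1e-6)
})

test_that("lasso lambda selection is seeded and flags grid boundaries", {
  set.seed(41)
  n <- 80
  X <- matrix(rnorm(n * 10), n, 10)
  ages <- 40 + X[, 1] * 10 + rnorm(n)
  spec <- model_spec("lasso", lasso_lambda_grid = 10^seq(1, -3, length.out = 30),
                     seed = 5)
  m1 <- train_model(spec, X, ages)
  m2 <- train_model(spec, X, ages)
  expect_identical(m1$lambda, m2$lambda)
  spec_edge <- model_spec("lasso", lasso_lambda_grid = c(100, 200), seed = 5)
  expect_warning(train_model(spec_edge, X, ages), "boundary")
})

test_that("linear SVR fits noiseless linear data within epsilon", {
  set.seed(42)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  ages <- 40 + X %*% c(5, -3, 2)
  spec <- model_spec("svr", svr_kernels = "linear", svr_C_grid = 100,
                     svr_epsilon = 0.1)
  m <- train_model(spec, X, as.numeric(ages))
  pred <- predict(m, X)
  # errors bounded by a small multiple of the insensitive-loss tube
  expect_lt(mae(as.numeric(ages), pred), 0.5)
})

test_that("K-fold validation partitions subjects exactly once", {
  ch <- small_cohort()
  X <- t(small_edge_matrix()$values)
  ages <- ch$metadata$age
  res <- kfold_validate(feature_builder("edge", l = 3), X, ages,
                        model_spec("ols"), K = 5, seed = 3)
  folds <- res$predictions$fold
  expect_equal(sort(unique(folds)), 1:5)
  expect_lte(diff(range(table(folds))), 1)
  expect_equal(nrow(res$predictions), length(ages))
  # identical seed reproduces the folds and metrics
  res2 <- kfold_validate(feature_builder("edge", l = 3), X, ages,
                         model_spec("ols"), K = 5, seed = 3)
  expect_identical(res$predictions, res2$predictions)
  expect_error(kfold_validate(feature_builder("edge", l = 3), X, ages,
                              model_spec("ols"), K = 20, seed = 1),
               "K too large")
})

test_that("a perfect feature yields r = 1 and zero error in CV", {
  ages <- runif(45, 6, 85)
  perfect <- feature_builder("temporal")
  X <- matrix(ages, ncol = 1, dimnames = list(NULL, "node1"))
  res <- kfold_validate(perfect, X, ages, model_spec("ols"), K = 5, seed = 2)
  expect_equal(res$pearson_r, 1, tolerance = 1e-8)
  expect_lt(res$mae_years, 1e-8)
})

test_that("external validation on an identical cohort matches training", {
  ch <- small_cohort()
  X <- t(small_edge_matrix()$values)
  ages <- ch$metadata$age
  ev <- external_validate(feature_builder("edge", l = 3), X, ages, X, ages,
                          model_spec("ols"))
  expect_equal(ev$external$pearson_r, ev$internal_train_r, tolerance = 1e-10)
  expect_equal(ev$external$mae_years, ev$internal_train_mae,
               tolerance = 1e-10)
  expect_error(external_validate(feature_builder("edge", l = 3), X, ages,
                                 X[, 1:10], ages, model_spec("ols")),
               "mismatch")
})

test_that("external cohorts without age signal predict near chance", {
  cfg <- generator_config(n_subjects = 40, n_nodes = 16, n_networks = 8,
                          n_volumes = 150,
                          age_slope_map = data.frame(i = integer(),
                                                     j = integer(),
                                                     slope = numeric()),
                          quadratic_edge_set = data.frame(i = integer(),
                                                          j = integer(),
                                                          curv = numeric()),
                          seed = 55)
  ch_null <- generate_cohort(cfg)
  # train on a same-sized cohort that does carry planted age signal
  cfg_tr <- generator_config(n_subjects = 60, n_nodes = 16, n_networks = 8,
                             n_volumes = 150, seed = 56)
  ch_sig <- generate_cohort(cfg_tr)
  X_tr <- t(build_cohort_matrix(ch_sig)$values)
  X_nu <- t(build_cohort_matrix(ch_null)$values)
  ev <- external_validate(feature_builder("edge", l = 3), X_tr,
                          ch_sig$metadata$age, X_nu, ch_null$metadata$age,
                          model_spec("ols"))
  expect_lt(abs(ev$external$pearson_r), 0.45)
})

test_that("Steiger's z matches a from-formula oracle", {
  steiger_oracle <- function(r1, r2, r12, n) {
    # Steiger (1980) modification of the Dunn-Clark z
    rm2 <- (r1^2 + r2^2) / 2
    f <- min((1 - r12) / (2 * (1 - rm2)), 1)
    h <- (1 - f * rm2) / (1 - rm2)
    (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  }
  res <- steiger_test(0.91, 0.724, 0.7, 173)
  expect_equal(res$z, steiger_oracle(0.91, 0.724, 0.7, 173),
               tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # equal correlations: z = 0; swapping arguments flips the sign
  expect_equal(steiger_test(0.5, 0.5, 0.3, 100)$z, 0)
  a <- steiger_test(0.6, 0.4, 0.5, 80)
  b <- steiger_test(0.4, 0.6, 0.5, 80)
  expect_equal(a$z, -b$z)
  expect_error(steiger_test(1, 0.5, 0.2, 50), "correlations")
  expect_error(steiger_test(0.5, 0.4, 0.2, 3), "n must exceed")
})

test_that("the group z-test is calibrated and detects group differences", {
  set.seed(60)
  make_result <- function(err, ages) {
    structure(list(predictions = data.frame(subject_id = seq_along(ages),
                                            age = ages,
                                            predicted = ages + err,
                                            fold = 1)),
              class = "prediction_result")
  }
  # identical error distributions: z near 0 over repeated draws
  zs <- replicate(200, {
    ages <- runif(60, 6, 85)
    groups <- rbinom(60, 1, 0.5)
    if (length(unique(groups)) < 2) return(NA)
    group_error_ztest(make_result(rnorm(60, 0, 5), ages), groups)$z
  })
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.2)
  # planted group difference is detected
  ages <- runif(200, 6, 85)
  groups <- rep(0:1, each = 100)
  err <- rnorm(200, 0, 2) + 6 * groups
  res <- group_error_ztest(make_result(err, ages), groups)
  expect_gt(res$z, 3)
  expect_error(group_error_ztest(make_result(rnorm(10), runif(10, 6, 85)),
                                 rep(1, 10)), "non-empty")
})

test_that("error-age correlation reproduces the closed-form t", {
  # t = r sqrt((n-2)/(1-r^2)): r = 0.469, n = 173 gives t = 6.94
  r <- 0.469; n <- 173
  expect_equal(r * sqrt((n - 2) / (1 - r^2)), 6.944, tolerance = 1e-3)
  set.seed(61)
  ages <- runif(100, 6, 85)
  err <- (ages - 6) / 10  # errors proportional to age offset
  res <- error_age_correlation(structure(list(predictions = data.frame(
    subject_id = 1:100, age = ages, predicted = ages + err, fold = 1)),
    class = "prediction_result"))
  expect_equal(res$r, 1, tolerance = 1e-10)
})

test_that("paper-mode leakage is optimistic relative to strict mode", {
  rs <- sapply(1:6, function(sd) {
    cfg <- generator_config(n_subjects = 50, n_nodes = 16, n_networks = 8,
                            n_volumes = 120, seed = 300 + sd)
    ch <- generate_cohort(cfg)
    X <- t(build_cohort_matrix(ch)$values)
    ages <- ch$metadata$age
    b <- feature_builder("edge", l = 5)
    strict <- kfold_validate(b, X, ages, model_spec("ols"), K = 5,
                             seed = sd, leakage_mode = "strict")
    paper <- kfold_validate(b, X, ages, model_spec("ols"), K = 5,
                            seed = sd, leakage_mode = "paper")
    c(strict = strict$pearson_r, paper = paper$pearson_r)
  })
  expect_gt(mean(rs["paper", ] - rs["strict", ]), 0)
})
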