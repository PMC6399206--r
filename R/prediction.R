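# Age prediction: OLS, lasso and support-vector regressors over any
# feature block, with inner-CV hyperparameter selection, K-fold internal
# validation, external validation, and the accompanying statistics
# (Pearson r, MAE, Steiger's z, group z-test on errors, error-age
# correlation).

#' Prediction model specification
#'
#' @param family `"ols"`, `"lasso"` or `"svr"`.
#' @param lasso_lambda_grid Lambda grid for the lasso (log-spaced
#'   default).
#' @param svr_kernels Subset of `c("linear", "radial", "polynomial")`.
#' @param svr_C_grid Cost grid for SVR.
#' @param svr_epsilon Epsilon of the insensitive loss.
#' @param rbf_gamma_grid Gamma grid for the radial kernel (`NULL`: the
#'   e1071 default 1/d).
#' @param inner_folds Folds for inner-CV hyperparameter selection.
#' @param seed Seed for the inner-CV fold assignment.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("ols", "lasso", "svr"),
                       lasso_lambda_grid = 10^seq(2, -4, length.out = 60),
                       svr_kernels = c("linear", "radial"),
                       svr_C_grid = c(0.1, 1, 10),
                       svr_epsilon = 0.1,
                       rbf_gamma_grid = NULL,
                       inner_folds = 5L,
                       seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family,
                 lasso_lambda_grid = sort(lasso_lambda_grid,
                                          decreasing = TRUE),
                 svr_kernels = svr_kernels, svr_C_grid = svr_C_grid,
                 svr_epsilon = svr_epsilon, rbf_gamma_grid = rbf_gamma_grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Pearson correlation between chronological and predicted age
#' @param x,y Numeric vectors of equal length (>= 3 for `pearson_r`).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input to pearson_r")
  stats::cor(x, y)
}

#' Mean absolute error in years
#' @rdname pearson_r
#' @export
mae <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("need equal-length non-empty vectors")
  mean(abs(x - y))
}

# near-equal-size fold labels from a seeded shuffle
make_folds <- function(n, K, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sample(rep_len(seq_len(K), n))
}

#' Train an age-prediction model
#'
#' OLS fits by least squares (and refuses d >= n, where a reducing
#' feature method is required first). The lasso's lambda and the SVR's
#' kernel/cost/gamma are chosen by inner-CV mean absolute error on the
#' training data only; fitting is deterministic given `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @param features A `feature_block` or plain subjects x d matrix.
#' @param ages Numeric vector of training ages.
#' @return A `fitted_model` with a `predict` method.
#' @export
train_model <- function(spec, features, ages) {
  X <- if (inherits(features, "feature_block")) features$matrix
       else as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (any(!is.finite(X))) stop("non-finite features")
  fm <- switch(spec$family,
    ols = {
      if (d >= n)
        stop("OLS requires fewer features than subjects (d = ", d,
             ", n = ", n, "); use a reducing feature method first")
      fit <- stats::lm.fit(cbind(1, X), ages)
      list(coef = fit$coefficients)
    },
    lasso = {
      grid <- spec$lasso_lambda_grid
      lam <- if (length(grid) == 1L) {
        grid  # nothing to select; skip the inner CV
      } else {
        foldid <- make_folds(n, min(spec$inner_folds, n %/% 3L), spec$seed)
        cvfit <- glmnet::cv.glmnet(X, ages, lambda = grid,
                                   type.measure = "mae", foldid = foldid)
        cvfit$lambda.min
      }
      boundary <- lam %in% range(grid)
      if (boundary && length(grid) > 1L)
        warning("selected lasso lambda lies on the grid boundary")
      list(fit = glmnet::glmnet(X, ages, lambda = grid), lambda = lam,
           boundary = boundary)
    },
    svr = {
      sel <- select_svr(spec, X, ages)
      list(fit = sel$fit, kernel = sel$kernel, C = sel$C, gamma = sel$gamma)
    })
  structure(c(fm, list(family = spec$family, d = d, spec = spec)),
            class = "fitted_model")
}

# inner-CV grid search for SVR hyperparameters by MAE
select_svr <- function(spec, X, ages) {
  n <- nrow(X)
  foldid <- make_folds(n, min(spec$inner_folds, n %/% 3L), spec$seed)
  gammas <- if (is.null(spec$rbf_gamma_grid)) 1 / ncol(X)
            else spec$rbf_gamma_grid
  grid <- do.call(rbind, lapply(spec$svr_kernels, function(k) {
    g <- if (k == "radial") gammas else gammas[1L]
    expand.grid(kernel = k, C = spec$svr_C_grid, gamma = g,
                stringsAsFactors = FALSE)
  }))
  cvm <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(sort(unique(foldid)), function(f) {
      tr <- foldid != f
      fit <- e1071::svm(X[tr, , drop = FALSE], ages[tr], type = "eps-regression",
                        kernel = grid$kernel[i], cost = grid$C[i],
                        gamma = grid$gamma[i], epsilon = spec$svr_epsilon,
                        degree = 3L)
      mae(ages[!tr], stats::predict(fit, X[!tr, , drop = FALSE]))
    }, 0)
    mean(errs)
  }, 0)
  best <- which.min(cvm)
  fit <- e1071::svm(X, ages, type = "eps-regression",
                    kernel = grid$kernel[best], cost = grid$C[best],
                    gamma = grid$gamma[best], epsilon = spec$svr_epsilon,
                    degree = 3L)
  list(fit = fit, kernel = grid$kernel[best], C = grid$C[best],
       gamma = grid$gamma[best])
}

#' Predict ages from a fitted model
#' @param object A `fitted_model`.
#' @param newdata `feature_block` or subjects x d matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_block")) newdata$matrix
       else as.matrix(newdata)
  switch(object$family,
    ols = as.numeric(cbind(1, X) %*% object$coef),
    lasso = as.numeric(stats::predict(object$fit, newx = X,
                                      s = object$lambda)),
    svr = as.numeric(stats::predict(object$fit, X)))
}

#' Linear coefficients of a fitted model in feature space
#'
#' For OLS and lasso the regression coefficients; for linear-kernel SVR
#' the primal weight vector. Nonlinear kernels have no feature-space
#' coefficient vector and raise an error.
#'
#' @param model A `fitted_model`.
#' @return Numeric vector of length d (no intercept).
#' @export
model_coefficients <- function(model) {
  switch(model$family,
    ols = model$coef[-1L],
    lasso = as.numeric(stats::coef(model$fit, s = model$lambda))[-1L],
    svr = {
      if (model$kernel != "linear")
        stop("edge significance requires a linear-kernel SVR; refit with ",
             "svr_kernels = \"linear\"")
      # e1071 scales x and y internally; recover primal weights on the
      # raw scale
      w <- as.numeric(crossprod(model$fit$coefs, model$fit$SV))
      if (!is.null(model$fit$x.scale))
        w <- w / model$fit$x.scale[["scaled:scale"]]
      if (!is.null(model$fit$y.scale))
        w <- w * model$fit$y.scale[["scaled:scale"]]
      w
    })
}

#' K-fold cross-validated age prediction
#'
#' Shuffles subjects into K near-equal folds with the given seed. In
#' `leakage_mode = "strict"` (default) the feature builder is refit on
#' each fold's training subjects only; `"paper"` fits it once on the
#' whole cohort before cross-validation, reproducing the optimistic
#' whole-cohort protocol. Metrics are reported pooled over all held-out
#' predictions (primary) and as per-fold averages.
#'
#' @param builder A [feature_builder()].
#' @param X Subjects x inputs matrix for the builder (edges or fALFF).
#' @param ages Numeric vector of ages.
#' @param spec A [model_spec()].
#' @param K Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param leakage_mode `"strict"` or `"paper"`.
#' @return A list of class `prediction_result` with `predictions`
#'   (subject, age, predicted, fold), `pearson_r`, `mae_years`,
#'   `per_fold` (fold, r, mae) and `fold_mean_r`, `fold_mean_mae`.
#' @export
kfold_validate <- function(builder, X, ages, spec, K = 10L, seed = 1L,
                           leakage_mode = c("strict", "paper")) {
  leakage_mode <- match.arg(leakage_mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n / 3) stop("K too large for ", n, " subjects")
  folds <- make_folds(n, K, seed)
  if (min(table(folds)) < 2L) stop("a fold has fewer than 2 subjects")
  shared <- if (leakage_mode == "paper") builder$fit(X, ages) else NULL
  pred <- numeric(n)
  for (f in seq_len(K)) {
    tr <- folds != f
    fitted_ftr <- if (leakage_mode == "paper") shared
                  else builder$fit(X[tr, , drop = FALSE], ages[tr])
    ftr_tr <- builder$transform(fitted_ftr, X[tr, , drop = FALSE])
    model <- train_model(spec, ftr_tr, ages[tr])
    ftr_te <- builder$transform(fitted_ftr, X[!tr, , drop = FALSE])
    pred[!tr] <- predict(model, ftr_te)
  }
  per_fold <- do.call(rbind, lapply(seq_len(K), function(f) {
    idx <- folds == f
    data.frame(fold = f,
               r = if (sum(idx) >= 3L && stats::sd(pred[idx]) > 0)
                 stats::cor(ages[idx], pred[idx]) else NA_real_,
               mae = mae(ages[idx], pred[idx]))
  }))
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(n))
  structure(list(predictions = data.frame(subject_id = ids, age = ages,
                                          predicted = pred, fold = folds),
                 pearson_r = pearson_r(ages, pred),
                 mae_years = mae(ages, pred),
                 per_fold = per_fold,
                 fold_mean_r = mean(per_fold$r, na.rm = TRUE),
                 fold_mean_mae = mean(per_fold$mae),
                 family = spec$family, method = builder$method,
                 leakage_mode = leakage_mode, K = K, seed = seed),
            class = "prediction_result")
}

#' Train on the whole internal cohort and validate externally
#'
#' @param builder A [feature_builder()].
#' @param X_int,ages_int Internal (training) inputs and ages.
#' @param X_ext,ages_ext External inputs and ages.
#' @param spec A [model_spec()].
#' @return List with the internal `fitted_features` and `model`, the
#'   external `prediction_result`, and internal training metrics.
#' @export
external_validate <- function(builder, X_int, ages_int, X_ext, ages_ext,
                              spec) {
  X_int <- as.matrix(X_int); X_ext <- as.matrix(X_ext)
  if (ncol(X_ext) != ncol(X_int)) stop("internal/external input mismatch")
  fitted_ftr <- builder$fit(X_int, ages_int)
  model <- train_model(spec, builder$transform(fitted_ftr, X_int), ages_int)
  pred_ext <- predict(model, builder$transform(fitted_ftr, X_ext))
  pred_int <- predict(model, builder$transform(fitted_ftr, X_int))
  res <- structure(list(predictions = data.frame(
    subject_id = seq_along(ages_ext), age = ages_ext,
    predicted = pred_ext, fold = 0L),
    pearson_r = pearson_r(ages_ext, pred_ext),
    mae_years = mae(ages_ext, pred_ext),
    family = spec$family, method = builder$method),
    class = "prediction_result")
  list(external = res, model = model, fitted_features = fitted_ftr,
       internal_train_r = pearson_r(ages_int, pred_int),
       internal_train_mae = mae(ages_int, pred_int))
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Compares r1 = cor(age, prediction 1) and r2 = cor(age, prediction 2)
#' given r12 = cor(prediction 1, prediction 2), over the same n
#' subjects (Steiger's modification of the Dunn-Clark z).
#'
#' @param r1,r2 Correlations with the shared variable.
#' @param r12 Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return List with `z` and two-sided `p`.
#' @export
steiger_test <- function(r1, r2, r12, n) {
  if (n <= 3L) stop("n must exceed 3")
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("correlations must lie in (-1, 1)")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rm2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r12) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample z-test on absolute prediction errors between groups
#'
#' Pooled-variance z on per-subject absolute errors (e.g. to test for
#' sex differences in prediction accuracy).
#'
#' @param result A `prediction_result`.
#' @param groups 0/1 vector aligned with the subjects.
#' @return List with `z`, two-sided `p` and the group means.
#' @export
group_error_ztest <- function(result, groups) {
  err <- abs(result$predictions$age - result$predictions$predicted)
  if (length(groups) != length(err)) stop("groups length mismatch")
  g0 <- err[groups == 0]; g1 <- err[groups == 1]
  if (length(g0) == 0L || length(g1) == 0L) stop("both groups must be non-empty")
  n0 <- length(g0); n1 <- length(g1)
  sp2 <- ((n0 - 1) * stats::var(g0) + (n1 - 1) * stats::var(g1)) /
    (n0 + n1 - 2)
  z <- (mean(g1) - mean(g0)) / sqrt(sp2 * (1 / n0 + 1 / n1))
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       mean_abs_error = c(group0 = mean(g0), group1 = mean(g1)))
}

#' Correlation of absolute prediction error with age
#'
#' @param result A `prediction_result`.
#' @return List with `r`, `t` (= r sqrt((n-2)/(1-r^2))) and two-sided `p`.
#' @export
error_age_correlation <- function(result) {
  age <- result$predictions$age
  err <- abs(age - result$predictions$predicted)
  n <- length(age)
  r <- stats::cor(err, age)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}
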