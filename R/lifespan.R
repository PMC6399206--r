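# Mass-univariate lifespan models: linear and quadratic age regressions
# with sex, head-motion (FD) and brain-volume (TIV) covariates at the
# edge, network-summary and node-fALFF levels, with Benjamini-Hochberg
# FDR control and trajectory classification.

#' Per-subject network connectivity summaries
#'
#' Within(X) is the mean Fisher-z over unordered node pairs inside
#' network X; Between(X, Y) the mean over pairs with one node in each;
#' WithinBetween(X) = Within(X) minus the mean of Between(X, Y) over all
#' other networks Y.
#'
#' @param Z Symmetric connectivity matrix (diagonal ignored).
#' @param partition Data frame with columns `node` and `network`.
#' @return List with `within` (named vector; `NA` for singleton
#'   networks), `between` (named vector, names `"X|Y"`), and
#'   `within_between` (named vector).
#' @export
network_summaries <- function(Z, partition) {
  sm <- network_summaries_matrix(Z, partition)
  within <- stats::setNames(sm$within$value, sm$within$network)
  between <- stats::setNames(sm$between$value,
                             paste(sm$between$network_a,
                                   sm$between$network_b, sep = "|"))
  nets <- names(within)
  wb <- vapply(nets, function(x) {
    others <- between[grepl(paste0("^", x, "\\|"), names(between)) |
                        grepl(paste0("\\|", x, "$"), names(between))]
    within[[x]] - mean(others)
  }, 0)
  list(within = within, between = between, within_between = wb)
}

#' Network summaries for every subject in a cohort edge matrix
#'
#' @param D A `cohort_edge_matrix`.
#' @param partition Partition table.
#' @return Matrix, summaries x subjects, rows named
#'   `Within(X)`, `Between(X,Y)`, `WithinBetween(X)`.
#' @export
cohort_network_summaries <- function(D, partition) {
  vals <- sapply(seq_len(ncol(D$values)), function(k) {
    Z <- devectorize_matrix(D$values[, k], diag = 0)
    s <- network_summaries(Z, partition)
    c(stats::setNames(s$within, sprintf("Within(%s)", names(s$within))),
      stats::setNames(s$between, sprintf("Between(%s)",
                                         sub("\\|", ",", names(s$between)))),
      stats::setNames(s$within_between,
                      sprintf("WithinBetween(%s)", names(s$within_between))))
  })
  colnames(vals) <- D$subject_ids
  vals
}

# design matrices for the two lifespan models; age centered at its
# cohort mean before squaring
lifespan_design <- function(meta, model) {
  age_c <- meta$age - mean(meta$age)
  X <- switch(model,
    linear = cbind(intercept = 1, age = meta$age, sex = meta$sex,
                   fd = meta$fd, tiv = meta$tiv),
    quadratic = cbind(intercept = 1, age = meta$age, age2 = age_c^2,
                      sex = meta$sex, fd = meta$fd, tiv = meta$tiv),
    stop("unknown model ", model))
  X
}

#' Fit a lifespan age model to one outcome
#'
#' Ordinary least squares for
#' `y = b0 + b1 age + b2 sex + b3 FD + b4 TIV + e` (linear) or
#' `y = b0 + b1 age + b2 age_c^2 + b3 sex + b4 FD + b5 TIV + e`
#' (quadratic; age centered at the cohort mean before squaring). Returns
#' two-sided t-test p-values for every coefficient and the overall-fit
#' F-test p.
#'
#' @param y Numeric outcome, one value per subject.
#' @param meta Data frame with columns `age`, `sex`, `fd`, `tiv`.
#' @param model `"linear"` or `"quadratic"`.
#' @return One-row data frame: coefficients, t-statistics and p-values
#'   per term, `age_term` (the tested age coefficient name), `age_p`,
#'   `model_p`, `sigma`, `age_se`.
#' @export
fit_age_model <- function(y, meta, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  X <- lifespan_design(meta, model)
  res <- fit_age_models_matrix(matrix(y, ncol = 1L), X, model)
  res
}

# shared-design OLS over many outcomes at once (columns of Y); returns a
# data frame with one row per outcome
fit_age_models_matrix <- function(Y, X, model) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2L) stop("too few subjects for the ", model, " model")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)                       # k x q
  fitted <- X %*% B
  resid <- Y - fitted
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtXinv), sigma2))    # k x q
  tstat <- B / se
  pvals <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  rss <- colSums(resid^2)
  fstat <- ((tss - rss) / (k - 1L)) / (rss / df)
  model_p <- stats::pf(fstat, k - 1L, df, lower.tail = FALSE)
  age_term <- if (model == "linear") "age" else "age2"
  ai <- match(age_term, colnames(X))
  out <- data.frame(model = model,
                    t(B), check.names = FALSE)
  names(out)[-1L] <- paste0("beta_", colnames(X))
  tt <- t(tstat); colnames(tt) <- paste0("t_", colnames(X))
  pp <- t(pvals); colnames(pp) <- paste0("p_", colnames(X))
  out <- cbind(out, tt, pp)
  out$age_term <- age_term
  out$age_beta <- B[ai, ]
  out$age_se <- se[ai, ]
  out$age_t <- tstat[ai, ]
  out$age_p <- pvals[ai, ]
  out$model_p <- model_p
  out$sigma <- sqrt(sigma2)
  rownames(out) <- colnames(Y)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the rejection
#' set at level `q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `p_fdr` and logical `reject`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0L) return(list(p_fdr = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p_fdr <- stats::p.adjust(p, method = "BH")
  list(p_fdr = p_fdr, reject = !is.na(p_fdr) & p_fdr <= q)
}

#' Fit linear and quadratic lifespan models to a table of outcomes
#'
#' Runs both models on every column of `Y`, FDR-corrects the age-term
#' and overall-model p-values within each (level, model) family, and
#' classifies each unit's trajectory.
#'
#' @param Y Numeric matrix, subjects x units (edges, network summaries,
#'   or nodes), with unit names as column names.
#' @param meta Metadata data frame (`age`, `sex`, `fd`, `tiv`).
#' @param q FDR level used for the significance gate.
#' @param precedence `"quadratic"` (default) or `"linear"`: which class
#'   wins when both age terms survive FDR.
#' @return List of class `age_model_table` with `linear` and `quadratic`
#'   model data frames (including `age_p_fdr`, `model_p_fdr`) and
#'   `class` (named character vector: linear-increase, linear-decrease,
#'   U, inverted-U, none).
#' @export
fit_lifespan_models <- function(Y, meta, q = 0.05,
                                precedence = c("quadratic", "linear")) {
  precedence <- match.arg(precedence)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("unit", seq_len(ncol(Y)))
  lin <- fit_age_models_matrix(Y, lifespan_design(meta, "linear"), "linear")
  qd <- fit_age_models_matrix(Y, lifespan_design(meta, "quadratic"),
                              "quadratic")
  lin$age_p_fdr <- fdr_adjust(lin$age_p, q)$p_fdr
  lin$model_p_fdr <- fdr_adjust(lin$model_p, q)$p_fdr
  qd$age_p_fdr <- fdr_adjust(qd$age_p, q)$p_fdr
  qd$model_p_fdr <- fdr_adjust(qd$model_p, q)$p_fdr
  cls <- classify_trajectories(lin, qd, q, precedence)
  structure(list(linear = lin, quadratic = qd, class = cls, q = q),
            class = "age_model_table")
}

#' Classify lifespan trajectories from fitted linear and quadratic models
#'
#' A unit is classified from the sign of its significant age term:
#' positive/negative linear slopes give linear-increase/linear-decrease;
#' positive/negative quadratic terms give U/inverted-U. Significance
#' requires both the age-term p and the overall model p to survive FDR
#' at level `q`. When both models' age terms survive, `precedence`
#' decides (quadratic by default).
#'
#' @param linear_table,quadratic_table Data frames from the fitter, with
#'   `age_beta`, `age_p_fdr`, `model_p_fdr`, sharing row names.
#' @param q FDR level.
#' @param precedence `"quadratic"` or `"linear"`.
#' @return Named character vector of classes.
#' @export
classify_trajectories <- function(linear_table, quadratic_table, q = 0.05,
                                  precedence = c("quadratic", "linear")) {
  precedence <- match.arg(precedence)
  if (!identical(rownames(linear_table), rownames(quadratic_table)))
    stop("linear and quadratic tables must cover identical units")
  if (!("age_p_fdr" %in% names(linear_table))) {
    linear_table$age_p_fdr <- fdr_adjust(linear_table$age_p, q)$p_fdr
    linear_table$model_p_fdr <- fdr_adjust(linear_table$model_p, q)$p_fdr
  }
  if (!("age_p_fdr" %in% names(quadratic_table))) {
    quadratic_table$age_p_fdr <- fdr_adjust(quadratic_table$age_p, q)$p_fdr
    quadratic_table$model_p_fdr <- fdr_adjust(quadratic_table$model_p, q)$p_fdr
  }
  lin_sig <- linear_table$age_p_fdr <= q & linear_table$model_p_fdr <= q
  qd_sig <- quadratic_table$age_p_fdr <= q & quadratic_table$model_p_fdr <= q
  cls <- rep("none", nrow(linear_table))
  lin_cls <- ifelse(linear_table$age_beta > 0, "linear-increase",
                    "linear-decrease")
  qd_cls <- ifelse(quadratic_table$age_beta > 0, "U", "inverted-U")
  if (precedence == "quadratic") {
    cls[lin_sig] <- lin_cls[lin_sig]
    cls[qd_sig] <- qd_cls[qd_sig]
  } else {
    cls[qd_sig] <- qd_cls[qd_sig]
    cls[lin_sig] <- lin_cls[lin_sig]
  }
  stats::setNames(cls, rownames(linear_table))
}

#' Edge-level lifespan models
#'
#' @param D A `cohort_edge_matrix`.
#' @param meta Metadata data frame aligned with the columns of D.
#' @param q FDR level.
#' @param ... Passed to [fit_lifespan_models()].
#' @return An `age_model_table` over edges (rows named `"i-j"`).
#' @export
edge_age_models <- function(D, meta, q = 0.05, ...) {
  Y <- t(D$values)
  colnames(Y) <- paste(D$edge_index[, 1L], D$edge_index[, 2L], sep = "-")
  fit_lifespan_models(Y, meta, q = q, ...)
}

#' Network-summary lifespan models
#'
#' @inheritParams edge_age_models
#' @param partition Partition table.
#' @return An `age_model_table` over network summaries.
#' @export
network_age_models <- function(D, meta, partition, q = 0.05, ...) {
  S <- cohort_network_summaries(D, partition)
  fit_lifespan_models(t(S), meta, q = q, ...)
}

#' Node-fALFF lifespan models
#'
#' @param falff Matrix, nodes x subjects, of fALFF values.
#' @param meta Metadata data frame aligned with the columns.
#' @param q FDR level.
#' @param ... Passed to [fit_lifespan_models()].
#' @return An `age_model_table` over nodes.
#' @export
falff_age_models <- function(falff, meta, q = 0.05, ...) {
  Y <- t(falff)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("node", seq_len(ncol(Y)))
  fit_lifespan_models(Y, meta, q = q, ...)
}
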