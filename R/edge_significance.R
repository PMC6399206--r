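# Permutation-based identification of edges with significant predictive
# weights, and network-level aggregation of edge weights.

#' Per-edge weights of a model fitted on supervised-reduced features
#'
#' Composes the model's coefficient vector in component space with the
#' reduction's linear map back to standardized edge space, giving one
#' weight per edge (canonical edge order). Only linear models qualify
#' (OLS, lasso, linear-kernel SVR).
#'
#' @param model A `fitted_model` trained on the reduction's components.
#' @param reduction The `supervised_reduction` that produced them.
#' @return Numeric vector, one weight per edge.
#' @export
edge_weights <- function(model, reduction) {
  beta <- model_coefficients(model)
  if (length(beta) != reduction$l)
    stop("model dimensionality does not match the reduction")
  as.numeric(reduction_rotation(reduction) %*% beta)
}

#' Permutation test for predictive edge weights
#'
#' Shuffles ages across subjects B times; each time the supervised
#' reduction is refit on the shuffled ages (by default - ages enter the
#' reduction, so the null must break that path) and the model refit with
#' hyperparameters frozen at their real-fit values. Two-tailed empirical
#' p per edge: (1 + #{|beta_b| >= |beta_real|}) / (B + 1).
#'
#' @param X Subjects x edges matrix.
#' @param ages Numeric vector of ages.
#' @param spec A [model_spec()] (`"ols"`, `"lasso"` or linear-kernel
#'   `"svr"`).
#' @param l Components for the supervised reduction.
#' @param B Number of permutations (>= 100).
#' @param alpha Two-tailed significance level; requires 1/(B+1) <= alpha.
#' @param seed Seed for the permutation stream.
#' @param refit_reduction If `FALSE`, the real-fit reduction is reused
#'   across permutations (faster, weaker null).
#' @return List of class `edge_significance`: `weights` (real fit),
#'   `p` (per edge), `significant`, `B`, `alpha`, plus the real
#'   `model` and `reduction`.
#' @export
permutation_test_edges <- function(X, ages, spec, l = 10L, B = 1000L,
                                   alpha = 0.001, seed = 1L,
                                   refit_reduction = TRUE) {
  if (B < 100L) stop("B must be at least 100")
  if (1 / (B + 1) > alpha)
    stop("B = ", B, " cannot resolve alpha = ", alpha,
         " (minimum attainable p = ", signif(1 / (B + 1), 3), ")")
  X <- as.matrix(X)
  n <- nrow(X)
  red <- fit_supervised_reduction(X, ages, l)
  model <- train_model(frozen_spec(spec, NULL), red$projections, ages)
  frozen <- frozen_spec(spec, model)
  w_real <- edge_weights(model, red)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  count <- integer(length(w_real))
  for (b in seq_len(B)) {
    perm <- sample(n)
    ages_b <- ages[perm]
    red_b <- if (refit_reduction) fit_supervised_reduction(X, ages_b, l)
             else red
    model_b <- train_model(frozen, red_b$projections, ages_b)
    w_b <- edge_weights(model_b, red_b)
    count <- count + (abs(w_b) >= abs(w_real))
  }
  p <- (1 + count) / (B + 1)
  structure(list(weights = w_real, p = p, significant = p <= alpha,
                 B = B, alpha = alpha, model = model, reduction = red,
                 family = spec$family),
            class = "edge_significance")
}

# freeze hyperparameters at the real-fit values so permuted refits skip
# the inner-CV search
frozen_spec <- function(spec, model) {
  if (is.null(model)) return(spec)
  s <- spec
  if (spec$family == "lasso") s$lasso_lambda_grid <- model$lambda
  if (spec$family == "svr") {
    s$svr_kernels <- model$kernel
    s$svr_C_grid <- model$C
    s$rbf_gamma_grid <- model$gamma
  }
  s
}

#' Aggregate edge weights within and between networks
#'
#' Sums and averages per-edge weights within each network and between
#' each network pair; computes per-node predictive power (sum of
#' |weights| of incident edges); and, when several models' significant
#' edge sets are supplied, intersects them into common
#' significant-positive and significant-negative edge sets.
#'
#' @param weights Numeric vector of per-edge weights (canonical order),
#'   or a named list of such vectors (one per model).
#' @param partition Partition table with `node` and `network`.
#' @param significant Logical vector, or list of vectors aligned with
#'   `weights`, flagging significant edges (optional).
#' @return List with `network_table` (within/between sums and means per
#'   model), `node_power` (per model), and when `significant` is given,
#'   `common_positive` / `common_negative` edge index vectors.
#' @export
network_weight_aggregation <- function(weights, partition,
                                       significant = NULL) {
  wl <- if (is.list(weights)) weights else list(model = weights)
  p <- nrow(partition)
  m <- p * (p - 1L) / 2L
  if (any(vapply(wl, length, 0L) != m))
    stop("weights length does not match the partition's edge count")
  ei <- edge_index(p)
  node_net <- partition$network[order(partition$node)]
  na <- node_net[ei[, 1L]]; nb <- node_net[ei[, 2L]]
  blk <- ifelse(na == nb, paste0("Within(", na, ")"),
                paste0("Between(", pmin(na, nb), ",", pmax(na, nb), ")"))
  network_table <- do.call(rbind, lapply(names(wl), function(nm) {
    s <- tapply(wl[[nm]], blk, sum)
    a <- tapply(wl[[nm]], blk, mean)
    data.frame(model = nm, block = names(s), sum = as.numeric(s),
               mean = as.numeric(a), row.names = NULL)
  }))
  node_power <- vapply(wl, function(w) {
    pow <- numeric(p)
    for (e in seq_len(m)) {
      pow[ei[e, 1L]] <- pow[ei[e, 1L]] + abs(w[e])
      pow[ei[e, 2L]] <- pow[ei[e, 2L]] + abs(w[e])
    }
    pow
  }, numeric(p))
  out <- list(network_table = network_table, node_power = node_power,
              edge_index = ei)
  if (!is.null(significant)) {
    sl <- if (is.list(significant)) significant else list(significant)
    pos <- lapply(seq_along(wl), function(k) which(sl[[k]] & wl[[k]] > 0))
    neg <- lapply(seq_along(wl), function(k) which(sl[[k]] & wl[[k]] < 0))
    out$common_positive <- Reduce(intersect, pos)
    out$common_negative <- Reduce(intersect, neg)
  }
  out
}
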