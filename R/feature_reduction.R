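# The three feature constructions used by the age predictors:
# (1) component-coefficient ("network") features from the cross-subject
#     PCA, (2) the supervised covariance-maximizing edge reduction, and
# (3) node-fALFF ("temporal") features. All fit on training data only
# and transform new data with stored parameters.

#' Fit the supervised edge-reduction
#'
#' Iteratively extracts unit-norm loading vectors p_k that maximize the
#' covariance between the edge-space projection u_k = X p_k and age,
#' deflating X and Y after each step (the closed-form maximizer of
#' Cov(Xp, Y) under ||p|| = 1 is X'Y / ||X'Y||). Edges and ages are
#' standardized with training means and sds first; zero-variance edges
#' are dropped (recorded) and zero-imputed at transform time.
#'
#' @param X Numeric matrix, subjects x edges.
#' @param Y Numeric vector of ages.
#' @param l Number of components to extract.
#' @return A list of class `supervised_reduction` with `loadings`
#'   (m x l, unit columns), `projections` (training n x l matrix U),
#'   `x_coeffs` (m x l matrix of deflation regressions c_k), `y_coeffs`
#'   (r_1..r_l), standardization parameters, `l` (components actually
#'   extracted) and `dropped_edges`.
#' @export
fit_supervised_reduction <- function(X, Y, l) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (length(Y) != n) stop("Y must have one age per row of X")
  if (l > min(n - 1L, m)) stop("l too large: must be <= min(n - 1, m)")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  dropped <- which(x_sd == 0)
  keep <- x_sd > 0
  y_mean <- mean(Y); y_sd <- stats::sd(Y)
  E <- sweep(sweep(X[, keep, drop = FALSE], 2L, x_mean[keep]), 2L,
             x_sd[keep], "/")
  Fv <- (Y - y_mean) / y_sd
  mk <- sum(keep)
  P <- matrix(0, mk, l); U <- matrix(0, n, l)
  Cm <- matrix(0, mk, l); r <- numeric(l)
  k <- 0L
  for (step in seq_len(l)) {
    w <- crossprod(E, Fv)                  # X'Y direction
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("covariance with age exhausted after ", k, " components")
      break
    }
    p <- as.numeric(w / nw)
    u <- as.numeric(E %*% p)
    uu <- sum(u^2)
    cvec <- as.numeric(crossprod(E, u)) / uu
    rk <- sum(Fv * u) / uu
    E <- E - tcrossprod(u, cvec)
    Fv <- Fv - u * rk
    k <- step
    P[, k] <- p; U[, k] <- u; Cm[, k] <- cvec; r[k] <- rk
  }
  structure(list(loadings = P[, seq_len(k), drop = FALSE],
                 projections = U[, seq_len(k), drop = FALSE],
                 x_coeffs = Cm[, seq_len(k), drop = FALSE],
                 y_coeffs = r[seq_len(k)],
                 x_mean = x_mean, x_sd = x_sd, keep = keep,
                 y_mean = y_mean, y_sd = y_sd,
                 l = k, n_edges = m, dropped_edges = dropped),
            class = "supervised_reduction")
}

#' Project new subjects through a fitted supervised reduction
#'
#' Standardizes `X_new` with the stored training means/sds and computes
#' the component scores sequentially with the stored loadings and
#' deflation coefficients. No refitting occurs.
#'
#' @param reduction A `supervised_reduction`.
#' @param X_new Numeric matrix, subjects x edges (same edge set as fit).
#' @return List of class `feature_block`: `matrix` (subjects x l),
#'   `feature_names`, `method = "edge"`.
#' @export
transform_supervised <- function(reduction, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != reduction$n_edges)
    stop("edge set mismatch: expected ", reduction$n_edges, " edges")
  keep <- reduction$keep
  E <- sweep(sweep(X_new[, keep, drop = FALSE], 2L, reduction$x_mean[keep]),
             2L, reduction$x_sd[keep], "/")
  l <- reduction$l
  U <- matrix(0, nrow(X_new), l)
  for (k in seq_len(l)) {
    u <- as.numeric(E %*% reduction$loadings[, k])
    U[, k] <- u
    E <- E - tcrossprod(u, reduction$x_coeffs[, k])
  }
  feature_block(U, paste0("edge_comp", seq_len(l)), "edge")
}

#' Linear map from standardized edge space to the reduction's components
#'
#' Returns the matrix R such that the component scores of a standardized
#' edge matrix Es are Es R (the sequential deflation applied by
#' [transform_supervised()] is exactly this linear map). Used to push
#' model coefficients back to edge space.
#'
#' @param reduction A `supervised_reduction`.
#' @return m x l matrix over the full (un-dropped) edge set; dropped
#'   edges get zero rows.
#' @export
reduction_rotation <- function(reduction) {
  P <- reduction$loadings; Cm <- reduction$x_coeffs
  R <- P %*% solve(crossprod(Cm, P))
  out <- matrix(0, reduction$n_edges, reduction$l)
  out[reduction$keep, ] <- R
  out
}

#' Component-coefficient ("network") features
#'
#' Training subjects get their coefficient rows from the fitted
#' decomposition; new subjects are projected onto the fitted components
#' by least squares in the component basis.
#'
#' @param decomp A `component_decomposition` fitted on training data.
#' @param L Number of leading components to use (default 150, capped at
#'   the retained components).
#' @return Object of class `network_feature_map` with a
#'   `$transform(edge_matrix)` closure; see [network_feature_transform()].
#' @export
network_feature_map <- function(decomp, L = 150L) {
  L <- min(L, ncol(decomp$components))
  Tm <- decomp$components[, seq_len(L), drop = FALSE]
  gram <- crossprod(Tm)
  structure(list(components = Tm, gram = gram, center = decomp$center,
                 L = L), class = "network_feature_map")
}

#' Project edge vectors onto fitted components
#'
#' @param map A `network_feature_map`.
#' @param edges Numeric matrix, m edges x n subjects (columns are
#'   subjects' edge vectors), or a `cohort_edge_matrix`.
#' @return `feature_block` with subjects x L coefficient matrix.
#' @export
network_feature_transform <- function(map, edges) {
  values <- if (inherits(edges, "cohort_edge_matrix")) edges$values
            else as.matrix(edges)
  coef <- solve(map$gram, crossprod(map$components, values - map$center))
  feature_block(t(coef), paste0("pc", seq_len(map$L)), "network")
}

#' Temporal (node-fALFF) features
#'
#' @param falff Matrix, nodes x subjects.
#' @return `feature_block` with subjects x nodes matrix (column order
#'   follows the node order of `falff`).
#' @export
temporal_features <- function(falff) {
  falff <- as.matrix(falff)
  nms <- rownames(falff)
  if (is.null(nms)) nms <- paste0("node", seq_len(nrow(falff)))
  feature_block(t(falff), nms, "temporal")
}

feature_block <- function(mat, names, method) {
  mat <- as.matrix(mat)
  colnames(mat) <- names
  structure(list(matrix = mat, feature_names = names, method = method),
            class = "feature_block")
}

#' Feature builders for the prediction pipeline
#'
#' Returns an object with `$fit(X, ages)` and `$transform(fitted, X)`
#' functions used by [kfold_validate()] and [external_validate()].
#' `X` is the subjects x edges matrix for methods `"network"` and
#' `"edge"`, and the subjects x nodes fALFF matrix for `"temporal"`.
#' Only `$fit` ever sees ages, and only those of the subjects it is
#' given; `"temporal"` and `"network"` ignore them.
#'
#' @param method `"network"`, `"edge"` or `"temporal"`.
#' @param L Components for the network method.
#' @param l Components for the edge method.
#' @return A `feature_builder` list.
#' @export
feature_builder <- function(method = c("network", "edge", "temporal"),
                            L = 150L, l = 20L) {
  method <- match.arg(method)
  fit <- switch(method,
    network = function(X, ages) {
      decomp <- fit_components(t(X), L = min(L, nrow(X)))
      network_feature_map(decomp, L = L)
    },
    edge = function(X, ages) fit_supervised_reduction(X, ages, l = l),
    temporal = function(X, ages) list(n_nodes = ncol(X)))
  transform <- switch(method,
    network = function(fitted, X) network_feature_transform(fitted, t(X)),
    edge = function(fitted, X) transform_supervised(fitted, X),
    temporal = function(fitted, X) {
      if (ncol(X) != fitted$n_nodes) stop("node set mismatch")
      feature_block(X, colnames(X), "temporal")
    })
  structure(list(method = method, fit = fit, transform = transform),
            class = "feature_builder")
}
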