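# Cross-subject principal components of the cohort edge matrix D:
# uncentered PCA via the eigenvectors of D'D, component characterization
# against the multi-subject and age-effect matrices, network summaries of
# a component, and the hemisphere chi-square test.

#' Principal components of the cohort edge matrix
#'
#' Decomposes the m-edges x n-subjects matrix D as T = D P, where the
#' columns of P are the eigenvectors of D'D sorted by descending
#' eigenvalue. By default the PCA is uncentered (performed on the raw
#' edge matrix), so the first component tracks the cohort-average
#' (intrinsic) connectivity pattern; an `edge_mean` centering option is
#' available. Each component's sign is fixed so that its coefficient
#' entry of largest magnitude is positive.
#'
#' @param D A `cohort_edge_matrix` (see [build_cohort_matrix()]) or a
#'   plain m x n matrix.
#' @param L Number of components to retain (default: all n).
#' @param centering `"none"` (default) or `"edge_mean"`.
#' @return A list of class `component_decomposition` with `components`
#'   (m x L matrix T), `coefficients` (n x L matrix; row i holds subject
#'   i's coefficients p_ij), `explained_variance` (fractions over all n
#'   components, non-increasing), `eigenvalues`, `edge_index`,
#'   `centering` and `center` (the subtracted edge means, or zeros).
#' @export
fit_components <- function(D, L = NULL, centering = c("none", "edge_mean")) {
  centering <- match.arg(centering)
  values <- if (inherits(D, "cohort_edge_matrix")) D$values else as.matrix(D)
  ei <- if (inherits(D, "cohort_edge_matrix")) D$edge_index else NULL
  m <- nrow(values); n <- ncol(values)
  if (is.null(L)) L <- n
  if (L > n) stop("L cannot exceed the number of subjects n = ", n)
  center <- if (centering == "edge_mean") rowMeans(values) else rep(0, m)
  X <- values - center
  G <- crossprod(X)                       # D'D, n x n
  e <- eigen(G, symmetric = TRUE)
  evals <- pmax(e$values, 0)              # rank deficiency: clamp to zero
  P <- e$vectors
  # sign convention: largest-|coefficient| entry positive per component
  for (j in seq_len(n)) {
    k <- which.max(abs(P[, j]))
    if (P[k, j] < 0) P[, j] <- -P[, j]
  }
  Tm <- X %*% P
  expl <- if (sum(evals) > 0) evals / sum(evals) else evals
  structure(list(components = Tm[, seq_len(L), drop = FALSE],
                 coefficients = P[, seq_len(L), drop = FALSE],
                 explained_variance = expl,
                 eigenvalues = evals,
                 edge_index = ei, n_subjects = n, n_edges = m,
                 centering = centering, center = center,
                 subject_ids = colnames(values)),
            class = "component_decomposition")
}

#' Reconstruct one subject's connectivity matrix from the components
#'
#' Computes the truncated expansion M_i = sum_j p_ij PC_j over the
#' retained components and devectorizes it with unit diagonal.
#'
#' @param decomp A `component_decomposition`.
#' @param i Subject index.
#' @param L Number of components to use (default: all retained).
#' @return Symmetric matrix with unit diagonal.
#' @export
subject_expansion <- function(decomp, i, L = NULL) {
  nL <- ncol(decomp$components)
  if (is.null(L)) L <- nL
  if (L > nL) stop("L exceeds the retained components")
  if (i < 1L || i > decomp$n_subjects) stop("subject index out of bounds")
  v <- decomp$components[, seq_len(L), drop = FALSE] %*%
    decomp$coefficients[i, seq_len(L)]
  devectorize_matrix(as.numeric(v) + decomp$center, diag = 1)
}

#' Correlation of each component's coefficients with age
#'
#' @param decomp A `component_decomposition`.
#' @param ages Numeric vector, one age per subject.
#' @return Data frame (component, r, abs_r, flag) sorted by descending
#'   |r|; zero-variance coefficient columns get r = 0 and a flag.
#' @export
coefficient_age_correlations <- function(decomp, ages) {
  if (length(ages) != decomp$n_subjects)
    stop("ages must have one entry per subject")
  nL <- ncol(decomp$coefficients)
  r <- numeric(nL); flag <- logical(nL)
  for (j in seq_len(nL)) {
    cj <- decomp$coefficients[, j]
    if (stats::sd(cj) == 0) { r[j] <- 0; flag[j] <- TRUE }
    else r[j] <- stats::cor(cj, ages)
  }
  out <- data.frame(component = seq_len(nL), r = r, abs_r = abs(r),
                    zero_variance = flag)
  out[order(-out$abs_r), ]
}

#' Edgewise age-effect matrix
#'
#' Correlates each edge's Fisher-z values with age across subjects and
#' devectorizes the result with unit diagonal.
#'
#' @param D A `cohort_edge_matrix` or m x n matrix.
#' @param ages Numeric vector of subject ages.
#' @return Symmetric matrix of edgewise Pearson correlations with age
#'   (unit diagonal); constant edges get 0 (with a `"flagged_edges"`
#'   attribute listing them).
#' @export
age_effect_matrix <- function(D, ages) {
  values <- if (inherits(D, "cohort_edge_matrix")) D$values else as.matrix(D)
  n <- ncol(values)
  if (length(ages) != n) stop("ages must have one entry per subject")
  if (n < 3L) stop("need at least 3 subjects")
  sds <- apply(values, 1L, stats::sd)
  r <- rep(0, nrow(values))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(t(values[ok, , drop = FALSE]), ages))
  M <- devectorize_matrix(r, diag = 1)
  attr(M, "flagged_edges") <- which(!ok)
  M
}

#' Compare two connectivity-style matrices edge by edge
#'
#' Correlates the off-diagonal upper triangles and fits linear and
#' quadratic least-squares models of `Mb` edges on `Ma` edges.
#'
#' @param Ma,Mb Symmetric matrices with the same node count.
#' @return List with `r` (Pearson correlation of the edge vectors),
#'   `linear` and `quadratic` fit tables (coefficients, t, p).
#' @export
compare_matrices <- function(Ma, Mb) {
  if (!all(dim(Ma) == dim(Mb))) stop("matrices must share dimensions")
  x <- vectorize_matrix(Ma); y <- vectorize_matrix(Mb)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance edge triangle")
  fit_tab <- function(fit) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1L], t = s[, 3L],
               p = s[, 4L], row.names = NULL)
  }
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  list(r = stats::cor(x, y), linear = fit_tab(lin), quadratic = fit_tab(quad))
}

#' Within/between-network summary of one component
#'
#' Devectorizes component `j`, averages its edge values within each
#' network and between each network pair, and lists edges whose absolute
#' value exceeds a presentation threshold.
#'
#' @param decomp A `component_decomposition`.
#' @param j Component index.
#' @param partition Data frame with columns `node`, `network` (and
#'   optionally `hemisphere`).
#' @param threshold Edges with |value| above this are listed (default
#'   `Inf`: none).
#' @return List with `within` (network, value), `between` (network_a,
#'   network_b, value) and `top_edges` (i, j, value).
#' @export
component_network_summary <- function(decomp, j, partition, threshold = Inf) {
  v <- decomp$components[, j]
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  M <- devectorize_matrix(v, diag = 0)
  sm <- network_summaries_matrix(M, partition)
  ei <- edge_index(nrow(M))
  keep <- abs(v) >= threshold
  top <- data.frame(i = ei[keep, 1L], j = ei[keep, 2L], value = v[keep])
  top <- top[order(-abs(top$value)), , drop = FALSE]
  list(within = sm$within, between = sm$between, top_edges = top)
}

# mean edge value within each network and between each pair, for a
# symmetric matrix with meaningless diagonal
network_summaries_matrix <- function(M, partition) {
  nets <- unique(partition$network)
  node_net <- partition$network[order(partition$node)]
  within <- data.frame(network = nets, value = NA_real_)
  for (k in seq_along(nets)) {
    nd <- which(node_net == nets[k])
    if (length(nd) >= 2L) {
      sub <- M[nd, nd]
      within$value[k] <- mean(sub[upper.tri(sub)])
    }
  }
  pairs <- utils::combn(nets, 2L)
  between <- data.frame(network_a = pairs[1L, ], network_b = pairs[2L, ],
                        value = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- which(node_net == pairs[1L, k]); b <- which(node_net == pairs[2L, k])
    between$value[k] <- mean(M[a, b, drop = FALSE])
  }
  list(within = within, between = between)
}

#' Chi-square test of intra- vs inter-hemispheric edge counts
#'
#' Tests whether the intra/inter-hemispheric split of an edge set differs
#' from the split among all possible edges (goodness of fit, 1 df).
#'
#' @param edge_set Two-column matrix or data frame of node pairs (i, j).
#' @param partition Data frame with columns `node` and `hemisphere`.
#' @return List with `statistic`, `p`, `observed`, `expected` and a
#'   `low_expected` warning flag when an expected count falls below 1.
#' @export
hemisphere_chi_square <- function(edge_set, partition) {
  edge_set <- as.matrix(edge_set)
  if (nrow(edge_set) == 0L) stop("edge_set is empty")
  hemi <- partition$hemisphere[order(partition$node)]
  p <- length(hemi)
  all_e <- edge_index(p)
  intra_all <- hemi[all_e[, 1L]] == hemi[all_e[, 2L]]
  prop <- c(intra = mean(intra_all), inter = mean(!intra_all))
  obs_intra <- sum(hemi[edge_set[, 1L]] == hemi[edge_set[, 2L]])
  observed <- c(intra = obs_intra, inter = nrow(edge_set) - obs_intra)
  expected <- prop * nrow(edge_set)
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = observed, expected = expected,
       low_expected = any(expected < 1))
}
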