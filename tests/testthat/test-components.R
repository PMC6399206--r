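# Cross-subject PCA of the edge matrix and component characterization.

test_that("fit_components reproduces a hand eigendecomposition", {
  D <- matrix(c(2, 0, 0, 1), 2, 2)  # D'D has eigenvalues 4 and 1
  dec <- fit_components(D)
  expect_equal(dec$explained_variance, c(0.8, 0.2))
  expect_equal(abs(dec$components[, 1]), c(2, 0))
  expect_equal(abs(dec$components[, 2]), c(0, 1))
})

test_that("components match an independent SVD oracle up to sign", {
  set.seed(14)
  D <- matrix(rnorm(50 * 20), 50, 20)
  dec <- fit_components(D)
  sv <- svd(D)
  # oracle: T = U S aligned to D's right singular vectors
  oracleT <- sv$u %*% diag(sv$d)
  for (j in 1:20) {
    s <- sign(sum(dec$components[, j] * oracleT[, j]))
    expect_equal(dec$components[, j], s * oracleT[, j], tolerance = 1e-8)
  }
  expect_equal(dec$explained_variance, sv$d^2 / sum(sv$d^2),
               tolerance = 1e-10)
  # explained variance is non-increasing and sums to one
  expect_true(all(diff(dec$explained_variance) <= 1e-12))
  expect_equal(sum(dec$explained_variance), 1)
  # full-rank reconstruction
  recon <- dec$components %*% t(dec$coefficients)
  expect_lt(max(abs(D - recon)), 1e-10 * max(abs(D)))
  # orthogonality of components
  G <- crossprod(dec$components)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
})

test_that("L is validated and rank deficiency is tolerated", {
  D <- matrix(rnorm(30), 10, 3)
  expect_error(fit_components(D, L = 4), "L cannot exceed")
  Ddef <- cbind(D[, 1], D[, 1], D[, 2])  # rank 2
  dec <- fit_components(Ddef)
  expect_equal(dec$eigenvalues[3], 0, tolerance = 1e-8)
})

test_that("subject_expansion recovers subjects and rank-1 residuals", {
  D <- small_edge_matrix()
  dec <- fit_components(D)
  n <- ncol(D$values)
  # complete expansion recovers the subject off-diagonal
  M5 <- devectorize_matrix(D$values[, 5], diag = 1)
  expect_equal(subject_expansion(dec, 5), M5, tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 truncation residual energy equals the tail eigenvalue energy
  resid2 <- sum(vapply(seq_len(n), function(i) {
    full <- D$values[, i]
    approx1 <- dec$components[, 1] * dec$coefficients[i, 1]
    sum((full - approx1)^2)
  }, 0))
  expect_equal(resid2, sum(dec$eigenvalues[-1]), tolerance = 1e-6)
  expect_error(subject_expansion(dec, n + 1), "out of bounds")
})

test_that("coefficient-age correlations rank the planted component", {
  dec <- fit_components(small_edge_matrix())
  ages <- small_cohort()$metadata$age
  tab <- coefficient_age_correlations(dec, ages)
  expect_equal(sort(tab$component), seq_len(ncol(dec$coefficients)))
  expect_true(all(diff(tab$abs_r) <= 1e-12))
  # coefficients equal to age give r = 1
  fake <- dec
  fake$coefficients[, 3] <- ages
  expect_equal(coefficient_age_correlations(fake, ages)$r[1], 1)
  # coefficients orthogonal to centered age give r = 0
  ac <- ages - mean(ages)
  v <- rnorm(length(ages))
  v <- v - ac * sum(v * ac) / sum(ac^2)
  fake$coefficients[, 3] <- v
  tab2 <- coefficient_age_correlations(fake, ages)
  expect_equal(tab2$r[tab2$component == 3], 0, tolerance = 1e-10)
})

test_that("age_effect_matrix detects perfect and absent age effects", {
  set.seed(2)
  ages <- runif(30, 6, 85)
  D <- matrix(rnorm(10 * 30), 10, 30)
  D[4, ] <- 0.01 * ages
  M <- age_effect_matrix(D, ages)
  ei <- edge_index(5)
  expect_equal(M[ei[4, 1], ei[4, 2]], 1, tolerance = 1e-12)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 5))
  # permuted (null) edges stay below a permutation-oracle quantile
  set.seed(7)
  null_max <- replicate(200, max(abs(cor(sample(ages), D[1, ]))))
  Mnull <- age_effect_matrix(D[, sample(30)], ages)
  expect_lt(abs(Mnull[ei[1, 1], ei[1, 2]]), quantile(null_max, 0.999))
})

test_that("compare_matrices fits identity, sign flips and exact quadratics", {
  M <- random_symmetric(8, seed = 4)
  res <- compare_matrices(M, M)
  expect_equal(res$r, 1)
  expect_equal(res$linear$estimate[res$linear$term == "x"], 1,
               tolerance = 1e-10)
  expect_equal(res$linear$estimate[res$linear$term == "(Intercept)"], 0,
               tolerance = 1e-10)
  expect_equal(compare_matrices(M, -M)$r, -1)
  # quadratic fit on y = x^2 samples
  Mb <- devectorize_matrix(vectorize_matrix(M)^2, diag = 1)
  resq <- compare_matrices(M, Mb)$quadratic
  expect_equal(resq$estimate[resq$term == "I(x^2)"], 1, tolerance = 1e-10)
  expect_equal(resq$estimate[resq$term == "x"], 0, tolerance = 1e-10)
  expect_error(compare_matrices(diag(3), M[1:3, 1:3]), "zero-variance")
})

test_that("component network summaries match hand arithmetic", {
  # 4 nodes, networks {1,2} and {3,4}; within-A edge 0.8, between 0.2
  part <- data.frame(node = 1:4, network = c("A", "A", "B", "B"))
  v <- c(0.8, 0.2, 0.2, 0.2, 0.2, 0.6)  # edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  dec <- list(components = matrix(v, ncol = 1), n_subjects = 1)
  class(dec) <- "component_decomposition"
  sm <- component_network_summary(dec, 1, part, threshold = 0.7)
  expect_equal(sm$within$value[sm$within$network == "A"], 0.8)
  expect_equal(sm$within$value[sm$within$network == "B"], 0.6)
  expect_equal(sm$between$value, 0.2)
  expect_equal(nrow(sm$top_edges), 1)  # only the 0.8 edge survives 0.7
  expect_equal(sm$top_edges$value, 0.8)
  # threshold above the maximum leaves the list empty
  expect_equal(nrow(component_network_summary(dec, 1, part,
                                              threshold = 2)$top_edges), 0)
  # constant component: all summaries equal the constant
  decc <- list(components = matrix(0.3, 6, 1), n_subjects = 1)
  class(decc) <- "component_decomposition"
  smc <- component_network_summary(decc, 1, part)
  expect_true(all(smc$within$value == 0.3))
  expect_true(all(smc$between$value == 0.3))
})

test_that("hemisphere chi-square matches the by-hand statistic", {
  part <- data.frame(node = 1:8, hemisphere = rep(c("L", "R"), each = 4))
  # all possible edges: 28; intra = 2 * C(4,2) = 12, prop = 12/28
  # build an edge set with observed 30 intra / 10 inter under 50/50
  # expectations by using a partition where the global split is even
  part2 <- data.frame(node = 1:100,
                      hemisphere = rep(c("L", "R"), 50))
  # choose hemispheres so that intra and inter proportions are ~0.5:
  # with alternating labels on 100 nodes: intra = 2*C(50,2) = 2450 of 4950
  intra_edges <- t(combn(seq(1, 99, by = 2), 2))[1:30, ]
  inter_edges <- cbind(seq(1, 20, by = 2), seq(2, 20, by = 2))[1:10, ]
  es <- rbind(intra_edges, inter_edges)
  res <- hemisphere_chi_square(es, part2)
  prop_intra <- 2450 / 4950
  expected <- c(40 * prop_intra, 40 * (1 - prop_intra))
  hand <- sum((c(30, 10) - expected)^2 / expected)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$p, pchisq(hand, 1, lower.tail = FALSE))
  # edge set matching global proportions gives statistic 0
  all_e <- edge_index(8)
  expect_equal(hemisphere_chi_square(all_e, part)$statistic, 0,
               tolerance = 1e-12)
  expect_error(hemisphere_chi_square(matrix(0, 0, 2), part), "empty")
})

test_that("subject relabeling only permutes coefficient rows", {
  D <- small_edge_matrix()
  perm <- sample(ncol(D$values))
  dec1 <- fit_components(D$values)
  dec2 <- fit_components(D$values[, perm])
  expect_equal(dec2$coefficients, dec1$coefficients[perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dec2$components, dec1$components, tolerance = 1e-6)
  expect_equal(dec2$explained_variance, dec1$explained_variance,
               tolerance = 1e-10)
})
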