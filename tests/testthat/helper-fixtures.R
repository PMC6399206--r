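# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small cohort reused across modules: 40 subjects, 20 nodes, 10 networks
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- generator_config(n_subjects = 40, n_nodes = 20, n_networks = 10,
                            n_volumes = 200, seed = 11)
    fixture_env$small <- generate_cohort(cfg)
  }
  fixture_env$small
}

small_edge_matrix <- function() {
  if (is.null(fixture_env$small_D))
    fixture_env$small_D <- build_cohort_matrix(small_cohort())
  fixture_env$small_D
}

# reference-condition cohort for recovery tests: 200 subjects, 50 nodes
reference_cohort <- function() {
  if (is.null(fixture_env$reference))
    fixture_env$reference <- generate_cohort(generator_config(seed = 7))
  fixture_env$reference
}

reference_edge_matrix <- function() {
  if (is.null(fixture_env$reference_D))
    fixture_env$reference_D <- build_cohort_matrix(reference_cohort())
  fixture_env$reference_D
}

# random symmetric matrix with unit diagonal
random_symmetric <- function(p, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(p * p), p, p)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# metadata table with independent covariates, for model-fitting tests
toy_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 6, 85), sex = rbinom(n, 1, 0.5),
             fd = exp(rnorm(n, -1.8, 0.3)), tiv = rnorm(n, 1400, 110))
}
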