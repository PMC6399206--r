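# End-to-end orchestration: simulate -> connectome -> decompose ->
# lifespan -> features -> predict -> permute -> report.

#' Pipeline configuration
#'
#' @param generator_internal,generator_external [generator_config()]
#'   objects; the external one may be `NULL` to skip external validation.
#' @param families Model families to run.
#' @param methods Feature methods to run.
#' @param K Cross-validation folds.
#' @param L Components for the network feature method.
#' @param l Components for the edge feature method.
#' @param q FDR level for the lifespan models.
#' @param leakage_mode `"strict"` or `"paper"` feature fitting.
#' @param permutation_B,permutation_alpha Permutation-test settings
#'   (`permutation_B = 0` skips the permutation stage).
#' @param permutation_family Model family for the permutation test.
#' @param seed Master seed for folds and permutations.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator_internal = generator_config(),
                            generator_external = NULL,
                            families = c("ols", "lasso", "svr"),
                            methods = c("network", "edge", "temporal"),
                            K = 10L, L = 150L, l = 20L, q = 0.05,
                            leakage_mode = "strict",
                            permutation_B = 500L,
                            permutation_alpha = 0.01,
                            permutation_family = "ols",
                            seed = 1L) {
  structure(list(generator_internal = generator_internal,
                 generator_external = generator_external,
                 families = families, methods = methods,
                 K = as.integer(K), L = as.integer(L), l = as.integer(l),
                 q = q, leakage_mode = leakage_mode,
                 permutation_B = as.integer(permutation_B),
                 permutation_alpha = permutation_alpha,
                 permutation_family = permutation_family,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates the cohort(s), builds connectivity and fALFF, fits the
#' cross-subject components and their age correlations, fits edge-,
#' network- and node-level lifespan models, runs every requested feature
#' method x model family combination through K-fold internal validation
#' (and external validation when an external generator is configured),
#' runs the permutation test for predictive edges, and collates a
#' report. Deterministic given the config seeds. When `out_dir` is
#' given, stage outputs and `report.json` are written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_run`: `cohorts`, `D`, `falff`,
#'   `decomposition` summaries, `lifespan`, `validation` (per
#'   method/family `prediction_result`s), `external`, `edge_significance`
#'   and `report` (plain-list summary).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  internal <- generate_cohort(config$generator_internal)
  external <- if (!is.null(config$generator_external))
    generate_paired_cohorts(config$generator_internal,
                            config$generator_external)$external else NULL

  D <- build_cohort_matrix(internal)
  X_edges <- t(D$values)
  ages <- internal$metadata$age
  falff <- sapply(internal$time_series, compute_falff,
                  tr_seconds = internal$tr_seconds)
  rownames(falff) <- rownames(internal$time_series[[1L]])

  # components
  decomp <- fit_components(D)
  agecor <- coefficient_age_correlations(decomp, ages)
  ms <- multi_subject_matrix(internal)
  pc1 <- devectorize_matrix(decomp$components[, 1L], diag = 1)
  cmp_intrinsic <- compare_matrices(pc1, ms)
  aem <- age_effect_matrix(D, ages)
  best_age_pc <- agecor$component[1L]
  pc_age <- devectorize_matrix(decomp$components[, best_age_pc], diag = 1)
  cmp_age <- compare_matrices(pc_age, aem)

  # lifespan models
  lifespan <- list(
    edges = edge_age_models(D, internal$metadata, q = config$q),
    networks = network_age_models(D, internal$metadata,
                                  internal$partition, q = config$q),
    falff = falff_age_models(falff, internal$metadata, q = config$q))

  # prediction grid
  ext_inputs <- NULL
  if (!is.null(external)) {
    D_ext <- build_cohort_matrix(external)
    ext_inputs <- list(edges = t(D_ext$values), ages = external$metadata$age,
                       cohort = external)
  }
  validation <- list(); external_results <- list()
  for (mth in config$methods) {
    bld <- feature_builder(mth, L = config$L, l = config$l)
    Xin <- if (mth == "temporal") t(falff) else X_edges
    for (fam in config$families) {
      spec <- model_spec(fam, seed = config$seed)
      key <- paste(mth, fam, sep = ".")
      validation[[key]] <- kfold_validate(bld, Xin, ages, spec,
                                          K = config$K, seed = config$seed,
                                          leakage_mode = config$leakage_mode)
      if (!is.null(ext_inputs) && mth != "temporal") {
        external_results[[key]] <- external_validate(
          bld, Xin, ages, ext_inputs$edges, ext_inputs$ages, spec)
      }
    }
  }

  edge_sig <- NULL
  if (config$permutation_B > 0L) {
    edge_sig <- permutation_test_edges(
      X_edges, ages, model_spec(config$permutation_family,
                                seed = config$seed),
      l = config$l, B = config$permutation_B,
      alpha = config$permutation_alpha, seed = config$seed)
  }

  grid <- do.call(rbind, lapply(names(validation), function(k) {
    v <- validation[[k]]
    e <- external_results[[k]]
    data.frame(method = v$method, family = v$family,
               internal_r = v$pearson_r, internal_mae = v$mae_years,
               external_r = if (is.null(e)) NA_real_ else e$external$pearson_r,
               external_mae = if (is.null(e)) NA_real_
                              else e$external$mae_years)
  }))
  report <- list(
    n_internal = nrow(internal$metadata),
    n_external = if (is.null(external)) 0L else nrow(external$metadata),
    explained_variance = decomp$explained_variance,
    pc1_variance_fraction = decomp$explained_variance[1L],
    top_age_components = utils::head(agecor, 5L),
    pc1_multisubject_r = cmp_intrinsic$r,
    age_component = best_age_pc,
    age_component_age_r = agecor$r[1L],
    age_component_effect_r = cmp_age$r,
    class_counts = lapply(lifespan, function(t) table(t$class)),
    metric_grid = grid,
    n_significant_edges = if (is.null(edge_sig)) NA_integer_
                          else sum(edge_sig$significant))
  run <- structure(list(cohorts = list(internal = internal,
                                       external = external),
                        D = D, falff = falff, decomposition = decomp,
                        age_correlations = agecor,
                        multi_subject = ms, age_effect = aem,
                        lifespan = lifespan, validation = validation,
                        external = external_results,
                        edge_significance = edge_sig,
                        report = report, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

# write stage outputs as plain-text files plus report.json
write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gz <- gzfile(file.path(out_dir, "cohort_edges.tsv.gz"), "w")
  utils::write.table(run$D$values, gz, sep = "\t", row.names = FALSE)
  close(gz)
  utils::write.table(run$D$edge_index, file.path(out_dir, "edge_index.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(run$falff, file.path(out_dir, "falff.tsv"), sep = "\t",
                     row.names = TRUE, col.names = NA)
  utils::write.csv(run$age_correlations,
                   file.path(out_dir, "age_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(
    run$decomposition$explained_variance),
    explained_variance = run$decomposition$explained_variance),
    file.path(out_dir, "explained_variance.csv"), row.names = FALSE)
  for (lvl in names(run$lifespan)) {
    t <- run$lifespan[[lvl]]
    out <- data.frame(unit = rownames(t$linear),
                      linear_beta = t$linear$age_beta,
                      linear_t = t$linear$age_t,
                      linear_p = t$linear$age_p,
                      linear_p_fdr = t$linear$age_p_fdr,
                      quadratic_beta = t$quadratic$age_beta,
                      quadratic_t = t$quadratic$age_t,
                      quadratic_p = t$quadratic$age_p,
                      quadratic_p_fdr = t$quadratic$age_p_fdr,
                      class = unname(t$class))
    utils::write.csv(out, file.path(out_dir,
                                    paste0(lvl, "_age_models.csv")),
                     row.names = FALSE)
  }
  for (k in names(run$validation))
    utils::write.csv(run$validation[[k]]$predictions,
                     file.path(out_dir, paste0("predictions_", k, ".csv")),
                     row.names = FALSE)
  if (!is.null(run$edge_significance)) {
    es <- run$edge_significance
    utils::write.csv(data.frame(i = run$D$edge_index[, 1L],
                                j = run$D$edge_index[, 2L],
                                weight = es$weights, p = es$p,
                                significant = es$significant),
                     file.path(out_dir, "edge_significance.csv"),
                     row.names = FALSE)
  }
  rep <- run$report
  # JSON has no NA scalar; drop fields for stages that did not run
  rep <- rep[!vapply(rep, function(x)
    is.atomic(x) && length(x) == 1L && is.na(x), NA)]
  rep$class_counts <- lapply(rep$class_counts, function(x)
    as.list(stats::setNames(as.integer(x), names(x))))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
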