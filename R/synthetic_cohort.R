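# Synthetic resting-state cohort generator. Emits ROI time series plus
# metadata with planted intrinsic (block) connectivity, an additive
# age-related connectivity pattern, planted quadratic edges, subject noise,
# and age-dependent low-frequency spectral power (fALFF), all reproducible
# from a seed and with ground truth retained for recovery tests.

#' Generator configuration
#'
#' Assembles and validates the configuration for [generate_cohort()]. The
#' defaults define the package's reference study conditions: 200 subjects,
#' 50 nodes in 10 networks of 5, 400 volumes at TR 0.645 s, ages uniform
#' on 6-85 years, block-structured baseline connectivity (within-network
#' z = 0.5, between-network z = 0.1), a sparse planted age pattern
#' (within-network declines of -0.004 z/yr in three networks, selected
#' between-network increases of +0.0025 z/yr), planted quadratic edges
#' (curvature +/- 1e-4 z/yr^2), edge noise sd 0.1 z, and node fALFF
#' baselines of 0.5 with linear slopes of -0.0015/yr over most nodes and
#' planted U-shaped nodes (curvature 2e-5 /yr^2).
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of ROIs (nodes).
#' @param n_networks Number of networks; `network_sizes` must sum to
#'   `n_nodes`.
#' @param network_sizes Integer vector of nodes per network.
#' @param n_volumes Time points per subject.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param age_range Length-2 numeric, years.
#' @param baseline_within_z,baseline_between_z Baseline Fisher-z for
#'   within- and between-network edges.
#' @param age_slope_map Data frame with columns `i`, `j`, `slope`
#'   (z-units per year); `NULL` uses the default planted pattern.
#' @param quadratic_edge_set Data frame with columns `i`, `j`, `curv`
#'   (z-units per year^2); `NULL` uses the default.
#' @param noise_sd_z Sd of the symmetric Gaussian edge noise (z-units).
#' @param falff_noise_sd Sd of between-subject node fALFF variability
#'   unrelated to age (added to the planted target before clipping).
#' @param falff_base Per-node baseline fALFF in (0, 1); recycled.
#' @param falff_age_slope Per-node fALFF change per year; recycled;
#'   `NULL` uses the default pattern.
#' @param falff_quadratic_nodes Integer node ids receiving a quadratic
#'   fALFF trend; `NULL` uses the default (the first zero-slope network).
#' @param falff_quadratic_curv Curvature (per year^2) for those nodes.
#' @param seed Integer RNG seed.
#' @param cohort_label Label written into metadata.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 200L, n_nodes = 50L,
                             n_networks = 10L,
                             network_sizes = NULL,
                             n_volumes = 400L, tr_seconds = 0.645,
                             age_range = c(6, 85),
                             baseline_within_z = 0.5,
                             baseline_between_z = 0.1,
                             age_slope_map = NULL,
                             quadratic_edge_set = NULL,
                             noise_sd_z = 0.1,
                             falff_noise_sd = 0.06,
                             falff_base = 0.5,
                             falff_age_slope = NULL,
                             falff_quadratic_nodes = NULL,
                             falff_quadratic_curv = 2e-5,
                             seed = 1L,
                             cohort_label = "internal") {
  if (is.null(network_sizes)) {
    base_sz <- n_nodes %/% n_networks
    network_sizes <- rep(base_sz, n_networks)
    network_sizes[n_networks] <- n_nodes - sum(network_sizes[-n_networks])
  }
  if (sum(network_sizes) != n_nodes)
    stop("network_sizes must sum to n_nodes")
  if (noise_sd_z < 0) stop("noise_sd_z must be >= 0")
  if (length(age_range) != 2L || age_range[1L] >= age_range[2L])
    stop("age_range must be increasing length 2")
  partition <- default_partition(network_sizes)
  if (is.null(age_slope_map))
    age_slope_map <- default_age_slope_map(partition)
  if (is.null(quadratic_edge_set))
    quadratic_edge_set <- default_quadratic_edges(partition)
  falff_base <- rep_len(falff_base, n_nodes)
  if (is.null(falff_age_slope))
    falff_age_slope <- default_falff_slopes(partition)
  falff_age_slope <- rep_len(falff_age_slope, n_nodes)
  if (is.null(falff_quadratic_nodes))
    falff_quadratic_nodes <- default_falff_quadratic_nodes(partition,
                                                          falff_age_slope)
  if (any(falff_base <= 0 | falff_base >= 1))
    stop("falff_base must lie in (0, 1)")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_nodes = as.integer(n_nodes),
              n_networks = as.integer(n_networks),
              network_sizes = as.integer(network_sizes),
              n_volumes = as.integer(n_volumes),
              tr_seconds = tr_seconds, age_range = age_range,
              baseline_within_z = baseline_within_z,
              baseline_between_z = baseline_between_z,
              age_slope_map = age_slope_map,
              quadratic_edge_set = quadratic_edge_set,
              noise_sd_z = noise_sd_z, falff_noise_sd = falff_noise_sd,
              falff_base = falff_base,
              falff_age_slope = falff_age_slope,
              falff_quadratic_nodes = as.integer(falff_quadratic_nodes),
              falff_quadratic_curv = falff_quadratic_curv,
              seed = as.integer(seed), cohort_label = cohort_label,
              partition = partition)
  class(cfg) <- "generator_config"
  cfg
}

# node -> network/hemisphere table; hemispheres alternate within networks
default_partition <- function(network_sizes) {
  n_nodes <- sum(network_sizes)
  network <- rep(sprintf("N%02d", seq_along(network_sizes)), network_sizes)
  data.frame(node = seq_len(n_nodes), network = network,
             hemisphere = rep_len(c("L", "R"), n_nodes),
             stringsAsFactors = FALSE)
}

# planted linear age pattern: within-network declines in networks 2-4,
# between-network increases for pairs (1,5), (1,6), (6,7)
default_age_slope_map <- function(partition) {
  nets <- split(partition$node, partition$network)
  rows <- list()
  for (k in intersect(c("N02", "N03", "N04"), names(nets))) {
    nd <- nets[[k]]
    if (length(nd) >= 2L) {
      ei <- edge_index(length(nd))
      rows[[length(rows) + 1L]] <-
        data.frame(i = nd[ei[, 1L]], j = nd[ei[, 2L]], slope = -0.004)
    }
  }
  for (pr in list(c("N01", "N05"), c("N01", "N06"), c("N06", "N07"))) {
    if (all(pr %in% names(nets))) {
      g <- expand.grid(i = nets[[pr[1L]]], j = nets[[pr[2L]]])
      rows[[length(rows) + 1L]] <-
        data.frame(i = pmin(g$i, g$j), j = pmax(g$i, g$j), slope = 0.0025)
    }
  }
  do.call(rbind, rows)
}

# planted quadratic edges: inverted-U within network 8, U within network 9
default_quadratic_edges <- function(partition) {
  nets <- split(partition$node, partition$network)
  rows <- list()
  spec <- list(N08 = -1e-4, N09 = 1e-4)
  for (k in intersect(names(spec), names(nets))) {
    nd <- nets[[k]]
    if (length(nd) >= 2L) {
      ei <- edge_index(length(nd))
      rows[[length(rows) + 1L]] <-
        data.frame(i = nd[ei[, 1L]], j = nd[ei[, 2L]], curv = spec[[k]])
    }
  }
  do.call(rbind, rows)
}

# fALFF slopes: decline in networks 1-6, rise in network 7, flat elsewhere
default_falff_slopes <- function(partition) {
  sl <- rep(0, nrow(partition))
  sl[partition$network %in% sprintf("N%02d", 1:6)] <- -0.0015
  sl[partition$network == "N07"] <- 0.001
  sl
}

default_falff_quadratic_nodes <- function(partition, slopes) {
  cand <- partition$node[partition$network == "N08"]
  cand[slopes[cand] == 0]
}

# symmetric matrix (zero diagonal) from an edge table with a value column
edge_table_matrix <- function(tab, n_nodes, value_col) {
  M <- matrix(0, n_nodes, n_nodes)
  if (!is.null(tab) && nrow(tab)) {
    idx_a <- cbind(tab$i, tab$j)
    M[idx_a] <- tab[[value_col]]
    M[idx_a[, 2:1, drop = FALSE]] <- tab[[value_col]]
  }
  M
}

#' Project a matrix to the nearest positive-semidefinite correlation matrix
#'
#' Eigenvalues are clipped at `eps`, the matrix is reconstructed, and the
#' diagonal is renormalized to exactly 1. Deterministic.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor.
#' @return Positive-semidefinite correlation matrix.
#' @export
nearest_psd_correlation <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= eps)) {
    diag(R) <- 1
    return(R)
  }
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  R2 <- (R2 + t(R2)) / 2
  diag(R2) <- 1
  R2
}

# expected fALFF of the mixture sqrt(w) lowband + sqrt(1-w) broadband,
# under the package's amplitude-spectrum estimator. pl/pw are normalized
# per-bin power profiles of the two components at the estimator's bins.
falff_mix_curve <- function(w, pl, pw, in_low, in_tot) {
  amp <- sqrt(w * pl + (1 - w) * pw)
  sum(amp[in_low]) / sum(amp[in_tot])
}

# per-bin power profiles for the estimator's frequency grid
falff_band_profiles <- function(n_volumes, tr_seconds,
                                band = c(0.01, 0.1), butter_order = 4,
                                low = c(0.01, 0.1), total = c(0.01, 0.25)) {
  freqs <- falff_freqs(n_volumes, tr_seconds)
  ny <- 1 / (2 * tr_seconds)
  tot_hi <- min(total[2L], ny * 0.999)
  bf <- signal::butter(butter_order, pmin(band, ny * 0.99) / ny, type = "pass")
  z <- exp(-1i * 2 * pi * freqs * tr_seconds)
  h <- vapply(z, function(zz)
    sum(bf$b * zz^(0:(length(bf$b) - 1L))) /
      sum(bf$a * zz^(0:(length(bf$a) - 1L))), complex(1))
  pl <- Mod(h)^4                       # filtfilt applies |H|^2 in amplitude
  pl <- pl / sum(pl)
  pw <- rep(1 / length(freqs), length(freqs))
  list(freqs = freqs,
       pl = pl, pw = pw,
       in_low = freqs >= low[1L] & freqs <= low[2L],
       in_tot = freqs >= total[1L] & freqs <= tot_hi)
}

# solve the low-band mixing weight for a target fALFF; clamps to the
# achievable range of the mixture
solve_falff_weight <- function(target, prof, tol = 0.05) {
  if (target < -tol || target > 1 + tol)
    stop("infeasible fALFF target ", signif(target, 4))
  f0 <- falff_mix_curve(0, prof$pl, prof$pw, prof$in_low, prof$in_tot)
  f1 <- falff_mix_curve(1, prof$pl, prof$pw, prof$in_low, prof$in_tot)
  if (target <= f0) return(0)
  if (target >= f1) return(1)
  stats::uniroot(function(w)
    falff_mix_curve(w, prof$pl, prof$pw, prof$in_low, prof$in_tot) - target,
    c(0, 1), tol = 1e-7)$root
}

#' Generate a synthetic cohort
#'
#' For subject i with age a_i the target Fisher-z matrix is
#' Z_i = B + (a_i - a_mid) A + (a_i - a_mid)^2 C + E_i, where B is the
#' block baseline, A the planted linear age pattern, C the planted
#' quadratic pattern, a_mid the midpoint of `age_range`, and E_i symmetric
#' Gaussian noise. Z_i is mapped to correlations by the inverse Fisher
#' transform and projected to the nearest positive-semidefinite
#' correlation matrix. Node time series mix an independent low-band
#' (0.01-0.1 Hz) component with a cross-node-correlated broadband
#' component; the mixing weight per node and subject is solved so the
#' expected fALFF equals the planted target, and the broadband correlation
#' is boosted to offset the dilution by the independent low-band part so
#' empirical correlations converge to the target matrix.
#'
#' @param config A [generator_config()].
#' @return A list of class `subject_cohort` with `time_series` (list of
#'   node x time matrices), `metadata` (subject_id, age, sex, fd, tiv,
#'   cohort), `partition`, `tr_seconds` and `ground_truth` (B, A,
#'   quadratic pattern C, age midpoint, fALFF targets).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  p <- config$n_nodes
  n <- config$n_subjects
  nt <- config$n_volumes
  part <- config$partition
  amid <- mean(config$age_range)

  # ground-truth patterns
  same_net <- outer(part$network, part$network, "==")
  B <- ifelse(same_net, config$baseline_within_z, config$baseline_between_z)
  diag(B) <- 1
  A <- edge_table_matrix(config$age_slope_map, p, "slope")
  C <- edge_table_matrix(config$quadratic_edge_set, p, "curv")

  # metadata
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  sex <- stats::rbinom(n, 1L, 0.5)
  zage <- as.numeric(scale(age))
  fd <- exp(-1.8 + 0.25 * (0.2 * zage + sqrt(1 - 0.04) * stats::rnorm(n)))
  tiv <- stats::rnorm(n, 1400, 110) + 140 * sex
  ids <- sprintf("%s-%03d", config$cohort_label, seq_len(n))
  meta <- data.frame(subject_id = ids, age = age, sex = sex, fd = fd,
                     tiv = tiv, cohort = config$cohort_label,
                     stringsAsFactors = FALSE)

  prof <- falff_band_profiles(nt, config$tr_seconds)
  quad_node <- seq_len(p) %in% config$falff_quadratic_nodes
  bf <- signal::butter(4, pmin(c(0.01, 0.1), 0.99 / (2 * config$tr_seconds)) /
                         (1 / (2 * config$tr_seconds)), type = "pass")

  falff_targets <- matrix(NA_real_, p, n)
  target_edges <- matrix(NA_real_, p * (p - 1L) / 2L, n)
  series <- vector("list", n)
  for (s in seq_len(n)) {
    da <- age[s] - amid
    Zt <- B + da * A + da^2 * C
    if (config$noise_sd_z > 0) {
      E <- matrix(stats::rnorm(p * p, 0, config$noise_sd_z), p, p)
      E <- (E + t(E)) / sqrt(2)
      diag(E) <- 0
      Zt <- Zt + E
    }
    target_edges[, s] <- vectorize_matrix(Zt)
    Rt <- fisher_z_inv(Zt)
    diag(Rt) <- 1
    Rt <- nearest_psd_correlation(Rt)

    tgt <- config$falff_base + config$falff_age_slope * da
    tgt[quad_node] <- tgt[quad_node] + config$falff_quadratic_curv * da^2
    if (config$falff_noise_sd > 0)
      tgt <- tgt + stats::rnorm(p, 0, config$falff_noise_sd)
    tgt <- pmin(pmax(tgt, 1e-3), 1 - 1e-3)
    falff_targets[, s] <- tgt
    w <- vapply(tgt, solve_falff_weight, 0, prof = prof)

    # broadband correlation boosted to offset low-band dilution
    boost <- 1 / sqrt(1 - w)
    Rbb <- Rt * tcrossprod(boost)
    Rbb[Rbb > 0.97] <- 0.97
    Rbb[Rbb < -0.97] <- -0.97
    diag(Rbb) <- 1
    Rbb <- nearest_psd_correlation(Rbb)
    ev <- eigen(Rbb, symmetric = TRUE)
    fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)

    bb <- fac %*% matrix(stats::rnorm(p * nt), p, nt)
    bb <- bb / apply(bb, 1L, stats::sd)
    lw <- t(apply(matrix(stats::rnorm(p * nt), p, nt), 1L, function(x)
      as.numeric(signal::filtfilt(bf, x))))
    lw <- lw / apply(lw, 1L, stats::sd)
    S <- sqrt(w) * lw + sqrt(1 - w) * bb
    rownames(S) <- sprintf("node%03d", seq_len(p))
    series[[s]] <- S
  }
  names(series) <- ids
  structure(list(time_series = series, metadata = meta, partition = part,
                 tr_seconds = config$tr_seconds,
                 ground_truth = list(B = B, A = A, C = C, age_mid = amid,
                                     target_edges = target_edges,
                                     falff_targets = falff_targets,
                                     falff_age_slope = config$falff_age_slope,
                                     falff_quadratic_nodes =
                                       config$falff_quadratic_nodes),
                 config = config),
            class = "subject_cohort")
}

#' Target Fisher-z matrix for one subject (without the noise draw)
#'
#' @param cohort A `subject_cohort`.
#' @param i Subject index.
#' @return The noiseless planted z-matrix B + da A + da^2 C (unit diagonal).
#' @export
target_z_matrix <- function(cohort, i) {
  gt <- cohort$ground_truth
  da <- cohort$metadata$age[i] - gt$age_mid
  Z <- gt$B + da * gt$A + da^2 * gt$C
  diag(Z) <- 1
  Z
}

#' Generate paired internal/external cohorts sharing ground truth
#'
#' @param config_internal,config_external [generator_config()] objects
#'   with identical node counts and partitions.
#' @param shared_truth If `TRUE` (default) the external cohort inherits
#'   the internal baseline, age-pattern and fALFF-trend fields so both
#'   cohorts share B, A and C.
#' @return List with elements `internal` and `external`.
#' @export
generate_paired_cohorts <- function(config_internal, config_external,
                                    shared_truth = TRUE) {
  if (config_internal$n_nodes != config_external$n_nodes)
    stop("internal and external configs must share n_nodes")
  if (!identical(config_internal$partition, config_external$partition))
    stop("internal and external configs must share the node partition")
  if (shared_truth) {
    for (f in c("baseline_within_z", "baseline_between_z", "age_slope_map",
                "quadratic_edge_set", "falff_base", "falff_age_slope",
                "falff_quadratic_nodes", "falff_quadratic_curv",
                "falff_noise_sd"))
      config_external[[f]] <- config_internal[[f]]
  }
  list(internal = generate_cohort(config_internal),
       external = generate_cohort(config_external))
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes one TSV per subject (nodes x volumes, a `# tr_seconds` header
#' line), `metadata.csv`, `partition.tsv` and ground-truth matrices.
#'
#' @param cohort A `subject_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$time_series)) {
    f <- file.path(dir, paste0(id, ".tsv"))
    con <- file(f, "w")
    writeLines(sprintf("# tr_seconds=%g", cohort$tr_seconds), con)
    utils::write.table(cohort$time_series[[id]], con, sep = "\t",
                       col.names = FALSE, row.names = TRUE, quote = FALSE)
    close(con)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$partition, file.path(dir, "partition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in c("B", "A", "C"))
    utils::write.table(cohort$ground_truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `metadata.csv`, `partition.tsv` and
#'   per-subject TSV files.
#' @return A `subject_cohort` (without ground truth unless present).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  part <- utils::read.table(file.path(dir, "partition.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  tr <- NA_real_
  series <- lapply(meta$subject_id, function(id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    hdr <- readLines(f, n = 1L)
    tr <<- as.numeric(sub("# tr_seconds=", "", hdr))
    m <- utils::read.table(f, sep = "\t", skip = 1L, row.names = 1L)
    as.matrix(m)
  })
  names(series) <- meta$subject_id
  gt <- NULL
  if (file.exists(file.path(dir, "truth_B.tsv"))) {
    gt <- lapply(c(B = "B", A = "A", C = "C"), function(nm)
      as.matrix(utils::read.table(file.path(dir, paste0("truth_", nm, ".tsv")),
                                  sep = "\t")))
  }
  structure(list(time_series = series, metadata = meta, partition = part,
                 tr_seconds = tr, ground_truth = gt),
            class = "subject_cohort")
}
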