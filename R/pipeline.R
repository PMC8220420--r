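#' Analyse a synthetic or measured kinetics dataset
#'
#' The full work-up behind the published rate tables: per association
#' concentration, replicates are normalized and averaged and the mean
#' trace is fitted with the requested number of exponential phases (or the
#' phase count chosen by [select_phase_count()]); apparent rates are
#' regressed against concentration per cassette phase; chase replicates
#' are averaged and fitted to yield dissociation rate constants, which are
#' authoritative over the titration intercepts.
#'
#' @param dataset A `kinetics_dataset` from [generate_kinetics_dataset()].
#' @param n_phases Number of exponential phases (default: the number of
#'   binding sites in the generating design; `"auto"` runs phase
#'   selection on the mean trace of the highest concentration).
#' @param calibration Optional isolated-cassette calibration table for
#'   phase-assignment validation ([brr2_rate_constants()] rows).
#' @return A list of class `kinetics_analysis`: `rates` (a
#'   [rate_constant_set()] with regression slopes/intercepts and
#'   chase-derived `k_minus1`), `titrations` (per cassette), `regressions`,
#'   `chase_fit`, `phase_selection` (when `n_phases = "auto"`).
#' @export
analyze_kinetics_dataset <- function(dataset, n_phases = NULL,
                                     calibration = NULL) {
  stopifnot(inherits(dataset, "kinetics_dataset"))
  design <- dataset$design
  n_sites <- length(design$sites)
  selection <- NULL
  if (is.null(n_phases)) n_phases <- n_sites
  if (identical(n_phases, "auto")) {
    top <- normalize_and_average(dataset$association[[length(dataset$association)]])
    selection <- select_phase_count(top)
    n_phases <- selection$n_phases
  }

  concs <- as.numeric(names(dataset$association))
  cass <- if (n_phases == 2L) c("NC", "CC") else design$rates$cassette[1]
  kapp <- matrix(NA_real_, length(concs), n_phases,
                 dimnames = list(NULL, cass))
  for (ci in seq_along(concs)) {
    avg <- normalize_and_average(dataset$association[[ci]])
    fit <- fit_exponentials(avg, n_phases)
    if (!fit$converged)
      warning(sprintf("association fit at %g uM flagged: %s",
                      concs[ci], paste(fit$flags, collapse = "; ")))
    if (n_phases == 2L) {
      asg <- assign_phases(fit, calibration)
      kapp[ci, asg$cassette] <- asg$k_app
    } else {
      kapp[ci, 1] <- fit$k_app[1]
    }
  }
  titrations <- list(); regressions <- list()
  for (cs in cass) {
    ser <- titration_series(concs, kapp[, cs], phase_label = cs)
    titrations[[cs]] <- ser
    regressions[[cs]] <- regress_kapp(ser)
  }

  chase_avg <- normalize_and_average(dataset$chase)
  chase_fit <- fit_exponentials(chase_avg, n_phases)
  chase_koff <- stats::setNames(rep(NA_real_, length(cass)), cass)
  chase_koff_se <- chase_koff
  if (chase_fit$converged) {
    if (n_phases == 2L) {
      # fast phase = NC, slow = CC (k_app already sorted fast -> slow)
      chase_koff[c("NC", "CC")] <- chase_fit$k_app
      chase_koff_se[c("NC", "CC")] <- chase_fit$param_se$k_app
    } else {
      chase_koff[1] <- chase_fit$k_app[1]
      chase_koff_se[1] <- chase_fit$param_se$k_app[1]
    }
  }

  rates <- do.call(rbind, lapply(cass, function(cs) {
    rate_constant_set(design$construct, design$nucleotide, cs,
                      k1 = regressions[[cs]]$k1,
                      k1_se = regressions[[cs]]$k1_se,
                      k_minus1 = chase_koff[[cs]],
                      k_minus1_se = chase_koff_se[[cs]],
                      provenance = "chase+regression")
  }))
  class(rates) <- c("rate_constant_set", "data.frame")
  structure(list(rates = rates, titrations = titrations,
                 regressions = regressions, chase_fit = chase_fit,
                 intercepts = vapply(regressions, `[[`, numeric(1), "k_minus1"),
                 phase_selection = selection),
            class = "kinetics_analysis")
}

#' @export
print.kinetics_analysis <- function(x, ...) {
  cat("<kinetics_analysis>\n")
  print(x$rates)
  invisible(x)
}

#' Seeded parameter-recovery experiment
#'
#' Repeats the simulate-then-analyse round trip over many seeds and
#' reports the median recovered rate constants: the regression slope `k1`
#' per cassette and the chase-derived `k_minus1` per cassette. This is the
#' package's yardstick for whether the experimental design can recover the
#' generating (published) constants.
#'
#' @param design A [kinetics_design()]; its `seed` field is replaced per
#'   repeat.
#' @param n_seeds Number of independent synthetic datasets (default 50).
#' @param base_seed Offset added to `1:n_seeds` to derive per-repeat seeds.
#' @param what `"both"`, `"association"` (skip chase fits) or `"chase"`
#'   (skip titrations; much faster for slow-release designs).
#' @return A list of class `recovery_result`: `k1` and `k_minus1` (named
#'   medians per cassette), `per_seed` (long data frame), `truth`.
#' @export
recover_rate_constants <- function(design, n_seeds = 50, base_seed = 0L,
                                   what = c("both", "association", "chase")) {
  stopifnot(inherits(design, "kinetics_design"))
  what <- match.arg(what)
  n_sites <- length(design$sites)
  cass <- if (n_sites == 2L) c("NC", "CC") else design$rates$cassette[1]
  rows <- list()
  for (s in seq_len(n_seeds)) {
    d <- design
    d$seed <- as.integer(base_seed + s)
    dataset <- generate_kinetics_dataset(d)
    if (what %in% c("both", "association")) {
      an <- analyze_association_only(dataset)
      for (cs in cass) {
        rows[[length(rows) + 1L]] <-
          data.frame(seed = d$seed, cassette = cs, quantity = "k1",
                     value = an[[cs]]$k1)
      }
    }
    if (what %in% c("both", "chase")) {
      ch <- analyze_chase_only(dataset)
      for (cs in cass) {
        rows[[length(rows) + 1L]] <-
          data.frame(seed = d$seed, cassette = cs, quantity = "k_minus1",
                     value = ch[[cs]])
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  med <- function(q) {
    out <- sapply(cass, function(cs) {
      v <- per_seed$value[per_seed$cassette == cs & per_seed$quantity == q]
      if (length(v)) stats::median(v, na.rm = TRUE) else NA_real_
    })
    stats::setNames(as.numeric(out), cass)
  }
  structure(list(k1 = med("k1"), k_minus1 = med("k_minus1"),
                 per_seed = per_seed, truth = design$rates,
                 n_seeds = n_seeds),
            class = "recovery_result")
}

# Titration-only work-up (association traces -> per-cassette regressions).
analyze_association_only <- function(dataset) {
  design <- dataset$design
  n_phases <- length(design$sites)
  concs <- as.numeric(names(dataset$association))
  cass <- if (n_phases == 2L) c("NC", "CC") else design$rates$cassette[1]
  kapp <- matrix(NA_real_, length(concs), n_phases,
                 dimnames = list(NULL, cass))
  for (ci in seq_along(concs)) {
    avg <- normalize_and_average(dataset$association[[ci]])
    fit <- fit_exponentials(avg, n_phases)
    if (n_phases == 2L) {
      asg <- assign_phases(fit)
      kapp[ci, asg$cassette] <- asg$k_app
    } else {
      kapp[ci, 1] <- fit$k_app[1]
    }
  }
  out <- list()
  for (cs in cass) {
    out[[cs]] <- regress_kapp(titration_series(concs, kapp[, cs],
                                               phase_label = cs))
  }
  out
}

# Chase-only work-up (average replicates, fit, k_off per cassette).
analyze_chase_only <- function(dataset) {
  design <- dataset$design
  n_phases <- length(design$sites)
  cass <- if (n_phases == 2L) c("NC", "CC") else design$rates$cassette[1]
  avg <- normalize_and_average(dataset$chase)
  fit <- fit_exponentials(avg, n_phases)
  koff <- stats::setNames(rep(NA_real_, length(cass)), cass)
  if (fit$converged) koff[seq_len(n_phases)] <- fit$k_app
  as.list(koff)
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d seeds\n", x$n_seeds))
  if (any(is.finite(x$k1)))
    cat("  median k1      :", paste(names(x$k1), signif(x$k1, 4),
                                    sep = "=", collapse = ", "), "/uM/s\n")
  if (any(is.finite(x$k_minus1)))
    cat("  median k_minus1:", paste(names(x$k_minus1), signif(x$k_minus1, 4),
                                    sep = "=", collapse = ", "), "/s\n")
  invisible(x)
}

# ---- configuration-driven runs -------------------------------------------

validate_config <- function(config, allowed, required = character(0)) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  config
}

#' Run the kinetics pipeline from a configuration
#'
#' End-to-end reproducible run: generate (or load) the dataset, average,
#' fit, assign phases, regress, and derive the affinity/fold table. Every
#' stage's output is returned, and persisted as delimited text plus a JSON
#' manifest when `out_dir` is given.
#'
#' @param config Named list (or path to a JSON file) with keys:
#'   `construct`, `nucleotide` (required), `protein_conc`, `conc_series`,
#'   `replicates`, `noise`, `n_points`, `seed`, `n_phases`.
#' @param out_dir Optional output directory.
#' @return A list of class `kinetics_run`: `analysis`
#'   ([analyze_kinetics_dataset()] result), `affinity`
#'   ([derive_affinity_table()] result), `config`.
#' @export
run_kinetics <- function(config, out_dir = NULL) {
  config <- validate_config(config,
    allowed = c("construct", "nucleotide", "protein_conc", "conc_series",
                "replicates", "noise", "n_points", "seed", "n_phases"),
    required = c("construct", "nucleotide"))
  args <- config[intersect(names(config),
                           c("construct", "nucleotide", "protein_conc",
                             "conc_series", "replicates", "noise",
                             "n_points", "seed"))]
  design <- do.call(kinetics_design, args)
  dataset <- generate_kinetics_dataset(design)
  analysis <- analyze_kinetics_dataset(dataset,
                                       n_phases = config$n_phases)
  affinity <- derive_affinity_table(analysis$rates)
  out <- structure(list(analysis = analysis, affinity = affinity,
                        config = config),
                   class = "kinetics_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(analysis$rates, file.path(out_dir, "rate_constants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(affinity$affinities, file.path(out_dir, "affinities.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(affinity$folds, file.path(out_dir, "folds.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(config = config, seed = design$seed),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the allosteric-communication pipeline from a configuration
#'
#' Builds the communication graph from an occupancy matrix (given
#' directly, read from a triplet table, computed from a trajectory, or
#' generated from a synthetic network design), extracts the k-shortest
#' paths per endpoint pair and computes participation, interface-crossing
#' and path-length outputs; flexibility outputs (RMSF, correlation, pocket
#' widths) are added when a trajectory is available.
#'
#' @param config Named list (or JSON path) with keys: one of
#'   `matrix`/`matrix_path`/`trajectory`/`network` (a [network_design()]
#'   argument list), plus `adjacency` (required with `matrix`),
#'   `endpoints` (list of length-2 residue-id pairs; required unless
#'   `network` supplies them), `k` (default 10), `criterion` (list with
#'   `d_max`, `theta_max`), `partition_boundary` or `partition_chains`,
#'   `n_blocks`, `seed`.
#' @param out_dir Optional output directory.
#' @return A list of class `allostery_run`: `graph`, `paths` (per
#'   endpoint pair), `participation`, `crossings`, `path_stats`,
#'   `flexibility` (or `NULL`), `config`.
#' @export
run_allostery <- function(config, out_dir = NULL) {
  config <- validate_config(config,
    allowed = c("matrix", "matrix_path", "trajectory", "network",
                "adjacency", "endpoints", "k", "criterion",
                "partition_boundary", "partition_chains", "n_blocks",
                "seed"))
  k <- config$k %||% 10
  crit <- if (is.null(config$criterion)) hbond_criterion() else
    do.call(hbond_criterion, config$criterion)

  flexibility <- NULL
  truth <- NULL
  if (!is.null(config$network)) {
    net_args <- config$network
    if (!is.null(config$seed)) net_args$seed <- config$seed
    design <- do.call(network_design, net_args)
    net <- generate_occupancy_network(design)
    mat <- net$matrix; adjacency <- net$adjacency
    partition <- net$partition
    endpoints <- config$endpoints %||% list(net$truth$endpoints)
    truth <- net$truth
  } else if (!is.null(config$trajectory)) {
    traj <- config$trajectory
    stopifnot(inherits(traj, "trajectory"))
    mat <- occupancy_matrix(traj, crit)
    adjacency <- covalent_adjacency(traj$topology)
    partition <- NULL
    endpoints <- config$endpoints
    aligned <- superpose(traj)
    n_blocks <- config$n_blocks %||% 5
    flexibility <- list(rmsf = rmsf(aligned, n_blocks = n_blocks),
                        correlation = cross_correlation(aligned))
  } else if (!is.null(config$matrix_path)) {
    mat <- read_hbond_matrix(config$matrix_path)
    adjacency <- config$adjacency
    partition <- NULL
    endpoints <- config$endpoints
  } else if (!is.null(config$matrix)) {
    mat <- config$matrix
    adjacency <- config$adjacency
    partition <- NULL
    endpoints <- config$endpoints
  } else {
    stop("config must provide one of 'matrix', 'matrix_path', 'trajectory', 'network'")
  }
  if (is.null(adjacency)) stop("covalent adjacency is required")
  if (is.null(endpoints)) stop("endpoint residue pairs are required")
  if (is.null(partition)) {
    if (!is.null(config$partition_chains)) {
      partition <- cassette_partition(mat$residues,
                                      by_chain = unlist(config$partition_chains))
    } else {
      partition <- cassette_partition(mat$residues,
                                      boundary = config$partition_boundary %||% 1282)
    }
  }

  graph <- build_graph(mat, adjacency)
  paths <- list(); crossings <- list()
  for (ep in endpoints) {
    miss <- setdiff(ep, graph$nodes)
    if (length(miss))
      stop("endpoint residue(s) not resolvable in the graph: ",
           paste(miss, collapse = ", "))
    key <- paste(ep, collapse = "-")
    ps <- k_shortest_paths(graph, ep[1], ep[2], k = k)
    paths[[key]] <- ps
    crossings[[key]] <- if (length(ps)) interface_crossings(ps, partition)
                        else NULL
  }
  participation <- lapply(paths, function(ps) {
    if (length(ps)) participation_frequency(ps) else numeric(0)
  })
  path_stats <- lapply(paths, function(ps) path_length_statistics(list(ps)))

  out <- structure(list(graph = graph, matrix = mat, paths = paths,
                        participation = participation,
                        crossings = crossings, path_stats = path_stats,
                        flexibility = flexibility, truth = truth,
                        config = config),
                   class = "allostery_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_comm_graph(graph, file.path(out_dir, "graph_edges.tsv"))
    write_hbond_matrix(mat, file.path(out_dir, "occupancy.tsv"))
    path_records <- lapply(paths, function(ps) lapply(ps, unclass))
    jsonlite::write_json(path_records, file.path(out_dir, "paths.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
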