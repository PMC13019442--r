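#' Run the estimator from a configuration
#'
#' Orchestrates a complete run from a configuration list or YAML file:
#' resolves the inputs (either a built-in toy system or
#' topology/trajectory files), executes the three-leg pipeline, and
#' optionally writes a JSON report. All defaults follow the method's
#' standard protocol: 2 kcal/mol clash threshold, `n_target = 1e9`
#' combinatorial pairs, `n_s = 5000` subsampling, 300 K.
#'
#' @param config A list or path to a YAML file. Recognized fields:
#'   `system` (either `list(kind = "toy", preset = <site kind>, ...)` with
#'   [make_harmonic_host_guest()] arguments, or
#'   `list(kind = "files", receptor, ligand, complex, receptor_traj,
#'   ligand_traj, complex_traj, receptor_atom_count)`),
#'   `pocket_atoms`, `temperature`, `energy_threshold`, `n_target`, `n_s`,
#'   `n_receptor_max`, `n_ligand_max`, `min_burn_in`, `decorrelate`,
#'   `sigma_scale`, `seed`, `n_frames` (toy sampling size), and `output`
#'   (report path).
#' @param backend Energy backend for file-based systems; toy systems build
#'   their own.
#' @return The `"dbfe"` fit (invisibly returns the report path as
#'   attribute `"report"` when one was written).
#' @export
dbfe_run <- function(config, backend = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  defaults <- list(temperature = 300, energy_threshold = 2, n_target = 1e9,
                   n_s = 5000, n_receptor_max = 400, n_ligand_max = 400,
                   min_burn_in = 0, decorrelate = TRUE, sigma_scale = 1,
                   n_frames = 2000, pocket_atoms = NULL)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(2^31 - 1, 1)   # recorded in the report
  }
  sys <- cfg$system
  if (is.null(sys$kind)) stop_dbfe("parameter", "config$system$kind is required")
  if (sys$kind == "toy") {
    args <- sys[setdiff(names(sys), c("kind", "preset"))]
    if (!is.null(sys$preset)) args$kind <- sys$preset
    if (is.null(args$seed)) args$seed <- cfg$seed
    spec <- do.call(make_harmonic_host_guest, args)
    backend <- make_toy_backend(spec)
    receptor <- direct_boltzmann_sample(spec, "receptor", cfg$n_frames,
                                        seed = derive_seed(cfg$seed, 101))
    ligand <- direct_boltzmann_sample(spec, "ligand", cfg$n_frames,
                                      seed = derive_seed(cfg$seed, 102))
    complex <- direct_boltzmann_sample(spec, "complex", cfg$n_frames,
                                       seed = derive_seed(cfg$seed, 103))
  } else if (sys$kind == "files") {
    if (is.null(backend)) {
      stop_dbfe("parameter", "file-based systems require an energy backend")
    }
    rtop <- read_topology(sys$receptor, "receptor", lj = sys$receptor_lj)
    ltop <- read_topology(sys$ligand, "ligand", lj = sys$ligand_lj)
    ctop <- read_topology(sys$complex, "complex", lj = sys$complex_lj,
                          receptor_atom_count = sys$receptor_atom_count)
    receptor <- read_trajectory(unlist(sys$receptor_traj), rtop)
    ligand <- read_trajectory(unlist(sys$ligand_traj), ltop)
    complex <- read_trajectory(unlist(sys$complex_traj), ctop)
  } else {
    stop_dbfe("parameter", sprintf("unknown system kind '%s'", sys$kind))
  }
  fit <- dbfe(receptor, ligand, complex, backend,
              pocket_atoms = cfg$pocket_atoms,
              temperature = cfg$temperature,
              energy_threshold = cfg$energy_threshold,
              n_target = cfg$n_target, n_s = cfg$n_s,
              n_receptor_max = cfg$n_receptor_max,
              n_ligand_max = cfg$n_ligand_max,
              min_burn_in = cfg$min_burn_in, decorrelate = cfg$decorrelate,
              sigma_scale = cfg$sigma_scale,
              seed = cfg$seed, verbose = isTRUE(cfg$verbose))
  fit$config$system <- sys
  if (sys$kind == "toy") {
    fit$exact_delta_g <- exact_delta_g_quadrature(spec)
  }
  if (!is.null(cfg$output)) {
    dbfe_report(fit, cfg$output)
    attr(fit, "report") <- cfg$output
  }
  fit
}

#' Write a fitted estimate as a JSON report
#'
#' The report carries the per-leg values and errors, diagnostics, the
#' configuration echo, the software version, and the seed. Reports are
#' byte-reproducible for identical configurations and seeds (no timestamp
#' unless requested).
#'
#' @param fit A `"dbfe"` fit.
#' @param path Output path, or `NULL` to return the JSON string.
#' @param include_timestamp Add a wall-clock timestamp field (default
#'   FALSE, keeping reports byte-identical across reruns).
#' @return `path` invisibly, or the JSON string.
#' @export
dbfe_report <- function(fit, path = NULL, include_timestamp = FALSE) {
  diag <- fit$diagnostics
  diag$elapsed_s <- NULL   # timing is not part of the reproducible payload
  doc <- list(
    tool = "dbfe",
    version = as.character(utils::packageVersion("dbfe")),
    seed = fit$seed,
    legs = list(dg_release = fit$dg_release, dg_filter = fit$dg_filter,
                dg_mbar = fit$dg_mbar),
    dg_total = fit$dg_total,
    se = list(se_release = fit$se_release, se_filter = fit$se_filter,
              se_mbar = fit$se_mbar, se_total = fit$se_total),
    diagnostics = diag,
    restraint = jsonlite::fromJSON(restraint_to_json(fit$restraint),
                                   simplifyVector = TRUE),
    config = fit$config)
  if (!is.null(fit$exact_delta_g)) doc$exact_delta_g <- fit$exact_delta_g
  if (include_timestamp) doc$timestamp <- format(Sys.time(), tz = "UTC")
  validate_report(doc)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(js, path)
  invisible(path)
}

#' Multi-pose runs with Boltzmann combination
#'
#' Runs the estimator for several binding poses (one configuration each)
#' and combines the per-pose free energies by Boltzmann weighting. Poses
#' that fail structurally (e.g. no clash-free samples because the site
#' closed) are excluded from the combination and reported with the reason,
#' rather than imputed.
#'
#' @param configs List of configurations (see [dbfe_run()]) or of already
#'   fitted `"dbfe"` objects.
#' @param temperature Kelvin for the combination (default 300).
#' @param backend Optional backend shared by file-based configs.
#' @return List with `combined_dg` (kcal/mol), `poses` (per-pose fits or
#'   `NULL`), `per_pose_dg`, and `excluded` (named reasons).
#' @export
dbfe_multipose <- function(configs, temperature = 300, backend = NULL) {
  fits <- vector("list", length(configs))
  excluded <- list()
  for (i in seq_along(configs)) {
    ci <- configs[[i]]
    res <- if (inherits(ci, "dbfe")) ci else {
      tryCatch(dbfe_run(ci, backend = backend),
               dbfe_error = function(e) e)
    }
    if (inherits(res, "dbfe")) {
      fits[[i]] <- res
    } else {
      excluded[[paste0("pose", i)]] <- conditionMessage(res)
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop_dbfe("no_overlap", "every pose failed; nothing to combine")
  }
  dgs <- vapply(fits[ok], function(f) f$dg_total, numeric(1))
  list(combined_dg = combine_poses(dgs, temperature),
       poses = fits, per_pose_dg = dgs, excluded = excluded)
}

#' Validate a run report against the package's schema contract
#'
#' Structural validation of a report (as an R list or a JSON file path)
#' against the contract published in `inst/schema/report.schema.json`:
#' required fields present, legs and errors numeric and finite, counts
#' positive, and `alpha`/`overlap` within the unit interval.
#'
#' @param report A report list (as built by [dbfe_report()]) or a path to
#'   a report JSON file.
#' @return `TRUE` invisibly; a `dbfe_report_error` otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  need <- c("tool", "version", "seed", "legs", "dg_total", "se",
            "diagnostics", "restraint", "config")
  miss <- setdiff(need, names(report))
  if (length(miss)) {
    stop_dbfe("report", sprintf("report is missing field(s): %s",
                                paste(miss, collapse = ", ")))
  }
  num_ok <- function(x, k = 1) {
    v <- unlist(x)
    length(v) == k && is.numeric(v) && all(is.finite(v))
  }
  if (!identical(report$tool, "dbfe")) stop_dbfe("report", "tool field must be 'dbfe'")
  leg_names <- c("dg_release", "dg_filter", "dg_mbar")
  if (!all(leg_names %in% names(report$legs)) ||
      !num_ok(report$legs[leg_names], 3) || !num_ok(report$dg_total)) {
    stop_dbfe("report", "legs and dg_total must be finite numbers")
  }
  se_names <- c("se_release", "se_filter", "se_mbar", "se_total")
  if (!all(se_names %in% names(report$se)) || !num_ok(report$se[se_names], 4)) {
    stop_dbfe("report", "standard errors must be finite numbers")
  }
  d <- report$diagnostics
  if (is.null(d$alpha) || d$alpha < 0 || d$alpha > 1 ||
      is.null(d$overlap) || d$overlap < 0 || d$overlap > 1 ||
      is.null(d$n_p) || d$n_p < 1 || is.null(d$n_tested) || d$n_tested < 1) {
    stop_dbfe("report", "diagnostics out of range")
  }
  r <- report$restraint
  if (length(unlist(r$mu)) != 3 || length(unlist(r$Z)) != 4) {
    stop_dbfe("report", "restraint block malformed")
  }
  invisible(TRUE)
}
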