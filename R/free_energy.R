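#' Evaluate both end-state reduced potentials on both sample sets
#'
#' Builds the 2 x N reduced-potential matrix for the final MBAR leg. The
#' two states are the restrained, clash-conditioned decoupled state
#' `u_rc = beta * (U_P + U_L + U_zeta)` (with `+Inf` outside the clash-free
#' region) and the coupled state `u_1 = beta * U_PL` (the physical complex,
#' no restraint: the restraint enters the cycle through the analytic
#' release leg only, so the three legs telescope exactly). Each sample set
#' is subsampled to at most `n_s` frames before any energy call.
#'
#' @param complex_ensemble `"trajectory_ensemble"` of complex frames
#'   (samples of the coupled state).
#' @param decoupled_samples List of composed clash-free samples, each a
#'   list with `receptor` (P x 3), `ligand` (L x 3, in the receptor
#'   frame's coordinates), and `zeta` (`"rigid_transform"`), as produced by
#'   the pose-composition step of [dbfe()].
#' @param backend An energy backend (see [make_toy_backend()]): a list with
#'   `evaluate(topology, coords)` returning kcal/mol.
#' @param restraint A `"dbfe_restraint"`.
#' @param geometry List with `reference_coords` (complex reference frame),
#'   `pocket_atoms`, `ligand_atoms`, and optionally `symmetry`, used to
#'   extract `zeta` for complex frames.
#' @param receptor_topology,ligand_topology Component topologies.
#' @param cutoffs Optional `"cutoff_matrix"`; when given, complex frames
#'   violating a cutoff get `u_rc = +Inf` (the conditional state has no
#'   support there).
#' @param temperature Kelvin (default 300).
#' @param n_s Subsampling cap per sample set (default 5000).
#' @param seed Integer seed for the subsampling.
#' @return Object of class `"reduced_potentials"`: `u` (2 x N, rows
#'   `c("decoupled_rc", "coupled")`), `origin` (per-column label), `n_k`,
#'   `temperature`, and `complex_zetas` (transforms of the retained complex
#'   frames, for diagnostics).
#' @export
evaluate_reduced_potentials <- function(complex_ensemble, decoupled_samples,
                                        backend, restraint, geometry,
                                        receptor_topology, ligand_topology,
                                        cutoffs = NULL, temperature = 300,
                                        n_s = 5000, seed = 1L) {
  if (!length(decoupled_samples)) stop_dbfe("parameter", "no decoupled samples")
  beta <- 1 / (.kB * temperature)
  ctop <- complex_ensemble$topology
  rid <- receptor_indices(ctop); lid <- ligand_indices(ctop)

  dec <- decoupled_samples
  if (length(dec) > n_s) {
    keep <- with_seed(derive_seed(seed, 1), sort(sample.int(length(dec), n_s)))
    dec <- dec[keep]
  }
  cplx <- complex_ensemble
  if (length(cplx$frames) > n_s) {
    cplx <- subsample_frames(cplx, n_s, seed = derive_seed(seed, 2))
  }

  eval_one <- function(top, coords) {
    e <- backend$evaluate(top, coords)
    if (!is.finite(e)) {
      stop_dbfe("energy_evaluation", "backend returned a non-finite energy")
    }
    e
  }

  # decoupled composed samples: clash-free by construction
  u_dec <- vapply(dec, function(s) {
    up <- eval_one(receptor_topology, s$receptor)
    ul <- eval_one(ligand_topology, s$ligand)
    uz <- restraint_energy(s$zeta, restraint, temperature)
    upl <- eval_one(ctop, rbind(s$receptor, s$ligand))
    c(rc = beta * (up + ul + uz), coupled = beta * upl)
  }, numeric(2))

  # complex-trajectory samples
  sym <- geometry$symmetry
  zlist <- lapply(cplx$frames, function(fr) {
    extract_zeta(fr, geometry$reference_coords, geometry$pocket_atoms,
                 geometry$ligand_atoms, sym)
  })
  u_cplx <- vapply(seq_along(cplx$frames), function(i) {
    fr <- cplx$frames[[i]]
    up <- eval_one(receptor_topology, fr[rid, , drop = FALSE])
    ul <- eval_one(ligand_topology, fr[lid, , drop = FALSE])
    upl <- eval_one(ctop, fr)
    uz <- restraint_energy(zlist[[i]], restraint, temperature)
    urc <- beta * (up + ul + uz)
    if (!is.null(cutoffs) &&
        !clash_free_cpp(fr[rid, , drop = FALSE], fr[lid, , drop = FALSE], cutoffs)) {
      urc <- Inf
    }
    c(rc = urc, coupled = beta * upl)
  }, numeric(2))

  u <- cbind(u_dec, u_cplx)
  rownames(u) <- c("decoupled_rc", "coupled")
  structure(list(u = u,
                 origin = c(rep("filtered_decoupled", ncol(u_dec)),
                            rep("complex_traj", ncol(u_cplx))),
                 n_k = c(ncol(u_dec), ncol(u_cplx)),
                 temperature = temperature,
                 complex_zetas = zlist),
            class = "reduced_potentials")
}

# single-structure clash test through the grid filter path
clash_free_cpp <- function(receptor_coords, ligand_coords, cutoffs) {
  as.logical(.clash_filter_poses_cpp(receptor_coords, ligand_coords,
                                     cutoffs$cutoffs, nrow(ligand_coords)))
}

#' @export
print.reduced_potentials <- function(x, ...) {
  cat(sprintf("reduced potentials: 2 states x %d samples (%d decoupled, %d complex)\n",
              ncol(x$u), x$n_k[1], x$n_k[2]))
  invisible(x)
}

#' Assemble the three legs into a total binding free energy
#'
#' Sums the release, filter, and MBAR legs and combines their
#' uncertainties in quadrature (the analytic release leg contributes no
#' statistical error; the filter leg a binomial error; the MBAR leg its
#' asymptotic error).
#'
#' @param dg_release,dg_filter,dg_mbar Leg values (kcal/mol).
#' @param se_filter,se_mbar Leg standard errors (kcal/mol).
#' @param diagnostics Optional list (overlap, sample counts, alpha, ...)
#'   stored on the result.
#' @return Object of class `"dbfe"`; see [dbfe()] for the methods it
#'   supports.
#' @export
assemble_total <- function(dg_release, dg_filter, dg_mbar,
                           se_filter = 0, se_mbar = 0, diagnostics = list()) {
  legs <- c(dg_release = dg_release, dg_filter = dg_filter, dg_mbar = dg_mbar)
  if (any(!is.finite(legs))) {
    stop_dbfe("assembly", "all legs must be finite to assemble a total")
  }
  structure(list(dg_release = dg_release, dg_filter = dg_filter,
                 dg_mbar = dg_mbar,
                 dg_total = dg_release + dg_filter + dg_mbar,
                 se_release = 0, se_filter = se_filter, se_mbar = se_mbar,
                 se_total = sqrt(se_filter^2 + se_mbar^2),
                 diagnostics = diagnostics),
            class = "dbfe")
}

#' Boltzmann combination of per-pose binding free energies
#'
#' Binding through any of several poses:
#' `dG = -kB T * log(sum_i exp(-dG_i / kB T))`, computed with a
#' log-sum-exp guard.
#'
#' @param dgs Numeric vector of per-pose free energies (kcal/mol, >= 1).
#' @param temperature Kelvin (default 300).
#' @return Combined free energy (kcal/mol).
#' @export
combine_poses <- function(dgs, temperature = 300) {
  if (!length(dgs)) stop_dbfe("parameter", "at least one pose is required")
  kT <- .kB * temperature
  x <- -dgs / kT
  m <- max(x)
  -kT * (m + log(sum(exp(x - m))))
}

#' End-state interaction-energy baseline (MM/GBSA-style)
#'
#' The single-trajectory end-state baseline: the mean over complex frames
#' of `U_PL(x) - U_P(x_P) - U_L(x_L)`, with the components extracted from
#' each complex frame and evaluated with the same (implicit-solvent)
#' backend. No conformational-entropy correction is applied, which is the
#' defining contrast with the full estimator.
#'
#' @param complex_ensemble `"trajectory_ensemble"` of complex frames.
#' @param backend Energy backend.
#' @return Mean interaction energy (kcal/mol).
#' @export
mmgbsa_baseline <- function(complex_ensemble, backend) {
  ctop <- complex_ensemble$topology
  rid <- receptor_indices(ctop); lid <- ligand_indices(ctop)
  rtop <- subset_topology(ctop, rid, role = "receptor")
  ltop <- subset_topology(ctop, lid, role = "ligand")
  vals <- vapply(complex_ensemble$frames, function(fr) {
    e <- backend$evaluate(ctop, fr) -
      backend$evaluate(rtop, fr[rid, , drop = FALSE]) -
      backend$evaluate(ltop, fr[lid, , drop = FALSE])
    if (!is.finite(e)) stop_dbfe("energy_evaluation", "backend returned a non-finite energy")
    e
  }, numeric(1))
  mean(vals)
}

# component topology of a complex (bonds reindexed into the subset)
subset_topology <- function(topology, idx, role) {
  keep <- topology$bonds[, 1] %in% idx & topology$bonds[, 2] %in% idx
  bonds <- topology$bonds[keep, , drop = FALSE]
  remap <- match(bonds, idx)
  bonds <- matrix(remap, ncol = 2)
  dbfe_topology(topology$atom_names[idx], topology$elements[idx],
                topology$lj_sigma[idx], topology$lj_epsilon[idx],
                bonds = bonds, role = role)
}

#' Bootstrap benchmark metrics for predicted vs experimental values
#'
#' RMSE, Pearson r, and Spearman rho with percentile bootstrap confidence
#' intervals over paired resamples.
#'
#' @param predicted,experimental Equal-length numeric vectors (n >= 3).
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List of `rmse`, `pearson_r`, `spearman_rho`, each a list with
#'   `estimate`, `lower`, `upper`. Correlations are `NA` (with a
#'   `note`) when either vector is constant.
#' @export
bootstrap_metrics <- function(predicted, experimental, n_resamples = 1000,
                              seed = 1L, conf = 0.95) {
  n <- length(predicted)
  if (n != length(experimental) || n < 3) {
    stop_dbfe("parameter", "need equal-length vectors with n >= 3")
  }
  metric <- function(p, e) {
    const <- stats::sd(p) == 0 || stats::sd(e) == 0
    c(rmse = sqrt(mean((p - e)^2)),
      pearson_r = if (const) NA_real_ else stats::cor(p, e),
      spearman_rho = if (const) NA_real_ else
        stats::cor(p, e, method = "spearman"))
  }
  est <- metric(predicted, experimental)
  boots <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(predicted[idx], experimental[idx])
    }, numeric(3))
  })
  a <- (1 - conf) / 2
  out <- lapply(seq_along(est), function(i) {
    v <- boots[i, ]
    list(estimate = unname(est[i]),
         lower = unname(stats::quantile(v, a, na.rm = TRUE, names = FALSE)),
         upper = unname(stats::quantile(v, 1 - a, na.rm = TRUE, names = FALSE)))
  })
  names(out) <- names(est)
  if (any(is.na(est[2:3]))) {
    out$note <- "correlation undefined for constant inputs"
  }
  out
}
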