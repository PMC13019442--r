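#' Direct binding free energy from end-state ensembles
#'
#' Fits the full three-leg estimator to receptor-only, ligand-only, and
#' complex ensembles: (i) a rigid-body pose restraint (Gaussian over
#' translations, Bingham over rotation quaternions) is fit to the largest
#' pose mode of the complex trajectory and released analytically at
#' standard state; (ii) decoupled samples are composed combinatorially
#' from receptor frames, ligand conformations, and restraint draws, and
#' filtered for steric clashes with Lennard-Jones-derived cutoffs, giving
#' `-kB T log(alpha)`; (iii) a single two-state MBAR step connects the
#' clash-free restrained decoupled ensemble to the physical complex
#' ensemble. The total is the standard-state binding free energy.
#'
#' @param receptor,ligand,complex `"trajectory_ensemble"` objects for the
#'   three end-state simulations.
#' @param backend Energy backend: a list with
#'   `evaluate(topology, coordinates)` in kcal/mol (see
#'   [make_toy_backend()]).
#' @param pocket_atoms Receptor atom indices used for pocket alignment
#'   (must index the leading receptor block of the complex). `NULL` uses
#'   all receptor atoms; `"auto8"` selects receptor atoms within 8
#'   Angstrom of the ligand in the reference frame.
#' @param temperature Kelvin (default 300).
#' @param energy_threshold Clash energy threshold in kcal/mol (default 2).
#' @param n_target Desired total number of combinatorial frame pairs
#'   (default 1e9; reduce for small studies).
#' @param n_s Subsampling cap per MBAR sample set (default 5000).
#' @param n_receptor_max,n_ligand_max Caps on the receptor frames and
#'   ligand conformations entering the combinatorial stage (default 400).
#' @param min_burn_in Minimum equilibration prefix per run, in frames.
#' @param decorrelate Reduce each ensemble to effectively independent
#'   frames first (default TRUE; the backend energy is the observable).
#' @param reference_frame Complex frame defining the reference pose
#'   (default 1).
#' @param use_symmetry Enumerate ligand graph automorphisms and extract
#'   symmetry-corrected transforms (default TRUE).
#' @param mode_bandwidth Optional mean-shift bandwidth override.
#' @param sigma_scale Multiplier applied to the fitted restraint's
#'   translational standard deviations before the downstream legs
#'   (default 1; used for restraint-width robustness checks).
#' @param batch_size Poses per clash-filter batch (default 4096).
#' @param seed Integer seed governing all randomness.
#' @param verbose Log per-leg progress (default FALSE).
#' @return An object of class `"dbfe"`: the three legs (`dg_release`,
#'   `dg_filter`, `dg_mbar`), `dg_total`, standard errors, the fitted
#'   `restraint`, and `diagnostics` (sample counts `n_p`, `n_l`, `n_zeta`,
#'   clash-free fraction `alpha`, MBAR `overlap`, pose-mode count, ...).
#'   Methods: `print`, `summary`, `coef`, `confint`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' spec <- make_harmonic_host_guest(seed = 7)
#' fit <- dbfe(direct_boltzmann_sample(spec, "receptor", 400),
#'             direct_boltzmann_sample(spec, "ligand", 400),
#'             direct_boltzmann_sample(spec, "complex", 400),
#'             backend = make_toy_backend(spec),
#'             n_target = 2e4, n_s = 1000, seed = 1)
#' coef(fit)
#' exact_delta_g_quadrature(spec)
#' }
#' @export
dbfe <- function(receptor, ligand, complex, backend,
                 pocket_atoms = NULL, temperature = 300,
                 energy_threshold = 2, n_target = 1e9, n_s = 5000,
                 n_receptor_max = 400, n_ligand_max = 400,
                 min_burn_in = 0, decorrelate = TRUE,
                 reference_frame = 1L, use_symmetry = TRUE,
                 mode_bandwidth = NULL, sigma_scale = 1,
                 batch_size = 4096, seed = 1L, verbose = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stopifnot(inherits(receptor, "trajectory_ensemble"),
            inherits(ligand, "trajectory_ensemble"),
            inherits(complex, "trajectory_ensemble"))
  ctop <- complex$topology
  if (ctop$role != "complex") stop_dbfe("topology", "complex ensemble has wrong role")
  rtop <- receptor$topology; ltop <- ligand$topology
  rid <- receptor_indices(ctop); lid <- ligand_indices(ctop)
  if (length(rid) != n_atoms(rtop) || length(lid) != n_atoms(ltop)) {
    stop_dbfe("topology", "complex partition does not match component topologies")
  }

  # -- decorrelation -------------------------------------------------------
  decorr_info <- NULL
  if (decorrelate) {
    obs <- function(ens, top) vapply(ens$frames, function(f)
      backend$evaluate(top, f), numeric(1))
    receptor <- decorrelate_frames(receptor, obs(receptor, rtop), min_burn_in)
    ligand <- decorrelate_frames(ligand, obs(ligand, ltop), min_burn_in)
    complex <- decorrelate_frames(complex, obs(complex, ctop), min_burn_in)
    decorr_info <- list(receptor = attr(receptor, "decorrelation"),
                        ligand = attr(ligand, "decorrelation"),
                        complex = attr(complex, "decorrelation"))
    say("decorrelated: %d receptor, %d ligand, %d complex frames",
        length(receptor$frames), length(ligand$frames), length(complex$frames))
  }
  if (reference_frame > length(complex$frames)) reference_frame <- 1L
  ref_coords <- complex$frames[[reference_frame]]

  if (is.null(pocket_atoms)) {
    pocket_atoms <- rid
  } else if (identical(pocket_atoms, "auto8")) {
    dmin <- apply(ref_coords[rid, , drop = FALSE], 1, function(a) {
      min(sqrt(rowSums(sweep(ref_coords[lid, , drop = FALSE], 2, a)^2)))
    })
    pocket_atoms <- rid[dmin <= 8]
    if (length(pocket_atoms) < 3) pocket_atoms <- rid
  }
  pocket_atoms <- as.integer(pocket_atoms)

  symmetry <- NULL
  if (use_symmetry) {
    symmetry <- enumerate_symmetry_permutations(ltop$elements, ltop$bonds)
  }
  geometry <- list(reference_coords = ref_coords, pocket_atoms = pocket_atoms,
                   ligand_atoms = lid, symmetry = symmetry)

  # -- leg 1: restraint fit and analytic release ---------------------------
  # restraint fitting needs a few thousand pose samples at most; cap the
  # O(n^2) mode search on very long complex trajectories
  cplx_fit <- subsample_frames(complex, 4000L, seed = derive_seed(seed, 20))
  zetas <- lapply(cplx_fit$frames, function(fr)
    extract_zeta(fr, ref_coords, pocket_atoms, lid, symmetry))
  mode <- select_largest_mode(zetas, bandwidth = mode_bandwidth)
  restraint <- fit_restraint(zetas, mode$member_indices,
                             reference_frame_index = reference_frame,
                             pocket_atoms = pocket_atoms)
  if (sigma_scale != 1) {
    restraint$sigma <- restraint$sigma * sigma_scale^2
  }
  dg_release <- delta_g_release(restraint, temperature)
  say("restraint fit on %d/%d frames in mode (of %d); dG(0->r) = %.3f kcal/mol",
      length(mode$member_indices), length(zetas), mode$n_modes, dg_release)

  # -- leg 2: combinatorial composition and clash filtering ----------------
  cutoffs <- compute_cutoff_matrix(rtop, ltop, energy_threshold)
  receptor_f <- subsample_frames(receptor, n_receptor_max,
                                 seed = derive_seed(seed, 21))
  ligand_f <- subsample_frames(ligand, n_ligand_max,
                               seed = derive_seed(seed, 22))
  np <- length(receptor_f$frames); nl <- length(ligand_f$frames)
  nz <- plan_pose_budget(np, nl, n_target)

  ref_lig <- ref_coords[lid, , drop = FALSE]
  shape_fits <- lapply(ligand_f$frames, function(cf) kabsch_superpose(cf, ref_lig))
  shapes <- lapply(seq_len(nl), function(j)
    apply_superposition(shape_fits[[j]], ligand_f$frames[[j]]))
  aligns <- lapply(receptor_f$frames, function(fr)
    kabsch_superpose(fr[pocket_atoms, , drop = FALSE],
                     ref_coords[pocket_atoms, , drop = FALSE]))
  receptor_aligned <- lapply(seq_len(np), function(i)
    apply_superposition(aligns[[i]], receptor_f$frames[[i]]))

  # zeta replicates streamed in blocks of bounded size; draws are seeded
  # per block so survivor poses can be regenerated without storing them
  max_poses <- 262144L
  nz_block <- max(1L, min(nz, as.integer(max_poses / nl)))
  blocks <- split(seq_len(nz), ceiling(seq_len(nz) / nz_block))
  surv <- vector("list", length(blocks))
  nL_at <- nrow(ref_lig)
  for (b in seq_along(blocks)) {
    ks <- blocks[[b]]
    zb <- sample_restraint(restraint, nl * length(ks),
                           seed = derive_seed(seed, 30, b))
    # pose order: j (conformation) fastest, then k (replicate)
    poses <- vector("list", nl * length(ks))
    for (kk in seq_along(ks)) {
      for (j in seq_len(nl)) {
        poses[[(kk - 1L) * nl + j]] <-
          apply_transform(zb[[(kk - 1L) * nl + j]], shapes[[j]])
      }
    }
    hits_i <- integer(0); hits_jk <- integer(0)
    for (i in seq_len(np)) {
      for (start in seq(1, length(poses), by = batch_size)) {
        idx <- start:min(start + batch_size - 1L, length(poses))
        ok <- .clash_filter_poses_cpp(receptor_aligned[[i]],
                                      do.call(rbind, poses[idx]),
                                      cutoffs$cutoffs, nL_at)
        hit <- idx[ok]
        hits_i <- c(hits_i, rep.int(i, length(hit)))
        hits_jk <- c(hits_jk, hit)
      }
    }
    surv[[b]] <- if (length(hits_i)) {
      cbind(block = rep.int(b, length(hits_i)), frame = hits_i, jk = hits_jk)
    } else {
      matrix(integer(0), 0, 3, dimnames = list(NULL, c("block", "frame", "jk")))
    }
    say("zeta block %d/%d: %d/%d pose tests clash-free", b, length(blocks),
        length(hits_i), np * length(poses))
  }
  surv <- do.call(rbind, surv)
  n_tested <- as.double(np) * nl * nz
  alpha <- nrow(surv) / n_tested
  filter_result <- structure(
    list(passing_pairs = surv, n_tested = n_tested, alpha = alpha,
         n_receptor_frames = np, n_poses = nl * nz,
         n_ligand_confs = nl, n_zeta = nz),
    class = "filter_result")
  leg2 <- delta_g_filter(filter_result, temperature)
  say("clash filter: alpha = %.4g over %.3g pairs; dG(r->rc) = %.3f kcal/mol",
      alpha, n_tested, leg2$dg)

  # -- compose surviving decoupled samples for the MBAR leg ----------------
  pick <- seq_len(nrow(surv))
  if (length(pick) > n_s) {
    pick <- with_seed(derive_seed(seed, 41), sort(sample.int(nrow(surv), n_s)))
  }
  chosen <- surv[pick, , drop = FALSE]
  decoupled <- vector("list", nrow(chosen))
  for (b in unique(chosen[, "block"])) {
    ks <- blocks[[b]]
    zb <- sample_restraint(restraint, nl * length(ks),
                           seed = derive_seed(seed, 30, b))
    rows <- which(chosen[, "block"] == b)
    for (r in rows) {
      jk <- chosen[r, "jk"]
      j <- ((jk - 1L) %% nl) + 1L
      i <- chosen[r, "frame"]
      zeta <- zb[[jk]]
      decoupled[[r]] <- list(
        receptor = receptor_f$frames[[i]],
        ligand = apply_transform(zeta, shapes[[j]], alignment = aligns[[i]]),
        zeta = zeta)
    }
  }

  # -- leg 3: two-state MBAR between Urc and the physical complex ----------
  rp <- evaluate_reduced_potentials(complex, decoupled, backend, restraint,
                                    geometry, rtop, ltop, cutoffs = cutoffs,
                                    temperature = temperature, n_s = n_s,
                                    seed = derive_seed(seed, 42))
  leg3 <- mbar_delta_g(rp, temperature)
  say("MBAR: dG(rc->1) = %.3f +/- %.3f kcal/mol, overlap %.3g",
      leg3$dg, leg3$se, leg3$overlap)

  fit <- assemble_total(dg_release, leg2$dg, leg3$dg,
                        se_filter = leg2$se, se_mbar = leg3$se,
                        diagnostics = list(
                          n_p = np, n_l = nl, n_zeta = nz,
                          n_tested = n_tested, alpha = alpha,
                          n_modes = mode$n_modes,
                          n_mode_members = length(mode$member_indices),
                          n_complex_frames = length(complex$frames),
                          n_decoupled_used = length(decoupled),
                          n_complex_used = rp$n_k[2],
                          overlap = leg3$overlap,
                          delta_f = leg3$delta_f,
                          elapsed_s = round(proc.time()[["elapsed"]] - t_start, 3)))
  fit$restraint <- restraint
  fit$temperature <- temperature
  fit$seed <- as.integer(seed)
  fit$config <- list(temperature = temperature,
                     energy_threshold = energy_threshold,
                     n_target = n_target, n_s = n_s,
                     n_receptor_max = n_receptor_max,
                     n_ligand_max = n_ligand_max,
                     min_burn_in = min_burn_in, decorrelate = decorrelate,
                     reference_frame = reference_frame,
                     use_symmetry = use_symmetry, sigma_scale = sigma_scale,
                     seed = as.integer(seed), backend = backend$name)
  fit$decorrelation <- decorr_info
  # compact diagnostics for plotting: pose embedding and state overlap
  fit$zeta_embedding <- zeta_matrix(zetas)
  fit$mode_members <- mode$member_indices
  fit$du <- rp$u[2, ] - rp$u[1, ]
  fit$du_origin <- rp$origin
  fit
}

#' @export
print.dbfe <- function(x, ...) {
  cat("Direct binding free energy estimate\n")
  cat(sprintf("  dG(0->r)   restraint release : %8.3f kcal/mol\n", x$dg_release))
  cat(sprintf("  dG(r->rc)  clash filter      : %8.3f kcal/mol (alpha = %.4g)\n",
              x$dg_filter, x$diagnostics$alpha))
  cat(sprintf("  dG(rc->1)  MBAR              : %8.3f kcal/mol\n", x$dg_mbar))
  cat(sprintf("  dG(binding)                  : %8.3f +/- %.3f kcal/mol\n",
              x$dg_total, x$se_total))
  invisible(x)
}

#' @export
summary.dbfe <- function(object, ...) {
  structure(list(fit = object), class = "summary.dbfe")
}

#' @export
print.summary.dbfe <- function(x, ...) {
  f <- x$fit
  print(f)
  d <- f$diagnostics
  cat(sprintf("\nSamples: N_P = %d receptor frames, N_L = %d ligand confs, N_zeta = %d\n",
              d$n_p, d$n_l, d$n_zeta))
  cat(sprintf("Pairs tested: %.4g, clash-free fraction alpha = %.4g\n",
              d$n_tested, d$alpha))
  cat(sprintf("Pose modes: %d (restraint fit on %d frames of %d)\n",
              d$n_modes, d$n_mode_members, d$n_complex_frames))
  cat(sprintf("MBAR: %d decoupled + %d complex samples, overlap = %.3g\n",
              d$n_decoupled_used, d$n_complex_used, d$overlap))
  if (d$overlap < 0.01) {
    cat("WARNING: low phase-space overlap; the estimate may be unreliable\n")
  }
  invisible(x)
}

#' @export
coef.dbfe <- function(object, ...) {
  c(dg_release = object$dg_release, dg_filter = object$dg_filter,
    dg_mbar = object$dg_mbar, dg_total = object$dg_total)
}

#' @export
confint.dbfe <- function(object, parm = "dg_total", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)[parm]
  se <- c(dg_release = 0, dg_filter = object$se_filter,
          dg_mbar = object$se_mbar, dg_total = object$se_total)[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  rownames(out) <- parm
  out
}

#' Draw pose samples from a fitted restraint
#'
#' `simulate()` on a fitted estimate returns rigid-body pose draws from
#' the fitted Gaussian-Bingham restraint, as an `nsim x 7` matrix
#' (tx, ty, tz, qw, qx, qy, qz).
#'
#' @param object A `"dbfe"` fit.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @export
simulate.dbfe <- function(object, nsim = 1, seed = 1L, ...) {
  z <- sample_restraint(object$restraint, nsim, seed = seed)
  m <- zeta_matrix(z)
  colnames(m) <- c("tx", "ty", "tz", "qw", "qx", "qy", "qz")
  m
}

#' Diagnostic plots for a fitted estimate
#'
#' Two panels: the pose-translation cloud with the restraint mode members
#' highlighted, and the distributions of the reduced-potential difference
#' `u_coupled - u_rc` for the two sample origins (the classic two-state
#' overlap picture: the histograms must overlap for the MBAR leg to be
#' well determined).
#'
#' @param x A `"dbfe"` fit.
#' @param ... Passed to `plot`.
#' @export
plot.dbfe <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  Z <- x$zeta_embedding
  col <- rep("grey60", nrow(Z))
  col[x$mode_members] <- "firebrick"
  graphics::plot(Z[, 1], Z[, 2], col = col, pch = 16, cex = 0.6,
                 xlab = "t_x (A)", ylab = "t_y (A)",
                 main = "pose translations (mode in red)", ...)
  du <- x$du[is.finite(x$du)]
  org <- x$du_origin[is.finite(x$du)]
  br <- pretty(range(du), 40)
  h1 <- graphics::hist(du[org == "filtered_decoupled"], breaks = br, plot = FALSE)
  h2 <- graphics::hist(du[org == "complex_traj"], breaks = br, plot = FALSE)
  ylim <- range(0, h1$density, h2$density)
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, ylim = ylim, xlab = "u_coupled - u_rc (kT)",
                 main = "state overlap")
  graphics::plot(h2, freq = FALSE, col = grDevices::adjustcolor("orange", 0.5),
                 border = NA, add = TRUE)
  graphics::legend("topright", c("decoupled", "complex"), bty = "n",
                   fill = grDevices::adjustcolor(c("steelblue", "orange"), 0.5))
  invisible(x)
}
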