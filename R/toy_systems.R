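#' Construct a toy host-guest system
#'
#' Builds a self-contained host-guest model whose Boltzmann distributions
#' are exactly samplable and whose binding free energy is computable by
#' low-dimensional quadrature, so every stage of the estimator can be
#' validated offline against ground truth.
#'
#' The host is a cage of atoms harmonically tethered to template positions
#' around the binding site; the guest is a rigid, geometrically asymmetric
#' molecule. The coupled potential acts on the guest's rigid-body pose:
#' a site term on the guest centroid (`kind`-dependent), an orientational
#' well `kappa * (1 - (q . q0)^2)` (antipodally symmetric, Bingham-shaped),
#' and a constant well depth. Because the site term acts on the pose and
#' the host tethers are independent of the guest, the configuration
#' integral factorizes and the exact standard-state binding free energy
#' reduces to one-dimensional quadratures. Per-atom Lennard-Jones
#' parameters on both species drive the steric clash filter.
#'
#' @param n_receptor_atoms Cage atom count (>= 4).
#' @param n_ligand_atoms Guest atom count (>= 3; distinct elements, so the
#'   guest has no exploitable graph symmetry).
#' @param stiffness Site translational stiffness `k_t` (kcal/mol/A^2).
#' @param well_depth Constant well depth (kcal/mol, subtracted in the
#'   bound state).
#' @param kappa Orientational stiffness (kcal/mol; 0 = free tumbling).
#' @param kind Site shape: `"harmonic"` (pure quadratic trap),
#'   `"harmonic_lj"` (quadratic trap plus a central soft-core
#'   Lennard-Jones sphere acting on the centroid distance, giving an
#'   anharmonic radial shell), `"double_well"` (quartic double well along
#'   z, quadratic in x/y), or `"box"` (flat well of volume `8*prod(box_half)`,
#'   entropy-free reference case).
#' @param cage_radius Host cage radius (Angstrom, default 5.5).
#' @param k_tether Host tether stiffness (kcal/mol/A^2, default 10).
#' @param guest_radius Guest template radius (Angstrom, default 1.1).
#' @param lj_site `c(sigma, epsilon)` of the central LJ sphere
#'   (`harmonic_lj` only).
#' @param dw_a,dw_b Quartic coefficient (kcal/mol/A^4) and well position
#'   (Angstrom) for `double_well`.
#' @param box_half Half-widths (length 3) for `box`.
#' @param temperature Kelvin (default 300).
#' @param seed Integer seed for the (deterministic) templates.
#' @return Object of class `"toy_system"`.
#' @export
make_harmonic_host_guest <- function(n_receptor_atoms = 24, n_ligand_atoms = 4,
                                     stiffness = 1, well_depth = 5, kappa = 2,
                                     kind = c("harmonic", "harmonic_lj",
                                              "double_well", "box"),
                                     cage_radius = 5.5, k_tether = 10,
                                     guest_radius = 1.1,
                                     lj_site = c(2.4, 0.4),
                                     dw_a = 2, dw_b = 1.2,
                                     box_half = c(1.5, 1.5, 1.5),
                                     temperature = 300, seed = 1L) {
  kind <- match.arg(kind)
  if (n_receptor_atoms < 4 || n_ligand_atoms < 3) {
    stop_dbfe("parameter", "need >= 4 receptor atoms and >= 3 ligand atoms")
  }
  if (n_ligand_atoms > 8) stop_dbfe("parameter", "toy guests support up to 8 atoms")
  # Fibonacci sphere cage with a seeded jitter
  i <- seq_len(n_receptor_atoms)
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  zc <- 1 - 2 * (i - 0.5) / n_receptor_atoms
  rho <- sqrt(pmax(0, 1 - zc^2))
  cage <- cage_radius * cbind(rho * cos(phi), rho * sin(phi), zc)
  cage <- cage + with_seed(derive_seed(seed, 11),
                           matrix(stats::rnorm(3 * n_receptor_atoms, sd = 0.25),
                                  ncol = 3))
  # rigid asymmetric guest template, centered, guaranteed non-collinear
  guest <- with_seed(derive_seed(seed, 12), {
    repeat {
      g <- matrix(stats::runif(3 * n_ligand_atoms, -guest_radius, guest_radius),
                  ncol = 3)
      g <- sweep(g, 2, colMeans(g))
      if (svd(g)$d[2] > 0.3 * guest_radius) break
    }
    g
  })
  structure(list(kind = kind,
                 n_receptor_atoms = n_receptor_atoms,
                 n_ligand_atoms = n_ligand_atoms,
                 receptor_template = cage, ligand_template = guest,
                 site_center = c(0, 0, 0),
                 stiffness = stiffness, well_depth = well_depth,
                 kappa = kappa, k_tether = k_tether,
                 lj_site = lj_site, dw_a = dw_a, dw_b = dw_b,
                 box_half = box_half,
                 lj_sigma_receptor = 3.4, lj_epsilon_receptor = 0.1,
                 lj_sigma_ligand = 3.4, lj_epsilon_ligand = 0.1,
                 temperature = temperature, seed = as.integer(seed)),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy host-guest system (%s site): %d cage + %d guest atoms, T = %g K\n",
              x$kind, x$n_receptor_atoms, x$n_ligand_atoms, x$temperature))
  invisible(x)
}

#' Topologies of a toy system
#'
#' @param spec A `"toy_system"`.
#' @return List of `"dbfe_topology"` objects: `receptor`, `ligand`,
#'   `complex`. Guest atoms get distinct elements and a chain of bonds.
#' @export
toy_topologies <- function(spec) {
  nr <- spec$n_receptor_atoms; nl <- spec$n_ligand_atoms
  el_l <- c("C", "N", "O", "S", "P", "F", "Cl", "Br")[seq_len(nl)]
  receptor <- dbfe_topology(
    atom_names = sprintf("R%d", seq_len(nr)),
    elements = rep("C", nr),
    lj_sigma = rep(spec$lj_sigma_receptor, nr),
    lj_epsilon = rep(spec$lj_epsilon_receptor, nr),
    bonds = NULL, role = "receptor")
  ligand <- dbfe_topology(
    atom_names = sprintf("L%d", seq_len(nl)),
    elements = el_l,
    lj_sigma = rep(spec$lj_sigma_ligand, nl),
    lj_epsilon = rep(spec$lj_epsilon_ligand, nl),
    bonds = cbind(seq_len(nl - 1), 2:nl), role = "ligand")
  complex <- dbfe_topology(
    atom_names = c(receptor$atom_names, ligand$atom_names),
    elements = c(receptor$elements, ligand$elements),
    lj_sigma = c(receptor$lj_sigma, ligand$lj_sigma),
    lj_epsilon = c(receptor$lj_epsilon, ligand$lj_epsilon),
    bonds = cbind(nr + seq_len(nl - 1), nr + 2:nl), role = "complex",
    receptor_atom_count = nr)
  list(receptor = receptor, ligand = ligand, complex = complex)
}

# site potential on the guest pose (t relative to site center, q canonical)
toy_site_energy <- function(spec, tvec, q) {
  dt <- tvec - spec$site_center
  e_or <- spec$kappa * (1 - q[1]^2)     # q0 = identity; (q . q0)^2 = q1^2
  e_tr <- switch(spec$kind,
    harmonic = 0.5 * spec$stiffness * sum(dt^2),
    harmonic_lj = {
      r <- max(sqrt(sum(dt^2)), 1e-8)
      s6 <- (spec$lj_site[1] / r)^6
      0.5 * spec$stiffness * r^2 + 4 * spec$lj_site[2] * (s6^2 - s6)
    },
    double_well = 0.5 * spec$stiffness * (dt[1]^2 + dt[2]^2) +
      spec$dw_a * (dt[3]^2 - spec$dw_b^2)^2,
    box = if (all(abs(dt) <= spec$box_half)) 0 else 1e6
  )
  e_tr + e_or - spec$well_depth
}

# extract the guest pose (t, q) from ligand coordinates in the lab frame
toy_guest_pose <- function(spec, ligand_coords) {
  tvec <- colMeans(ligand_coords)
  fit <- kabsch_superpose(spec$ligand_template, ligand_coords)
  list(t = tvec, q = fit$q)
}

#' Energy backend for toy systems
#'
#' Returns the energy-evaluator contract used by the estimator: a list
#' with `evaluate(topology, coordinates)` giving the potential energy in
#' kcal/mol. For a toy system: host atoms are harmonically tethered to the
#' cage template (in the lab frame), the rigid guest has zero internal
#' energy, and the complex adds the site energy of the guest pose.
#'
#' @param spec A `"toy_system"`.
#' @return A backend list with elements `evaluate` and `name`.
#' @export
make_toy_backend <- function(spec) {
  tether <- function(coords) {
    0.5 * spec$k_tether * sum((coords - spec$receptor_template)^2)
  }
  evaluate <- function(topology, coords) {
    coords <- as.matrix(coords)
    switch(topology$role,
      receptor = tether(coords),
      ligand = 0,
      complex = {
        nr <- topology$receptor_atom_count
        pose <- toy_guest_pose(spec, coords[(nr + 1):nrow(coords), , drop = FALSE])
        tether(coords[seq_len(nr), , drop = FALSE]) +
          toy_site_energy(spec, pose$t, pose$q)
      })
  }
  list(evaluate = evaluate, name = sprintf("toy_%s", spec$kind))
}

# 1-D Boltzmann sampler: inverse CDF on a fine grid with within-cell
# jitter (piecewise-uniform approximation of the density)
.grid_sampler <- function(f, lo, hi, n_grid = 8192) {
  x <- seq(lo, hi, length.out = n_grid)
  dx <- x[2] - x[1]
  d <- f(x)
  d <- d / sum(d)
  cdf <- cumsum(d)
  function(u) {
    i <- pmin(findInterval(u, cdf) + 1L, n_grid)
    pmin(hi, pmax(lo, x[i] + stats::runif(length(u), -dx / 2, dx / 2)))
  }
}

#' Draw exact Boltzmann samples from a toy system
#'
#' Independent samples from the receptor-only, ligand-only, or complex
#' Boltzmann distribution of a toy system: Gaussian tether displacements
#' for the host, uniform rigid rotations for the free guest, and
#' site-potential pose sampling (closed-form or 1-D inverse-CDF /
#' rejection) for the complex.
#'
#' @param spec A `"toy_system"`.
#' @param which One of `"receptor"`, `"ligand"`, `"complex"`.
#' @param n Number of frames.
#' @param seed Integer seed.
#' @return A `"trajectory_ensemble"` (complex frames stack host atoms
#'   first, then guest atoms, matching the complex topology).
#' @export
direct_boltzmann_sample <- function(spec, which = c("receptor", "ligand", "complex"),
                                    n, seed = 1L) {
  which <- match.arg(which)
  tops <- toy_topologies(spec)
  kT <- .kB * spec$temperature
  with_seed(derive_seed(seed, match(which, c("receptor", "ligand", "complex"))), {
    if (which == "receptor") {
      sd_r <- sqrt(kT / spec$k_tether)
      frames <- lapply(seq_len(n), function(i) {
        spec$receptor_template +
          matrix(stats::rnorm(3 * spec$n_receptor_atoms, sd = sd_r), ncol = 3)
      })
      return(trajectory_ensemble(tops$receptor, frames, "toy_receptor"))
    }
    if (which == "ligand") {
      qs <- random_quaternions(n)
      frames <- lapply(seq_len(n), function(i) {
        spec$ligand_template %*% t(quaternion_to_matrix(qs[i, ]))
      })
      return(trajectory_ensemble(tops$ligand, frames, "toy_ligand"))
    }
    # complex: host displacement + guest pose from the site Boltzmann
    sd_r <- sqrt(kT / spec$k_tether)
    tmat <- switch(spec$kind,
      harmonic = matrix(stats::rnorm(3 * n, sd = sqrt(kT / spec$stiffness)),
                        ncol = 3),
      harmonic_lj = {
        rad <- .grid_sampler(function(r) {
          s6 <- (spec$lj_site[1] / pmax(r, 1e-6))^6
          r^2 * exp(-(0.5 * spec$stiffness * r^2 +
                        4 * spec$lj_site[2] * (s6^2 - s6)) / kT)
        }, 1e-4, spec$lj_site[1] + 12 * sqrt(kT / spec$stiffness))
        r <- rad(stats::runif(n))
        dir <- matrix(stats::rnorm(3 * n), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        dir * r
      },
      double_well = {
        zs <- .grid_sampler(function(z) {
          exp(-spec$dw_a * (z^2 - spec$dw_b^2)^2 / kT)
        }, -spec$dw_b - 6, spec$dw_b + 6)
        cbind(matrix(stats::rnorm(2 * n, sd = sqrt(kT / spec$stiffness)),
                     ncol = 2), zs(stats::runif(n)))
      },
      box = matrix(stats::runif(3 * n, -1, 1), ncol = 3) %*% diag(spec$box_half)
    )
    tmat <- sweep(tmat, 2, spec$site_center, "+")
    # orientation: rejection from uniform S^3, accept prob exp(-beta*kappa*(1-q1^2))
    qs <- matrix(NA_real_, n, 4)
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 64L)
      cand <- random_quaternions(m)
      acc <- stats::runif(m) < exp(-spec$kappa * (1 - cand[, 1]^2) / kT)
      k <- which(acc)
      if (length(k)) {
        k <- k[seq_len(min(length(k), n - got))]
        qs[(got + 1):(got + length(k)), ] <- cand[k, , drop = FALSE]
        got <- got + length(k)
      }
    }
    frames <- lapply(seq_len(n), function(i) {
      host <- spec$receptor_template +
        matrix(stats::rnorm(3 * spec$n_receptor_atoms, sd = sd_r), ncol = 3)
      guest <- spec$ligand_template %*% t(quaternion_to_matrix(qs[i, ]))
      guest <- sweep(guest, 2, tmat[i, ], "+")
      rbind(host, guest)
    })
    trajectory_ensemble(tops$complex, frames, "toy_complex")
  })
}

#' Exact binding free energy of a toy system by quadrature
#'
#' Computes the standard-state binding free energy
#' `dG = -kB T * log(Z_t * A_rot * exp(beta * depth) / V0)`, where `Z_t`
#' is the configuration integral of the site's translational term (closed
#' form for harmonic and box sites, deterministic 1-D quadrature
#' otherwise), and `A_rot` the orientational factor
#' `E_uniform[exp(-beta*kappa*(1-x^2))]` over the uniform quaternion
#' sphere (1-D quadrature; 1 when `kappa = 0`). The host tethers and the
#' rigid guest's internal coordinates cancel exactly between the bound and
#' unbound states because the site potential acts only on the guest pose.
#'
#' @param spec A `"toy_system"`.
#' @param rel_tol Relative quadrature tolerance (default 1e-9).
#' @return Exact binding free energy (kcal/mol).
#' @export
exact_delta_g_quadrature <- function(spec, rel_tol = 1e-9) {
  kT <- .kB * spec$temperature
  z_t <- switch(spec$kind,
    harmonic = (2 * pi * kT / spec$stiffness)^(3 / 2),
    harmonic_lj = {
      f <- function(r) {
        s6 <- (spec$lj_site[1] / pmax(r, 1e-9))^6
        4 * pi * r^2 * exp(-(0.5 * spec$stiffness * r^2 +
                               4 * spec$lj_site[2] * (s6^2 - s6)) / kT)
      }
      up <- spec$lj_site[1] + 14 * sqrt(kT / spec$stiffness)
      q <- stats::integrate(f, 0, up, rel.tol = rel_tol, abs.tol = 0,
                            subdivisions = 500L)
      if (q$abs.error > 10 * rel_tol * abs(q$value)) {
        stop_dbfe("numeric", sprintf("radial quadrature tolerance not met (%.1e)",
                                     q$abs.error / abs(q$value)))
      }
      q$value
    },
    double_well = {
      zint <- stats::integrate(function(z) {
        exp(-spec$dw_a * (z^2 - spec$dw_b^2)^2 / kT)
      }, -spec$dw_b - 8, spec$dw_b + 8, rel.tol = rel_tol, abs.tol = 0,
      subdivisions = 500L)$value
      (2 * pi * kT / spec$stiffness) * zint
    },
    box = 8 * prod(spec$box_half)
  )
  a_rot <- if (spec$kappa == 0) 1 else {
    num <- stats::integrate(function(x) {
      exp(-spec$kappa * (1 - x^2) / kT) * sqrt(1 - x^2)
    }, -1, 1, rel.tol = rel_tol, abs.tol = 0, subdivisions = 500L)$value
    num / (pi / 2)
  }
  -kT * (log(z_t) + log(a_rot) + spec$well_depth / kT - log(.V0))
}

#' Write toy fixture trajectories, topologies, and a manifest
#'
#' Generates receptor/ligand/complex ensembles, writes them in the
#' package's plain-text XYZ format together with PDB/SDF topologies, JSON
#' Lennard-Jones sidecars, and a manifest recording the seeds and the
#' exact binding free energy.
#'
#' @param spec A `"toy_system"`.
#' @param out_dir Output directory (created if missing).
#' @param n_frames Frames per species (default 200).
#' @param seed Integer seed.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
generate_fixture_trajectories <- function(spec, out_dir, n_frames = 200,
                                          seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tops <- toy_topologies(spec)
  paths <- list()
  for (which in c("receptor", "ligand", "complex")) {
    ens <- direct_boltzmann_sample(spec, which, n_frames, seed)
    p <- file.path(out_dir, paste0(which, ".xyz"))
    write_trajectory_xyz(ens, p)
    paths[[which]] <- basename(p)
    top <- tops[[which]]
    lj <- stats::setNames(lapply(seq_len(n_atoms(top)), function(i) {
      list(sigma = top$lj_sigma[i], epsilon = top$lj_epsilon[i])
    }), as.character(seq_len(n_atoms(top))))
    jsonlite::write_json(lj, file.path(out_dir, paste0(which, ".lj.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write_toy_pdb(tops$receptor, spec$receptor_template,
                file.path(out_dir, "receptor.pdb"))
  write_toy_pdb(tops$complex,
                rbind(spec$receptor_template,
                      sweep(spec$ligand_template, 2, spec$site_center, "+")),
                file.path(out_dir, "complex.pdb"))
  write_toy_sdf(tops$ligand, spec$ligand_template,
                file.path(out_dir, "ligand.sdf"))
  manifest <- list(kind = spec$kind, seed = spec$seed, sample_seed = seed,
                   n_frames = n_frames, temperature = spec$temperature,
                   exact_delta_g = exact_delta_g_quadrature(spec),
                   files = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# minimal PDB writer (ATOM + CONECT) for toy topologies
write_toy_pdb <- function(topology, coords, path) {
  n <- n_atoms(topology)
  lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(n), substr(topology$atom_names, 1, 4), "TOY",
                   seq_len(n), coords[, 1], coords[, 2], coords[, 3],
                   topology$elements)
  if (nrow(topology$bonds)) {
    lines <- c(lines, sprintf("CONECT%5d%5d", topology$bonds[, 1],
                              topology$bonds[, 2]))
  }
  writeLines(c(lines, "END"), path)
}

# minimal V2000 SDF writer for toy guests
write_toy_sdf <- function(topology, coords, path) {
  n <- n_atoms(topology); nb <- nrow(topology$bonds)
  lines <- c("toy guest", "  dbfe", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     coords[, 1], coords[, 2], coords[, 3], topology$elements))
  if (nb) {
    lines <- c(lines, sprintf("%3d%3d  1  0", topology$bonds[, 1],
                              topology$bonds[, 2]))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
}
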