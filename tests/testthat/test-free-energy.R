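kT300 <- 0.0019872041 * 300

test_that("reduced potentials have the documented structure on a toy system", {
  spec <- make_harmonic_host_guest(kind = "harmonic", seed = 8)
  backend <- make_toy_backend(spec)
  tops <- toy_topologies(spec)
  cpx <- direct_boltzmann_sample(spec, "complex", 40, seed = 1)
  rec <- direct_boltzmann_sample(spec, "receptor", 10, seed = 2)
  ref <- cpx$frames[[1]]
  nr <- spec$n_receptor_atoms
  lid <- (nr + 1):(nr + spec$n_ligand_atoms)
  geometry <- list(reference_coords = ref, pocket_atoms = 1:nr,
                   ligand_atoms = lid, symmetry = NULL)
  restraint <- fit_restraint(lapply(cpx$frames, function(fr)
    extract_zeta(fr, ref, 1:nr, lid)))
  # composed decoupled samples: receptor frame + ligand posed by a draw
  zs <- sample_restraint(restraint, 10, seed = 3)
  dec <- lapply(1:10, function(i) {
    align <- kabsch_superpose(rec$frames[[i]][1:nr, ], ref[1:nr, ])
    list(receptor = rec$frames[[i]],
         ligand = apply_transform(zs[[i]], ref[lid, ], alignment = align),
         zeta = zs[[i]])
  })
  rp <- evaluate_reduced_potentials(cpx, dec, backend, restraint, geometry,
                                    tops$receptor, tops$ligand,
                                    temperature = 300, n_s = 25, seed = 4)
  expect_s3_class(rp, "reduced_potentials")
  expect_equal(dim(rp$u), c(2, 35))
  expect_equal(rp$n_k, c(10, 25))        # subsampled complex set, seed-stable
  expect_equal(rp$origin,
               c(rep("filtered_decoupled", 10), rep("complex_traj", 25)))
  rp2 <- evaluate_reduced_potentials(cpx, dec, backend, restraint, geometry,
                                     tops$receptor, tops$ligand,
                                     temperature = 300, n_s = 25, seed = 4)
  expect_identical(rp$u, rp2$u)

  # hand evaluation on the composed samples: u_rc = beta(U_P + U_L + U_zeta),
  # u_coupled = beta * U_PL
  beta <- 1 / kT300
  for (i in c(1, 5)) {
    up <- backend$evaluate(tops$receptor, dec[[i]]$receptor)
    uz <- restraint_energy(dec[[i]]$zeta, restraint, 300)
    upl <- backend$evaluate(tops$complex, rbind(dec[[i]]$receptor, dec[[i]]$ligand))
    expect_equal(rp$u[1, i], beta * (up + 0 + uz), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rp$u[2, i], beta * upl, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("with a noninteracting complex the state difference is minus the restraint", {
  # backend where U_PL = U_P + U_L identically: the coupled/decoupled
  # difference reduces to the (reduced) restraint energy alone
  spec <- make_harmonic_host_guest(kind = "harmonic", seed = 8)
  tops <- toy_topologies(spec)
  base <- make_toy_backend(spec)
  nonint <- list(name = "noninteracting", evaluate = function(top, coords) {
    if (top$role == "complex") {
      nr <- top$receptor_atom_count
      base$evaluate(tops$receptor, coords[1:nr, , drop = FALSE])
    } else if (top$role == "receptor") base$evaluate(top, coords) else 0
  })
  cpx <- direct_boltzmann_sample(spec, "complex", 30, seed = 5)
  rec <- direct_boltzmann_sample(spec, "receptor", 10, seed = 6)
  ref <- cpx$frames[[1]]
  nr <- spec$n_receptor_atoms
  lid <- (nr + 1):(nr + spec$n_ligand_atoms)
  geometry <- list(reference_coords = ref, pocket_atoms = 1:nr,
                   ligand_atoms = lid, symmetry = NULL)
  restraint <- fit_restraint(lapply(cpx$frames, function(fr)
    extract_zeta(fr, ref, 1:nr, lid)))
  zs <- sample_restraint(restraint, 10, seed = 7)
  dec <- lapply(1:10, function(i) {
    align <- kabsch_superpose(rec$frames[[i]][1:nr, ], ref[1:nr, ])
    list(receptor = rec$frames[[i]],
         ligand = apply_transform(zs[[i]], ref[lid, ], alignment = align),
         zeta = zs[[i]])
  })
  rp <- evaluate_reduced_potentials(cpx, dec, nonint, restraint, geometry,
                                    tops$receptor, tops$ligand,
                                    temperature = 300, n_s = 30, seed = 8)
  beta <- 1 / kT300
  uz <- vapply(seq_len(10), function(i)
    restraint_energy(dec[[i]]$zeta, restraint, 300), numeric(1))
  expect_equal(rp$u[2, 1:10] - rp$u[1, 1:10], -beta * uz, tolerance = 1e-10)
})

test_that("assembly sums legs and combines errors in quadrature", {
  res <- assemble_total(-2, 1, -4, se_filter = 0.03, se_mbar = 0.04)
  expect_equal(res$dg_total, -5)
  expect_equal(res$se_total, sqrt(0.03^2 + 0.04^2))
  z <- assemble_total(0, 0, 0, se_filter = 0.1, se_mbar = 0.2)
  expect_equal(z$dg_total, 0)
  expect_equal(z$se_total^2, 0.1^2 + 0.2^2)
  expect_error(assemble_total(NaN, 0, 0), class = "dbfe_assembly_error")
  expect_error(assemble_total(0, Inf, 0), class = "dbfe_assembly_error")
})

test_that("pose combination is a guarded log-sum-exp", {
  kT <- kT300
  expect_equal(combine_poses(-5, 300), -5)
  expect_equal(combine_poses(c(-5, -5), 300), -5 - kT * log(2), tolerance = 1e-12)
  expect_equal(combine_poses(c(-5, 50), 300), -5, tolerance = 1e-9)
  # extreme values do not overflow
  expect_equal(combine_poses(c(-500, -500), 300), -500 - kT * log(2),
               tolerance = 1e-9)
  expect_error(combine_poses(numeric(0)), class = "dbfe_parameter_error")
})

test_that("the end-state interaction baseline decomposes complex energies", {
  spec <- make_harmonic_host_guest(kind = "harmonic", seed = 8, well_depth = 3)
  tops <- toy_topologies(spec)
  base <- make_toy_backend(spec)
  cpx <- direct_boltzmann_sample(spec, "complex", 50, seed = 9)
  # noninteracting: exactly zero
  nonint <- list(name = "ni", evaluate = function(top, coords) {
    if (top$role == "complex") {
      nr <- top$receptor_atom_count
      base$evaluate(tops$receptor, coords[1:nr, , drop = FALSE])
    } else if (top$role == "receptor") base$evaluate(top, coords) else 0
  })
  expect_equal(mmgbsa_baseline(cpx, nonint), 0, tolerance = 1e-10)
  # constant interaction of -3: exactly -3
  const <- list(name = "const", evaluate = function(top, coords) {
    if (top$role == "complex") -3 else 0
  })
  expect_equal(mmgbsa_baseline(cpx, const), -3)
  # toy backend: matches frame-by-frame hand evaluation
  hand <- mean(vapply(cpx$frames, function(fr) {
    nr <- spec$n_receptor_atoms
    pose <- dbfe:::toy_guest_pose(spec, fr[(nr + 1):nrow(fr), , drop = FALSE])
    dbfe:::toy_site_energy(spec, pose$t, pose$q)
  }, numeric(1)))
  expect_equal(mmgbsa_baseline(cpx, base), hand, tolerance = 1e-9)
})

test_that("bootstrap metrics match closed forms and handle degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  m <- bootstrap_metrics(x, x, n_resamples = 200, seed = 1)
  expect_equal(m$rmse$estimate, 0)
  expect_equal(m$pearson_r$estimate, 1)
  expect_equal(m$spearman_rho$estimate, 1)
  m2 <- bootstrap_metrics(x, rev(x), n_resamples = 200, seed = 1)
  expect_equal(m2$spearman_rho$estimate, -1)
  # 5-point set against the covariance-formula oracle
  set.seed(75)
  p <- rnorm(5); e <- rnorm(5)
  r_oracle <- sum((p - mean(p)) * (e - mean(e))) /
    sqrt(sum((p - mean(p))^2) * sum((e - mean(e))^2))
  m3 <- bootstrap_metrics(p, e, n_resamples = 200, seed = 2)
  expect_equal(m3$pearson_r$estimate, r_oracle, tolerance = 1e-12)
  expect_equal(m3$rmse$estimate, sqrt(mean((p - e)^2)), tolerance = 1e-12)
  expect_lte(m3$pearson_r$lower, m3$pearson_r$estimate)
  expect_gte(m3$pearson_r$upper, m3$pearson_r$estimate)
  # reproducible under seed
  m4 <- bootstrap_metrics(p, e, n_resamples = 200, seed = 2)
  expect_identical(m3, m4)
  # constant predictions: correlation reported as undefined, no crash
  mc <- bootstrap_metrics(rep(1, 5), e, n_resamples = 50, seed = 3)
  expect_true(is.na(mc$pearson_r$estimate))
  expect_match(mc$note, "constant")
})
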