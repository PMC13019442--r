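test_that("toy specs are deterministic under seed", {
  a <- make_harmonic_host_guest(seed = 4)
  b <- make_harmonic_host_guest(seed = 4)
  c <- make_harmonic_host_guest(seed = 5)
  expect_identical(a$receptor_template, b$receptor_template)
  expect_identical(a$ligand_template, b$ligand_template)
  expect_false(identical(a$ligand_template, c$ligand_template))
})

test_that("exact free energy matches closed forms where they exist", {
  kB <- 0.0019872041; v0 <- 1660
  # pure harmonic site, free tumbling: -kT log[(2 pi kT / k)^{3/2} / V0] - depth
  spec <- make_harmonic_host_guest(stiffness = 1.3, well_depth = 5, kappa = 0,
                                   kind = "harmonic", seed = 2)
  kT <- kB * spec$temperature
  closed <- -kT * log((2 * pi * kT / 1.3)^(3 / 2) / v0) - 5
  expect_equal(exact_delta_g_quadrature(spec), closed, tolerance = 1e-9)
  # box site, no coupling beyond confinement: volume ratio only
  specb <- make_harmonic_host_guest(kind = "box", well_depth = 0, kappa = 0,
                                    box_half = c(2, 3, 4), seed = 2)
  expect_equal(exact_delta_g_quadrature(specb),
               -kT * log(8 * 2 * 3 * 4 / v0), tolerance = 1e-12)
  # zero well depth: pure restraint/volume term
  spec0 <- make_harmonic_host_guest(stiffness = 2, well_depth = 0, kappa = 0,
                                    kind = "harmonic", seed = 2)
  expect_equal(exact_delta_g_quadrature(spec0),
               -kT * log((2 * pi * kT / 2)^(3 / 2) / v0), tolerance = 1e-9)
  # orientational stiffness adds a positive (entropy-loss) contribution
  speck <- make_harmonic_host_guest(stiffness = 2, well_depth = 0, kappa = 2,
                                    kind = "harmonic", seed = 2)
  expect_gt(exact_delta_g_quadrature(speck), exact_delta_g_quadrature(spec0))
})

test_that("LJ-shell exact quadrature agrees with Monte-Carlo integration", {
  spec <- make_harmonic_host_guest(kind = "harmonic_lj", stiffness = 1,
                                   well_depth = 0, kappa = 0, seed = 3)
  kT <- 0.0019872041 * spec$temperature
  got <- exact_delta_g_quadrature(spec)
  # oracle: MC integration of Z_t over a box, 1e7 points in chunks
  set.seed(80)
  half <- 12
  tot <- 0; n <- 0
  for (chunk in 1:10) {
    x <- matrix(runif(3e6, -half, half), ncol = 3)
    r <- sqrt(rowSums(x^2))
    s6 <- (spec$lj_site[1] / pmax(r, 1e-9))^6
    u <- 0.5 * spec$stiffness * r^2 + 4 * spec$lj_site[2] * (s6^2 - s6)
    tot <- tot + sum(exp(-u / kT)); n <- n + nrow(x)
  }
  z_mc <- (2 * half)^3 * tot / n
  dg_mc <- -kT * log(z_mc / 1660)
  expect_lt(abs(got - dg_mc), 0.01)
})

test_that("complex samples follow the site Boltzmann distribution", {
  # harmonic site: guest centroid displacements are Gaussian with
  # variance kT/k per coordinate (equipartition)
  spec <- make_harmonic_host_guest(stiffness = 2, kappa = 1, seed = 6)
  kT <- 0.0019872041 * spec$temperature
  cpx <- direct_boltzmann_sample(spec, "complex", 4000, seed = 21)
  nr <- spec$n_receptor_atoms
  tm <- t(vapply(cpx$frames, function(fr)
    colMeans(fr[(nr + 1):nrow(fr), , drop = FALSE]), numeric(3)))
  expect_lt(max(abs(colMeans(tm) - spec$site_center)), 0.05)
  expect_lt(max(abs(diag(cov(tm)) - kT / 2)), 0.05 * kT / 2 + 0.01)
  # double-well site: the z histogram matches the 1-D Boltzmann density
  specd <- make_harmonic_host_guest(kind = "double_well", kappa = 0, seed = 6)
  cpxd <- direct_boltzmann_sample(specd, "complex", 6000, seed = 22)
  z <- vapply(cpxd$frames, function(fr)
    mean(fr[(nr + 1):nrow(fr), 3]), numeric(1))
  br <- seq(-2.5, 2.5, length.out = 26)
  dens <- function(x) exp(-specd$dw_a * (x^2 - specd$dw_b^2)^2 / kT)
  pexp <- vapply(seq_len(length(br) - 1), function(i)
    integrate(dens, br[i], br[i + 1])$value, numeric(1))
  pexp <- pexp / sum(pexp)
  obs <- table(cut(z, br))
  keep <- pexp > 1e-8
  chi <- suppressWarnings(chisq.test(obs[keep], p = pexp[keep] / sum(pexp[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("receptor samples pass the decorrelation stage nearly untouched", {
  spec <- make_harmonic_host_guest(seed = 7)
  rec <- direct_boltzmann_sample(spec, "receptor", 800, seed = 31)
  backend <- make_toy_backend(spec)
  obs <- vapply(rec$frames, function(f)
    backend$evaluate(rec$topology, f), numeric(1))
  g <- statistical_inefficiency(obs)
  expect_lt(g, 1.5)  # independent by construction
})

test_that("fixtures round trip and the manifest is self-consistent", {
  spec <- make_harmonic_host_guest(seed = 9, n_receptor_atoms = 8,
                                   n_ligand_atoms = 3)
  dir <- tempfile()
  man <- generate_fixture_trajectories(spec, dir, n_frames = 12, seed = 5)
  expect_equal(man$exact_delta_g, exact_delta_g_quadrature(spec))
  tops <- toy_topologies(spec)
  # coordinates survive the write/read round trip to format precision
  rec <- direct_boltzmann_sample(spec, "receptor", 12, seed = 5)
  back <- read_trajectory(file.path(dir, "receptor.xyz"), tops$receptor)
  for (i in 1:12) expect_equal(back$frames[[i]], rec$frames[[i]],
                               tolerance = 1e-6, ignore_attr = TRUE)
  # the written PDB + sidecar reproduce the receptor topology
  rt <- read_topology(file.path(dir, "receptor.pdb"), "receptor",
                      lj = file.path(dir, "receptor.lj.json"))
  expect_equal(rt$lj_sigma, tops$receptor$lj_sigma)
  expect_equal(length(rt$atom_names), spec$n_receptor_atoms)
  # the written SDF reproduces the guest graph
  lt <- read_topology(file.path(dir, "ligand.sdf"), "ligand",
                      lj = file.path(dir, "ligand.lj.json"))
  expect_equal(nrow(lt$bonds), spec$n_ligand_atoms - 1)
  # regeneration with the manifest seeds is byte-identical
  dir2 <- tempfile()
  generate_fixture_trajectories(spec, dir2, n_frames = man$n_frames,
                                seed = man$sample_seed)
  for (f in c("receptor.xyz", "ligand.xyz", "complex.xyz", "manifest.json")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("the end-state baseline contrast: exact on a flat well, biased on a stiff trap", {
  kB <- 0.0019872041
  # entropy-free flat (box) well of standard-state volume: the mean
  # interaction energy IS the binding free energy
  v0 <- 1660
  half <- (v0 / 8)^(1 / 3)
  specb <- make_harmonic_host_guest(kind = "box", well_depth = 4, kappa = 0,
                                    box_half = rep(half, 3), seed = 11)
  exact_b <- exact_delta_g_quadrature(specb)
  cpxb <- direct_boltzmann_sample(specb, "complex", 400, seed = 41)
  mm_b <- mmgbsa_baseline(cpxb, make_toy_backend(specb))
  expect_equal(exact_b, -4, tolerance = 1e-9)
  expect_lt(abs(mm_b - exact_b), 0.1)
  # soft harmonic trap: the baseline misses the configurational-entropy
  # cost by the analytically computable amount
  speck <- make_harmonic_host_guest(kind = "harmonic", stiffness = 0.5,
                                    well_depth = 4, kappa = 0, seed = 11)
  kT <- kB * speck$temperature
  exact_h <- exact_delta_g_quadrature(speck)
  cpxh <- direct_boltzmann_sample(speck, "complex", 4000, seed = 42)
  mm_h <- mmgbsa_baseline(cpxh, make_toy_backend(speck))
  # <U_site> = -depth + (3/2) kT by equipartition
  expect_lt(abs(mm_h - (-4 + 1.5 * kT)), 0.05)
  gap_expected <- (-4 + 1.5 * kT) - exact_h
  expect_lt(abs((mm_h - exact_h) - gap_expected), 0.05)
  expect_gt(abs(gap_expected), 0.5)  # the entropy term is material here
})
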