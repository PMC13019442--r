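make_params <- function(mu = c(0, 0, 0), sigma = diag(3), M = diag(4),
                        Z = c(0, 0, 0, 0), rotation_active = TRUE) {
  structure(list(mu = mu, sigma = sigma, M = M, Z = Z,
                 rotation_active = rotation_active,
                 reference_frame_index = 0L, pocket_atoms = integer(0)),
            class = "dbfe_restraint")
}

rand_orthogonal4 <- function() qr.Q(qr(matrix(rnorm(16), 4)))

test_that("mode selection handles degenerate and well-separated cases", {
  z0 <- rigid_transform(c(1, 2, 3), c(1, 0, 0, 0))
  all_same <- replicate(50, z0, simplify = FALSE)
  m <- select_largest_mode(all_same)
  expect_equal(m$n_modes, 1)
  expect_length(m$member_indices, 50)
  expect_equal(m$mode_center[1:3], c(1, 2, 3), tolerance = 1e-9)

  set.seed(50)
  mk <- function(n, c0) lapply(seq_len(n), function(i)
    rigid_transform(c0 + rnorm(3, sd = 0.3), c(1, 0, 0, 0)))
  zs <- c(mk(80, c(0, 0, 0)), mk(20, c(6, 0, 0)))
  m2 <- select_largest_mode(zs)
  # oracle: nearest-center assignment on the generating centers; points
  # essentially equidistant from both centers are allowed to go either way
  X <- t(vapply(zs, function(z) z$t, numeric(3)))
  d1 <- sqrt(colSums((t(X) - c(0, 0, 0))^2))
  d2 <- sqrt(colSums((t(X) - c(6, 0, 0))^2))
  want <- which(d1 < d2)
  ambiguous <- which(abs(d1 - d2) < 2)
  mism <- union(setdiff(m2$member_indices, want),
                setdiff(want, m2$member_indices))
  expect_true(all(mism %in% ambiguous))
  expect_lt(abs(length(m2$member_indices) - 80), 3)
  expect_equal(m2$mode_center[1:3], c(0, 0, 0), tolerance = 0.5)
  # the mode center lies inside the convex hull of member translations
  tr <- X[m2$member_indices, ]
  expect_true(all(m2$mode_center[1:3] >= apply(tr, 2, min) &
                    m2$mode_center[1:3] <= apply(tr, 2, max)))
})

test_that("restraint fit recovers known parameters and is antipodally invariant", {
  set.seed(51)
  mu <- c(1, -0.5, 2)
  sigma <- diag(c(0.4, 0.25, 0.6))
  M <- rand_orthogonal4()
  Z <- c(0, -4, -12, -30)
  params <- make_params(mu, sigma, M, Z)
  zs <- sample_restraint(params, 2e4, seed = 3)
  fit <- fit_restraint(zs)
  expect_lt(max(abs(fit$mu - mu)), 0.05)
  expect_lt(max(abs(fit$sigma - sigma)), 0.1 * max(diag(sigma)))
  expect_lt(max(abs(fit$Z - Z) / pmax(abs(Z), 1)), 0.15)

  # duplicating every sample with q -> -q leaves the fit unchanged
  # (antipodal/double-cover invariance)
  zs2 <- c(zs[1:500], lapply(zs[1:500], function(z) {
    w <- z; w$q <- canonical_quaternion(-z$q); w
  }))
  f1 <- fit_restraint(zs[1:500])
  f2 <- fit_restraint(zs2)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
  expect_equal(f1$Z, f2$Z, tolerance = 1e-8)
})

test_that("degenerate translations hit the covariance floor", {
  zs <- replicate(20, rigid_transform(c(1, 1, 1), c(1, 0, 0, 0)),
                  simplify = FALSE)
  fit <- fit_restraint(zs)
  expect_equal(fit$mu, c(1, 1, 1))
  expect_equal(fit$sigma, diag(1e-4, 3), tolerance = 1e-10)
  expect_false(fit$rotation_active)  # identity quaternions: uniform rotations
  expect_equal(fit$Z, rep(0, 4))
})

test_that("restraint energy has the gauge-fixed quadratic form", {
  set.seed(52)
  M <- rand_orthogonal4()
  Z <- c(0, -5, -10, -20)
  sigma <- diag(c(0.5, 1, 2))
  params <- make_params(c(1, 2, 3), sigma, M, Z)
  kT <- dbfe_constants()$kB * 300
  # at the mode (t = mu, q = leading Bingham axis): energy exactly 0
  e0 <- restraint_energy(rigid_transform(c(1, 2, 3), M[, 1]), params)
  expect_equal(e0, 0, tolerance = 1e-10)
  # one Mahalanobis unit of translation costs kT/2
  dt <- c(sqrt(0.5), 0, 0)
  e1 <- restraint_energy(rigid_transform(c(1, 2, 3) + dt, M[, 1]), params)
  expect_equal(e1, kT / 2, tolerance = 1e-9)
  # q -> -q invariance
  for (i in 1:100) {
    q <- rnorm(4)
    za <- rigid_transform(rnorm(3), q)
    zb <- rigid_transform(za$t, -q)
    expect_equal(restraint_energy(za, params), restraint_energy(zb, params),
                 tolerance = 1e-12)
  }
})

test_that("sampler moments match the parameters", {
  set.seed(53)
  sigma <- crossprod(matrix(rnorm(9, sd = 0.5), 3)) + diag(0.2, 3)
  params <- make_params(c(2, -1, 0.5), sigma)
  zs <- sample_restraint(params, 1e5, seed = 9)
  tm <- t(vapply(zs, function(z) z$t, numeric(3)))
  expect_lt(max(abs(colMeans(tm) - params$mu)), 0.02)
  expect_lt(max(abs(cov(tm) - sigma)), 0.05 * max(diag(sigma)))
  qs <- t(vapply(zs, function(z) z$q, numeric(4)))
  expect_equal(rowSums(qs^2), rep(1, nrow(qs)), tolerance = 1e-9)
  expect_true(all(qs[, 1] >= -1e-12))  # canonical hemisphere
  # Z = 0: uniform on S^3, scatter matrix I/4
  S <- crossprod(qs) / nrow(qs)
  expect_lt(max(abs(S - diag(4) / 4)), 0.01)
})

test_that("sampled density matches the restraint energy (histogram test)", {
  set.seed(54)
  params <- make_params(Z = c(0, -2, -6, -6), M = rand_orthogonal4())
  zs <- sample_restraint(params, 4e4, seed = 2)
  kT <- dbfe_constants()$kB * 300
  # project on the leading Bingham axis: x = (q . m1)^2 has density
  # prop. to marginal of exp(sum z_i y_i^2); compare histogram of a 1-D
  # statistic against its quadrature prediction via chi-square
  qs <- t(vapply(zs, function(z) z$q, numeric(4)))
  w <- qs %*% params$M
  x <- w[, 1]^2
  # predicted density of x via MC from an independent uniform oracle,
  # importance-weighted by the Bingham density
  qu <- matrix(rnorm(4 * 2e5), ncol = 4)
  qu <- qu / sqrt(rowSums(qu^2))
  wu <- (qu %*% params$M)
  dens <- exp(rowSums(sweep(wu^2, 2, params$Z, "*")))
  xu <- wu[, 1]^2
  br <- seq(0, 1, length.out = 21)
  obs <- table(cut(x, br))
  pexp <- tapply(dens, cut(xu, br), sum)
  pexp[is.na(pexp)] <- 0
  pexp <- pexp / sum(pexp)
  keep <- pexp > 1e-6
  chi <- suppressWarnings(chisq.test(obs[keep], p = pexp[keep] / sum(pexp[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("log partition is exact for Z = 0 and gauge/axes invariant", {
  p0 <- make_params()
  lp <- restraint_log_partition(p0)
  expect_equal(lp$log_z, 3 / 2 * log(2 * pi) + log(2 * pi^2), tolerance = 1e-10)

  set.seed(55)
  Z <- c(0, -3, -8, -15)
  p1 <- make_params(Z = Z, M = rand_orthogonal4())
  p2 <- make_params(Z = Z, M = rand_orthogonal4())
  expect_equal(restraint_log_partition(p1)$log_z_rot,
               restraint_log_partition(p2)$log_z_rot, tolerance = 1e-7)
  # gauge: shifting Z by c scales the constant by exp(c)
  p3 <- make_params(Z = Z - 5, M = p1$M)
  expect_equal(restraint_log_partition(p3)$log_z_rot,
               restraint_log_partition(p1)$log_z_rot - 5, tolerance = 1e-7)
})

test_that("release free energy has the closed forms and monotonicity", {
  kT <- dbfe_constants()$kB * 300
  v0 <- dbfe_constants()$v0
  # restraint volume equal to the standard-state volume -> zero cost
  s2 <- (v0^(2 / 3)) / (2 * pi)
  p <- make_params(sigma = diag(s2, 3))
  expect_equal(delta_g_release(p, 300), 0, tolerance = 1e-9)
  # closed form for isotropic sigma
  for (s in c(0.3, 1, 3)) {
    p <- make_params(sigma = diag(s^2, 3))
    expect_equal(delta_g_release(p, 300),
                 -kT * log((2 * pi * s^2)^(3 / 2) / v0), tolerance = 1e-9)
  }
  # tightening the restraint strictly increases the release cost
  grid <- vapply(c(4, 2, 1, 0.5, 0.25), function(s)
    delta_g_release(make_params(sigma = diag(s^2, 3)), 300), numeric(1))
  expect_true(all(diff(grid) > 0))
  # a rotational restraint adds a positive cost
  pz <- make_params(Z = c(0, -10, -10, -10))
  expect_gt(delta_g_release(pz, 300), delta_g_release(make_params(), 300))
})

test_that("restraints serialize to JSON and back", {
  set.seed(56)
  p <- make_params(mu = c(1, 2, 3), sigma = diag(c(1, 2, 3)),
                   M = rand_orthogonal4(), Z = c(0, -1, -2, -3))
  path <- tempfile(fileext = ".json")
  restraint_to_json(p, path)
  q <- restraint_from_json(path)
  expect_equal(q$mu, p$mu)
  expect_equal(q$sigma, p$sigma, tolerance = 1e-12)
  expect_equal(q$M, p$M, tolerance = 1e-12)
  expect_equal(q$Z, p$Z)
  # identical energies under the round trip
  z <- rigid_transform(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(restraint_energy(z, q), restraint_energy(z, p))
})
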