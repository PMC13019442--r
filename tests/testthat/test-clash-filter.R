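mk_top <- function(sigma, eps, role = "receptor") {
  n <- length(sigma)
  dbfe_topology(sprintf("A%d", 1:n), rep("C", n), sigma, eps, role = role)
}

test_that("clash cutoffs solve the repulsive-branch LJ equation", {
  set.seed(60)
  # single pairs against an independent bisection root finder
  for (i in 1:200) {
    sig <- runif(1, 2, 4); eps <- runif(1, 0.01, 1)
    cm <- compute_cutoff_matrix(mk_top(sig, eps), mk_top(sig, eps, "ligand"),
                                energy_threshold = 2)
    expect_lt(abs(cm$cutoffs[1, 1] - bisect_lj_cutoff(sig, eps, 2)), 1e-8)
    # the root lies on the repulsive branch
    expect_lt(cm$cutoffs[1, 1], 2^(1 / 6) * sig)
  }
  # mixed pairs: Lorentz-Berthelot combination
  rt <- mk_top(c(3.0, 3.8), c(0.2, 0.05))
  lt <- mk_top(c(2.6, 3.4, 4.0), c(0.1, 0.3, 0.0), "ligand")
  cm <- compute_cutoff_matrix(rt, lt, 2)
  for (i in 1:2) for (j in 1:2) {
    sig <- (rt$lj_sigma[i] + lt$lj_sigma[j]) / 2
    eps <- sqrt(rt$lj_epsilon[i] * lt$lj_epsilon[j])
    expect_lt(abs(cm$cutoffs[i, j] - bisect_lj_cutoff(sig, eps, 2)), 1e-8)
  }
  # epsilon = 0 pairs are exempt
  expect_equal(cm$cutoffs[, 3], c(0, 0))
})

test_that("the threshold-to-zero limit approaches the LJ zero crossing", {
  sig <- 3.5; eps <- 0.5
  for (thr in c(1, 0.1, 1e-3, 1e-6)) {
    cm <- compute_cutoff_matrix(mk_top(sig, eps), mk_top(sig, eps, "ligand"), thr)
    expect_lt(cm$cutoffs[1, 1], sig)
  }
  cm <- compute_cutoff_matrix(mk_top(sig, eps), mk_top(sig, eps, "ligand"), 1e-9)
  expect_equal(cm$cutoffs[1, 1], sig, tolerance = 1e-6)
  expect_error(compute_cutoff_matrix(mk_top(sig, eps), mk_top(sig, eps, "ligand"), 0),
               class = "dbfe_parameter_error")
})

test_that("pose budgets follow the target-pair arithmetic", {
  expect_equal(plan_pose_budget(100, 1000, 1e9), 1e4)
  expect_equal(plan_pose_budget(1, 1, 1e9), 1e9)
  expect_equal(plan_pose_budget(5e4, 5e4, 1e9), 1)  # floor clamp at 1
  expect_equal(plan_pose_budget(300, 300, 4.5e5), 5)
})

test_that("grid filter matches vectorized brute force on random instances", {
  set.seed(61)
  for (inst in 1:60) {
    P <- sample(10:60, 1); L <- sample(3:12, 1)
    rt <- mk_top(runif(P, 2.5, 4), runif(P, 0, 0.5) * rbinom(P, 1, 0.9))
    lt <- mk_top(runif(L, 2.5, 4), runif(L, 0, 0.5), "ligand")
    cm <- compute_cutoff_matrix(rt, lt, 2)
    frames <- lapply(1:3, function(i) matrix(runif(3 * P, -8, 8), ncol = 3))
    poses <- lapply(1:40, function(i) matrix(runif(3 * L, -9, 9), ncol = 3))
    res <- filter_frame_pairs(frames, poses, cm, batch_size = 17)
    stacked <- do.call(rbind, poses)
    want <- do.call(rbind, lapply(seq_along(frames), function(i) {
      ok <- brute_filter(frames[[i]], stacked, cm$cutoffs, L)
      if (!any(ok)) return(matrix(integer(0), 0, 2))
      cbind(i, which(ok))
    }))
    got <- res$passing_pairs
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(res$n_tested, 3 * 40)
    expect_equal(res$alpha, nrow(want) / 120)
  }
})

test_that("far-away poses all pass and coincident atoms fail", {
  P <- 10; L <- 4
  rt <- mk_top(rep(3.4, P), rep(0.1, P))
  lt <- mk_top(rep(3.4, L), rep(0.1, L), "ligand")
  cm <- compute_cutoff_matrix(rt, lt, 2)
  set.seed(62)
  frame <- matrix(runif(3 * P, -5, 5), ncol = 3)
  shift <- max(abs(frame)) + cm$max_cutoff + 1
  far <- lapply(1:20, function(i) matrix(runif(3 * L, shift, shift + 3), ncol = 3))
  res <- filter_frame_pairs(list(frame), far, cm)
  expect_equal(res$alpha, 1)
  ontop <- list(rbind(frame[1, ], matrix(shift, 3, 3)))
  res2 <- filter_frame_pairs(list(frame), ontop, cm)
  expect_equal(res2$alpha, 0)
})

test_that("raising the clash threshold shrinks cutoffs and raises alpha", {
  set.seed(63)
  P <- 30; L <- 5
  rt <- mk_top(runif(P, 3, 4), runif(P, 0.05, 0.3))
  lt <- mk_top(runif(L, 3, 4), runif(L, 0.05, 0.3), "ligand")
  frames <- lapply(1:5, function(i) matrix(runif(3 * P, -6, 6), ncol = 3))
  poses <- lapply(1:200, function(i) matrix(runif(3 * L, -6, 6), ncol = 3))
  thresholds <- c(0.5, 2, 8, 32)
  cms <- lapply(thresholds, function(th) compute_cutoff_matrix(rt, lt, th))
  for (k in 2:length(cms)) expect_true(all(cms[[k]]$cutoffs <= cms[[k - 1]]$cutoffs))
  alphas <- vapply(cms, function(cm)
    filter_frame_pairs(frames, poses, cm)$alpha, numeric(1))
  expect_true(all(diff(alphas) >= 0))
})

test_that("hard-sphere exclusion reproduces the analytic volume fraction", {
  # point receptor at the origin; poses uniform in a box enclosing the
  # exclusion sphere: alpha -> 1 - (4/3) pi c^3 / V
  sig <- 3.5; eps <- 0.3
  rt <- mk_top(sig, eps)
  lt <- mk_top(sig, eps, "ligand")
  cm <- compute_cutoff_matrix(rt, lt, 2)
  cc <- cm$cutoffs[1, 1]
  half <- 5
  V <- (2 * half)^3
  n <- 2e5
  set.seed(64)
  poses <- matrix(runif(3 * n, -half, half), ncol = 3)
  ok <- dbfe:::.clash_filter_poses_cpp(matrix(0, 1, 3), poses, cm$cutoffs, 1L)
  alpha_hat <- mean(ok)
  alpha_true <- 1 - (4 / 3) * pi * cc^3 / V
  se <- sqrt(alpha_true * (1 - alpha_true) / n)
  expect_lt(abs(alpha_hat - alpha_true), 4 * se)
  # and the corresponding free energy matches the analytic exclusion cost
  kT <- dbfe_constants()$kB * 300
  dg <- delta_g_filter(list(alpha = alpha_hat, n_tested = n), 300)
  expect_lt(abs(dg$dg - (-kT * log(alpha_true))), 4 * kT * se / alpha_true)
})

test_that("the filter free energy has the right arithmetic and failure mode", {
  kT <- dbfe_constants()$kB * 300
  expect_equal(delta_g_filter(list(alpha = 1, n_tested = 100))$dg, 0)
  got <- delta_g_filter(list(alpha = 0.5, n_tested = 1000), 300)
  expect_equal(got$dg, -0.0019872041 * 300 * log(0.5), tolerance = 1e-12)
  expect_equal(got$se, kT * sqrt(0.5 / (0.5 * 1000)), tolerance = 1e-12)
  expect_error(delta_g_filter(list(alpha = 0, n_tested = 1000)),
               class = "dbfe_no_overlap_error")
})
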