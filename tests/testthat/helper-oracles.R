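# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R brute force, closed forms, and textbook
# iterations.

# Bennett acceptance ratio through its maximum-likelihood (logistic
# regression) formulation: classify which state each pooled sample came
# from with the known slope and a free intercept; the intercept fit by
# stats::glm (IRLS -- an entirely separate solver) recovers delta_f.
# w_f = u_B(x) - u_A(x) on A-samples, w_r = u_A(x) - u_B(x) on B-samples.
bar_bennett <- function(w_f, w_r) {
  du <- c(w_f, -w_r)                       # u_B - u_A on all pooled samples
  y <- c(rep(0, length(w_f)), rep(1, length(w_r)))
  fit <- suppressWarnings(
    stats::glm(y ~ 1, offset = -du, family = stats::binomial()))
  unname(stats::coef(fit)[1]) - log(length(w_r) / length(w_f))
}

# exhaustive element-preserving automorphism search (molecules <= 8 atoms)
brute_automorphisms <- function(elements, bonds) {
  n <- length(elements)
  adj <- matrix(FALSE, n, n)
  if (NROW(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[bonds[k, 1], bonds[k, 2]] <- TRUE
      adj[bonds[k, 2], bonds[k, 1]] <- TRUE
    }
  }
  perms <- list()
  for (p in asplit(gtools_permutations(n), 1)) {
    if (any(elements[p] != elements)) next
    if (identical(adj[p, p], adj)) perms[[length(perms) + 1]] <- as.integer(p)
  }
  perms
}

# all permutations of 1..n (small n), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# independent bisection root finder for the LJ clash distance
bisect_lj_cutoff <- function(sigma, eps, threshold, tol = 1e-12) {
  f <- function(d) 4 * eps * ((sigma / d)^12 - (sigma / d)^6) - threshold
  lo <- 1e-6 * sigma; hi <- 2^(1 / 6) * sigma
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# vectorized brute-force clash check of many poses against one frame
brute_filter <- function(receptor, poses_stacked, cutoffs, L) {
  B <- nrow(poses_stacked) / L
  out <- logical(B)
  c2 <- cutoffs^2
  active <- cutoffs > 0
  for (b in seq_len(B)) {
    pl <- poses_stacked[((b - 1) * L + 1):(b * L), , drop = FALSE]
    d2 <- outer(rowSums(receptor^2), rowSums(pl^2), "+") -
      2 * (receptor %*% t(pl))
    out[b] <- !any(active & d2 < c2)
  }
  out
}

# minimal CHARMM-format DCD writer (binary fixture generated at test time)
write_minimal_dcd <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    tcon <- rawConnection(raw(0), "wb")
    writer(tcon)
    body <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(body), con, size = 4)
    writeBin(body, con)
    writeBin(length(body), con, size = 4)
  }
  n <- nrow(frames[[1]])
  rec(function(c2) {
    writeChar("CORD", c2, 4, eos = NULL)
    ints <- integer(20); ints[1] <- length(frames); ints[2] <- 1L
    ints[3] <- 1L; ints[4] <- length(frames)
    writeBin(ints, c2, size = 4)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(sprintf("%-80s", "toy fixture"), c2, 80, eos = NULL)
  })
  rec(function(c2) writeBin(n, c2, size = 4))
  for (f in frames) {
    for (d in 1:3) rec(function(c2) writeBin(as.numeric(f[, d]), c2, size = 4))
  }
  invisible(path)
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  quaternion_to_matrix(q)
}

# small shared toy pipeline fit (built once per test run)
toy_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- make_harmonic_host_guest(kind = "harmonic", seed = 5)
      rec <- direct_boltzmann_sample(spec, "receptor", 1500, seed = 11)
      lig <- direct_boltzmann_sample(spec, "ligand", 1500, seed = 12)
      cpx <- direct_boltzmann_sample(spec, "complex", 1500, seed = 13)
      fit <- dbfe(rec, lig, cpx, make_toy_backend(spec),
                  n_target = 1.5e5, n_s = 1500, n_receptor_max = 150,
                  n_ligand_max = 150, seed = 1)
      cache <<- list(spec = spec, fit = fit,
                     exact = exact_delta_g_quadrature(spec))
    }
    cache
  }
})
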