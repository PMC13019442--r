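#' Statistical inefficiency of a correlated time series
#'
#' Estimates `g = 1 + 2 * sum_t (1 - t/N) * C(t)`, the factor by which
#' correlated samples overcount independent ones, from the normalized
#' autocorrelation function `C(t)` of the observable. The sum is truncated
#' at the first lag where `C(t)` drops below zero, the standard
#' noise-robust truncation for molecular-simulation time series.
#'
#' @param x Numeric observable series.
#' @return `g >= 1` (dimensionless). A constant (zero-variance) series is
#'   treated as uncorrelated and returns 1.
#' @export
statistical_inefficiency <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) return(1)
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v <= .Machine$double.eps * max(1, mean(abs(x)))^2) return(1)
  # autocovariance via FFT (circular, zero-padded to linear)
  m <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:n] / m
  ac <- ac / ac[1]
  g <- 1
  for (t in 1:(n - 1)) {
    if (ac[t + 1] <= 0) break
    g <- g + 2 * (1 - t / n) * ac[t + 1]
  }
  max(1, g)
}

#' Detect the equilibrated region of a time series
#'
#' Scans candidate burn-in points on a geometric grid and picks the one
#' maximizing the number of effectively uncorrelated samples
#' `(N - t0) / g(x[t0+1..N])`, the standard automated equilibration
#' heuristic for molecular simulation data.
#'
#' @param x Numeric observable series.
#' @param min_burn_in Minimum number of frames to discard (default 0).
#' @return List with `t0` (frames discarded), `g` (statistical
#'   inefficiency of the retained region) and `n_effective`.
#' @export
detect_equilibration <- function(x, min_burn_in = 0) {
  n <- length(x)
  min_burn_in <- min(as.integer(min_burn_in), n - 2L)
  if (n < 3) return(list(t0 = max(0L, min_burn_in), g = 1, n_effective = n))
  cand <- unique(pmin(n - 2L, pmax(min_burn_in, as.integer(
    c(min_burn_in, round(exp(seq(0, log(max(1, n / 2)), length.out = 20)))))))
  )
  best <- NULL
  for (t0 in sort(cand)) {
    g <- statistical_inefficiency(x[(t0 + 1):n])
    neff <- (n - t0) / g
    if (is.null(best) || neff > best$n_effective + 1e-12) {
      best <- list(t0 = t0, g = g, n_effective = neff)
    }
  }
  best
}

#' Reduce an ensemble to effectively independent frames
#'
#' Drops an equilibration prefix (at least `min_burn_in` frames, chosen per
#' run by maximizing the effective sample count) and thins the remainder by
#' the statistical inefficiency of the supplied observable. Runs pooled
#' from independent sources are treated independently and re-pooled.
#'
#' @param ensemble A `"trajectory_ensemble"`.
#' @param observable Per-frame scalar series (same length as the ensemble).
#'   Defaults to the first principal component of the flattened coordinates,
#'   used when no energy backend is attached.
#' @param min_burn_in Minimum burn-in, in frames, per run (default 0).
#' @return The decorrelated `"trajectory_ensemble"`; the attribute
#'   `"decorrelation"` records per-run `t0`, `g`, and retained counts.
#' @export
decorrelate_frames <- function(ensemble, observable = NULL, min_burn_in = 0) {
  n <- length(ensemble$frames)
  if (is.null(observable)) {
    flat <- t(vapply(ensemble$frames, as.numeric,
                     numeric(3 * n_atoms(ensemble$topology))))
    flat <- sweep(flat, 2, colMeans(flat))
    s <- svd(flat, nu = 1, nv = 0)
    observable <- as.numeric(s$u[, 1] * s$d[1])
  }
  if (length(observable) != n) {
    stop_dbfe("parameter", "observable length must equal the frame count")
  }
  keep <- integer(0)
  info <- list()
  for (run in unique(ensemble$source_runs)) {
    pos <- which(ensemble$source_runs == run)
    if (length(pos) - min_burn_in < 2) {
      stop_dbfe("insufficient_data",
                sprintf("run '%s' has fewer than 2 frames after burn-in", run))
    }
    eq <- detect_equilibration(observable[pos], min_burn_in)
    post <- pos[(eq$t0 + 1):length(pos)]
    if (length(post) < 2) {
      stop_dbfe("insufficient_data",
                sprintf("run '%s' has fewer than 2 frames after burn-in", run))
    }
    stride <- max(1L, as.integer(round(eq$g)))
    sel <- post[seq(1, length(post), by = stride)]
    keep <- c(keep, sel)
    info[[run]] <- list(t0 = eq$t0, g = eq$g, n_in = length(pos),
                        n_kept = length(sel))
  }
  keep <- sort(keep)
  out <- ensemble_subset(ensemble, keep)
  attr(out, "decorrelation") <- info
  out
}

#' Randomly subsample an ensemble without replacement
#'
#' Identity when the ensemble already has at most `n` frames; otherwise a
#' uniform, seed-reproducible sample of `n` distinct frames (original order
#' preserved).
#'
#' @param ensemble A `"trajectory_ensemble"`.
#' @param n Target frame count (>= 1).
#' @param seed Integer seed.
#' @return A `"trajectory_ensemble"` with at most `n` frames.
#' @export
subsample_frames <- function(ensemble, n, seed = 1L) {
  if (n < 1) stop_dbfe("parameter", "n must be >= 1")
  m <- length(ensemble$frames)
  if (m <= n) return(ensemble)
  keep <- with_seed(seed, sort(sample.int(m, n)))
  ensemble_subset(ensemble, keep)
}
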