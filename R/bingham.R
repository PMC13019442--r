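# Bingham distribution on the unit quaternion sphere S^3: density
# proportional to exp(q' M Z M' q), with orthogonal axes M (4x4) and
# diagonal concentrations Z, gauge-fixed so max(Z) = 0 (the density is
# invariant to adding a constant to all concentrations). Antipodal
# symmetry (q == -q) makes it the natural rotation analogue of a Gaussian.

#' Log normalization constant of a Bingham density on S^3
#'
#' Computes `log C(Z)` with `C(Z) = integral over S^3 of exp(sum z_i q_i^2)`
#' for diagonal concentrations `z` (the constant depends on `M` only
#' through nothing -- the sphere measure is rotation invariant).
#'
#' @param z Numeric length-4 concentrations (any gauge; typically max 0).
#' @param rel_tol Relative tolerance of the quadrature (default 1e-8).
#' @return `log C(Z)` (dimensionless). `z = c(0,0,0,0)` gives `log(2*pi^2)`.
#' @details In hyperspherical coordinates the azimuthal integral has the
#'   closed form `2*pi*exp(s*(z3+z4)/2)*I0(s*(z3-z4)/2)`, reducing the
#'   problem to a smooth 2-D integral evaluated by tensor Gauss-Legendre
#'   quadrature with order doubling until the requested tolerance.
#' @export
bingham_log_constant <- function(z, rel_tol = 1e-8) {
  stopifnot(length(z) == 4, all(is.finite(z)))
  zmax <- max(z)
  z <- z - zmax  # gauge shift; restored at the end
  prev <- NA_real_
  for (ord in c(48, 96, 192, 384, 768)) {
    val <- .bingham_quad(z, ord)
    if (!is.na(prev) && abs(val - prev) < rel_tol) {
      return(val + zmax)
    }
    prev <- val
  }
  if (is.na(prev) || !is.finite(prev)) {
    stop_dbfe("numeric", "Bingham normalization quadrature failed to converge")
  }
  # final order difference above tolerance: report achieved accuracy
  warn_dbfe("numeric",
            sprintf("Bingham quadrature reached order 768 with residual %.1e",
                    abs(val - prev)))
  val + zmax
}

# tensor Gauss-Legendre evaluation of log C(z) at fixed order (z <= 0)
.bingham_quad <- function(z, ord) {
  gl <- .gauss_legendre(ord)
  # psi and theta both mapped from [0, pi]
  psi <- pi / 2 * (gl$x + 1); wpsi <- pi / 2 * gl$w
  theta <- psi; wtheta <- wpsi
  sp2 <- sin(psi)^2
  ct2 <- cos(theta)^2
  st2 <- sin(theta)^2
  # log integrand on the (psi x theta) grid, phi integrated analytically
  a <- outer(sp2, ct2) * z[2]                    # z2 sin^2psi cos^2theta
  s <- outer(sp2, st2)                           # sin^2psi sin^2theta
  b <- s * (z[3] + z[4]) / 2
  d <- s * (z[3] - z[4]) / 2
  logI0 <- log(besselI(abs(d), 0, expon.scaled = TRUE)) + abs(d)
  logf <- z[1] * (1 - sp2) + a + b + logI0 +
    log(outer(sin(psi)^2, sin(theta))) + log(2 * pi)
  m <- max(logf)
  m + log(sum(exp(logf - m) * outer(wpsi, wtheta)))
}

# Gauss-Legendre nodes/weights on [-1, 1]; Golub-Welsch via symmetric
# tridiagonal eigendecomposition. Cached per order.
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  out <- list(x = x, w = w)
  .gl_cache[[key]] <- out
  out
}

# gradient of log C wrt z (= E[q_i^2] under the Bingham), central differences
bingham_dlogC <- function(z, h = 1e-5) {
  vapply(1:4, function(i) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    (bingham_log_constant(zp) - bingham_log_constant(zm)) / (2 * h)
  }, numeric(1))
}

# Maximum-likelihood Bingham concentrations from scatter eigenvalues.
# ev: eigenvalues of E[q q'] sorted decreasing (sum 1). Returns z (gauge
# z[1] = 0, decreasing). Concave log-likelihood l(z) = sum z*ev - log C(z).
bingham_fit_concentrations <- function(ev, tol = 1e-8, z_floor = -5e3) {
  stopifnot(length(ev) == 4)
  if (any(ev < 1e-12)) {
    stop_dbfe("degenerate_fit",
              "quaternion scatter is rank deficient; cannot fit concentrations")
  }
  # classic starting guess: z_i ~ -1/(2 ev_i) + 1/(2 ev_1)
  z0 <- pmax(z_floor + 1, -1 / (2 * ev[2:4]) + 1 / (2 * ev[1]))
  nll <- function(zt) {
    zf <- c(0, zt)
    -(sum(zf * ev) - bingham_log_constant(zf))
  }
  grad <- function(zt) {
    zf <- c(0, zt)
    -(ev - bingham_dlogC(zf))[2:4]
  }
  fit <- stats::optim(z0, nll, gr = grad, method = "L-BFGS-B",
                      lower = rep(z_floor, 3), upper = rep(0, 3),
                      control = list(factr = 1e3, pgtol = tol))
  z <- c(0, pmin(0, fit$par))
  sort(z, decreasing = TRUE)
}

# ACG-envelope rejection sampler for the Bingham density prop. to
# exp(-sum lambda_i w_i^2) in the principal-axis frame (lambda = -z >= 0).
# Returns n x 4 coordinates in that frame. Kent-Ganeiber-Mardia scheme.
bingham_sample_axes <- function(lambda, n) {
  stopifnot(all(lambda >= 0))
  # envelope concentration b: sum 1/(b + 2 lambda_i) = 1, b in (0, 4]
  f <- function(b) sum(1 / (b + 2 * lambda)) - 1
  b <- if (all(lambda == 0)) 4 else stats::uniroot(f, c(1e-12, 4),
                                                   tol = 1e-12)$root
  omega <- 1 + 2 * lambda / b
  logM <- -(4 - b) / 2 + 2 * log(4 / b)
  out <- matrix(NA_real_, n, 4)
  got <- 0L
  tries <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    y <- matrix(stats::rnorm(4 * m), ncol = 4)
    y <- sweep(y, 2, sqrt(omega), "/")
    q <- y / sqrt(rowSums(y^2))
    qa <- rowSums(sweep(q^2, 2, lambda, "*"))     # q' Lambda q
    qo <- rowSums(sweep(q^2, 2, omega, "*"))      # q' Omega q
    logr <- -qa - logM + 2 * log(qo)
    acc <- log(stats::runif(m)) < logr
    k <- which(acc)
    if (length(k)) {
      k <- k[seq_len(min(length(k), n - got))]
      out[(got + 1):(got + length(k)), ] <- q[k, , drop = FALSE]
      got <- got + length(k)
    }
    tries <- tries + m
    if (tries > 1000 * n && got < max(1, n * 1e-3)) {
      stop_dbfe("concentration_overflow",
                "Bingham rejection sampler acceptance rate below 1e-3")
    }
  }
  out
}
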