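# Quaternion algebra. Convention used throughout the package: scalar-first
# unit quaternions q = (w, x, y, z), right-handed rotations, canonicalized
# to the hemisphere with nonnegative scalar part (q and -q encode the same
# rotation; the double cover is handled by antipodally symmetric densities).

#' Canonicalize a unit quaternion
#'
#' Maps a quaternion to its canonical double-cover representative: the
#' hemisphere with nonnegative scalar part, ties broken by requiring the
#' first nonzero component to be positive. `q` and `-q` always map to the
#' same representative.
#'
#' @param q Numeric length-4 quaternion, scalar first.
#' @return The canonical representative, normalized to unit length.
#' @export
canonical_quaternion <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) {
    stop_dbfe("degenerate_geometry", "zero-norm quaternion cannot be canonicalized")
  }
  q <- q / n
  tol <- 1e-12
  if (q[1] > tol) return(q)
  if (q[1] < -tol) return(-q)
  # scalar part is (numerically) zero: first nonzero component positive
  for (i in 2:4) {
    if (abs(q[i]) > tol) {
      return(if (q[i] > 0) q else -q)
    }
  }
  q
}

#' Convert a unit quaternion to a rotation matrix
#' @param q Numeric length-4 unit quaternion, scalar first.
#' @return 3x3 proper rotation matrix.
#' @export
quaternion_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a canonical unit quaternion
#' @param R 3x3 proper rotation matrix.
#' @return Canonical scalar-first unit quaternion.
#' @export
matrix_to_quaternion <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # Shepperd's method: pick the numerically largest pivot
  m <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  k <- which.max(m)
  if (k == 1) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (k == 2) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (k == 3) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  canonical_quaternion(q)
}

#' Draw quaternions uniformly on the rotation group
#'
#' Samples unit quaternions uniformly on S^3 (normalized 4-vectors of
#' standard normals), canonicalized. Uniform on S^3 corresponds to the Haar
#' measure on rotations under the double cover.
#'
#' @param n Number of quaternions.
#' @return `n x 4` matrix of canonical unit quaternions.
#' @export
random_quaternions <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  t(apply(q, 1, canonical_quaternion))
}

#' Construct a rigid-body transform
#'
#' A rigid transform `zeta = (t, q)` as used for the ligand pose: rotation
#' `q` about the reference-pose centroid followed by translation `t`.
#'
#' @param t Translation 3-vector (Angstrom).
#' @param q Unit quaternion (scalar first); canonicalized on construction.
#' @return Object of class `"rigid_transform"` with elements `t` and `q`.
#' @export
rigid_transform <- function(t = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  stopifnot(length(t) == 3, all(is.finite(t)))
  structure(list(t = as.numeric(t), q = canonical_quaternion(q)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: t = (%.4f, %.4f, %.4f) A, q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$t[1], x$t[2], x$t[3], x$q[1], x$q[2], x$q[3], x$q[4]))
  invisible(x)
}

# stack a list of rigid transforms into an n x 7 matrix (t, q)
zeta_matrix <- function(zetas) {
  do.call(rbind, lapply(zetas, function(z) c(z$t, z$q)))
}
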