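#' Optimal rigid superposition of two point sets
#'
#' Kabsch superposition: finds the proper rotation and translation that
#' minimize the (weighted) RMSD between `mobile` and `target`. Reflections
#' are excluded by the usual determinant sign correction, so the result is
#' always a physical rotation.
#'
#' @param mobile `N x 3` coordinates to be moved.
#' @param target `N x 3` coordinates to superpose onto.
#' @param weights Optional nonnegative per-atom weights.
#' @return A list with `rotation` (3x3 matrix), `q` (canonical quaternion),
#'   `translation` (3-vector such that `mobile %*% t(rotation) + translation`
#'   best matches `target`), and `rmsd` (the minimized weighted RMSD, in
#'   Angstrom).
#' @details At least 3 points not all collinear are required; degenerate
#'   geometries raise a `dbfe_degenerate_geometry_error`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(x, x + rep(c(1, 2, 3), each = 10))
#' fit$translation # ~ c(1, 2, 3)
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!is.numeric(mobile) || ncol(mobile) != 3 || ncol(target) != 3 ||
      nrow(mobile) != nrow(target)) {
    stop_dbfe("parameter", "mobile and target must be N x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3) {
    stop_dbfe("degenerate_geometry", "superposition needs at least 3 points")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_dbfe("parameter", "weights must be nonnegative with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  # collinearity check on the mobile set: rank of centered coords must be >= 2
  sv_a <- svd(A * sqrt(w))$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1e-8)) {
    stop_dbfe("degenerate_geometry",
              "point set is (nearly) collinear; rotation is not determined")
  }
  H <- crossprod(A * w, B)        # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)       # target ~ R %*% mobile
  tvec <- ct - as.numeric(R %*% cm)
  moved <- A %*% t(R)             # centered mobile rotated
  rmsd <- sqrt(sum(w * rowSums((moved - B)^2)))
  list(rotation = R, q = matrix_to_quaternion(R), translation = tvec,
       rmsd = rmsd)
}

# apply a superposition fit to arbitrary coordinates
apply_superposition <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

# invert a superposition fit
invert_superposition <- function(fit) {
  Rinv <- t(fit$rotation)
  list(rotation = Rinv, q = matrix_to_quaternion(Rinv),
       translation = -as.numeric(Rinv %*% fit$translation), rmsd = fit$rmsd)
}
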