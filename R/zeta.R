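#' Extract the rigid-body ligand transform from a complex frame
#'
#' Computes the rigid-body transformation `zeta = (t, q)` between the
#' ligand coordinates of a complex frame and those of a reference frame,
#' after superposing the pocket atoms of the current frame onto the
#' reference frame. Over all symmetry-equivalent atom permutations of the
#' ligand, the transform with the smallest RMSD is returned (ties broken
#' towards the lexicographically smallest permutation), so symmetric poses
#' map to the identity.
#'
#' @param complex_coords `N x 3` coordinates of the current complex frame.
#' @param reference_coords `N x 3` coordinates of the reference frame.
#' @param pocket_atoms Integer indices of the pocket (alignment) atoms,
#'   typically binding-site C-alpha atoms.
#' @param ligand_atoms Integer indices of the ligand atoms.
#' @param symmetry Optional `"symmetry_group"` for the ligand (identity
#'   only if `NULL`).
#' @return A `"rigid_transform"` with attributes `rmsd` (minimized ligand
#'   RMSD after transform), `permutation` (the winning atom permutation)
#'   and `rotation_defined` (`FALSE` when the ligand has fewer than 3
#'   non-collinear atoms, in which case `q` is the identity and only the
#'   translation is meaningful).
#' @details The rotation acts about the centroid of the reference-pose
#'   ligand, which decouples the translation and rotation components:
#'   `current = R (ref - c_ref) + c_ref + t` with
#'   `t = centroid(current) - c_ref` in pocket-aligned coordinates.
#' @seealso [apply_transform()] for the exact inverse operation.
#' @export
extract_zeta <- function(complex_coords, reference_coords, pocket_atoms,
                         ligand_atoms, symmetry = NULL) {
  complex_coords <- as.matrix(complex_coords)
  reference_coords <- as.matrix(reference_coords)
  if (!all(dim(complex_coords) == dim(reference_coords))) {
    stop_dbfe("parameter", "complex and reference frames must have equal atom counts")
  }
  align <- kabsch_superpose(complex_coords[pocket_atoms, , drop = FALSE],
                            reference_coords[pocket_atoms, , drop = FALSE])
  cur <- apply_superposition(align, complex_coords[ligand_atoms, , drop = FALSE])
  ref <- reference_coords[ligand_atoms, , drop = FALSE]
  perms <- if (is.null(symmetry)) list(seq_along(ligand_atoms)) else symmetry$permutations

  c_ref <- colMeans(ref)
  c_cur <- colMeans(cur)
  nl <- length(ligand_atoms)

  rotation_defined <- nl >= 3 &&
    svd(sweep(ref, 2, c_ref))$d[2] > 1e-8 * max(svd(sweep(ref, 2, c_ref))$d[1], 1e-8)

  best <- NULL
  for (p in perms) {
    if (!rotation_defined) {
      # rotation unresolvable: translation-only transform, RMSD about centroids
      r <- sqrt(mean(rowSums((sweep(ref[p, , drop = FALSE], 2, c_ref) -
                                sweep(cur, 2, c_cur))^2)))
      cand <- list(q = c(1, 0, 0, 0), rmsd = r)
    } else {
      fit <- kabsch_superpose(ref[p, , drop = FALSE], cur)
      cand <- list(q = fit$q, rmsd = fit$rmsd)
    }
    if (is.null(best) || cand$rmsd < best$rmsd - 1e-12) best <- cand
  }
  z <- rigid_transform(t = c_cur - c_ref, q = best$q)
  attr(z, "rmsd") <- best$rmsd
  attr(z, "permutation") <- NULL
  attr(z, "rotation_defined") <- rotation_defined
  z
}

#' Apply a rigid-body transform to the reference ligand pose
#'
#' Rotates the reference-pose ligand about its centroid by `q`, translates
#' the centroid by `t`, and (optionally) maps the result into a receptor
#' frame's own coordinate system via the inverse of that frame's pocket
#' alignment. On noise-free data this is the exact inverse of
#' [extract_zeta()].
#'
#' @param zeta A `"rigid_transform"`.
#' @param reference_ligand `N x 3` ligand coordinates of the reference pose
#'   (in reference-frame coordinates).
#' @param alignment Optional pocket-alignment fit (as returned by
#'   [kabsch_superpose()] for current-pocket onto reference-pocket); its
#'   inverse is applied so the pose lands in the current frame's lab
#'   coordinates. `NULL` keeps reference coordinates.
#' @return `N x 3` transformed ligand coordinates.
#' @export
apply_transform <- function(zeta, reference_ligand, alignment = NULL) {
  ref <- as.matrix(reference_ligand)
  c_ref <- colMeans(ref)
  R <- quaternion_to_matrix(zeta$q)
  out <- sweep(sweep(ref, 2, c_ref) %*% t(R), 2, c_ref + zeta$t, "+")
  if (!is.null(alignment)) {
    out <- apply_superposition(invert_superposition(alignment), out)
  }
  out
}
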