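#' Enumerate symmetry-equivalent atom permutations of a molecule
#'
#' Finds all element-preserving automorphisms of the molecular graph
#' (bonded connectivity). These are the atom relabelings under which the
#' molecule is chemically indistinguishable, e.g. the two hydrogens of
#' water or the two terminal carbons of propane. Rigid-body transform
#' extraction minimizes RMSD over this group so that symmetric ligand poses
#' are not spuriously penalized.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Two-column integer matrix of bonded atom index pairs
#'   (1-based), or `NULL`/zero rows for a single atom.
#' @param cap Maximum number of permutations to return (default 10000);
#'   highly symmetric graphs are truncated with a warning recorded in the
#'   result.
#' @return Object of class `"symmetry_group"`: a list with `permutations`
#'   (list of integer vectors, the identity first) and `truncated` (logical).
#' @details The search is a depth-first backtracking over candidate images
#'   refined by element and vertex degree; adjacency must be preserved
#'   exactly. The graph must be connected (a ligand is one molecule).
#' @examples
#' # water-like: O bonded to two H -> identity + H swap
#' g <- enumerate_symmetry_permutations(c("O", "H", "H"),
#'                                      rbind(c(1, 2), c(1, 3)))
#' length(g$permutations) # 2
#' @export
enumerate_symmetry_permutations <- function(elements, bonds, cap = 10000) {
  n <- length(elements)
  if (n == 0) stop_dbfe("parameter", "no atoms given")
  adj <- matrix(FALSE, n, n)
  if (!is.null(bonds) && NROW(bonds) > 0) {
    bonds <- as.matrix(bonds)
    if (any(bonds < 1) || any(bonds > n)) {
      stop_dbfe("parameter", "bond indices out of range")
    }
    for (k in seq_len(nrow(bonds))) {
      adj[bonds[k, 1], bonds[k, 2]] <- TRUE
      adj[bonds[k, 2], bonds[k, 1]] <- TRUE
    }
  }
  if (n > 1) {
    # connectivity check (BFS)
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) {
      stop_dbfe("format", "molecular graph is disconnected; ligand must be one molecule")
    }
  }
  deg <- rowSums(adj)
  # invariant signature per atom: element + degree (+ sorted neighbor elements)
  sig <- vapply(seq_len(n), function(i) {
    paste(elements[i], deg[i],
          paste(sort(elements[which(adj[i, ])]), collapse = ","), sep = "|")
  }, character(1))

  perms <- list()
  truncated <- FALSE
  mapping <- integer(n)  # mapping[i] = image of atom i; 0 = unset
  used <- logical(n)

  backtrack <- function(i) {
    if (truncated) return()
    if (i > n) {
      if (length(perms) >= cap) {
        truncated <<- TRUE
        return()
      }
      perms[[length(perms) + 1L]] <<- mapping
      return()
    }
    for (j in seq_len(n)) {
      if (used[j] || sig[j] != sig[i]) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (adj[i, k] != adj[j, mapping[k]]) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[i] <<- j; used[j] <<- TRUE
      backtrack(i + 1L)
      used[j] <<- FALSE; mapping[i] <<- 0L
      if (truncated) return()
    }
  }
  backtrack(1L)

  # identity first, then lexicographic order for determinism
  ord <- order(vapply(perms, function(p) paste(sprintf("%06d", p), collapse = ""),
                      character(1)))
  perms <- perms[ord]
  if (truncated) {
    warn_dbfe("truncation",
              sprintf("symmetry enumeration truncated at %d permutations", cap))
  }
  structure(list(permutations = perms, truncated = truncated),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat(sprintf("symmetry group: %d permutation(s)%s\n", length(x$permutations),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
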