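#' Construct a molecular topology
#'
#' A topology holds atom identities, Lennard-Jones parameters, and bonded
#' connectivity for one of the three species handled by the method:
#' receptor, ligand, or their complex. For a complex, atoms
#' `1..receptor_atom_count` are the receptor and the remainder the ligand.
#'
#' @param atom_names Character vector of atom identifiers.
#' @param elements Character vector of element symbols.
#' @param lj_sigma Per-atom Lennard-Jones sigma (Angstrom, >= 0).
#' @param lj_epsilon Per-atom Lennard-Jones epsilon (kcal/mol, >= 0).
#' @param bonds Two-column integer matrix of bonded pairs (1-based), or NULL.
#' @param role One of `"receptor"`, `"ligand"`, `"complex"`.
#' @param receptor_atom_count For `role = "complex"`, the number of leading
#'   receptor atoms (0 < count < total).
#' @return Object of class `"dbfe_topology"`.
#' @export
dbfe_topology <- function(atom_names, elements, lj_sigma, lj_epsilon,
                          bonds = NULL, role = c("receptor", "ligand", "complex"),
                          receptor_atom_count = NULL) {
  role <- match.arg(role)
  n <- length(atom_names)
  if (length(elements) != n || length(lj_sigma) != n || length(lj_epsilon) != n) {
    stop_dbfe("parameter", "atom_names, elements and LJ arrays must have equal length")
  }
  if (any(!is.finite(lj_sigma)) || any(!is.finite(lj_epsilon)) ||
      any(lj_sigma < 0) || any(lj_epsilon < 0)) {
    stop_dbfe("parameterization", "LJ parameters must be finite and nonnegative")
  }
  if (!is.null(bonds) && NROW(bonds) > 0) {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
    if (any(bonds < 1) || any(bonds > n)) {
      stop_dbfe("parameter", "bond indices out of range")
    }
  } else {
    bonds <- matrix(integer(0), ncol = 2)
  }
  if (role == "complex") {
    if (is.null(receptor_atom_count) || receptor_atom_count <= 0 ||
        receptor_atom_count >= n) {
      stop_dbfe("parameter",
                "complex topology needs 0 < receptor_atom_count < n_atoms")
    }
    receptor_atom_count <- as.integer(receptor_atom_count)
  }
  structure(list(atom_names = as.character(atom_names),
                 elements = as.character(elements),
                 lj_sigma = as.numeric(lj_sigma),
                 lj_epsilon = as.numeric(lj_epsilon),
                 bonds = bonds, role = role,
                 receptor_atom_count = receptor_atom_count),
            class = "dbfe_topology")
}

#' @export
print.dbfe_topology <- function(x, ...) {
  cat(sprintf("dbfe topology (%s): %d atoms, %d bonds\n", x$role,
              length(x$atom_names), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(topology) length(topology$atom_names)

receptor_indices <- function(topology) seq_len(topology$receptor_atom_count)

ligand_indices <- function(topology) {
  seq.int(topology$receptor_atom_count + 1L, n_atoms(topology))
}

#' Read Lennard-Jones parameters from a JSON sidecar
#'
#' The sidecar maps 1-based atom indices to `sigma` (Angstrom) and
#' `epsilon` (kcal/mol): `{"1": {"sigma": 3.4, "epsilon": 0.1}, ...}`.
#'
#' @param path JSON file path.
#' @param n_atoms Expected atom count.
#' @return List with numeric vectors `sigma` and `epsilon`.
#' @export
read_lj_sidecar <- function(path, n_atoms) {
  if (!file.exists(path)) stop_dbfe("format", sprintf("LJ sidecar not found: %s", path))
  raw <- jsonlite::read_json(path)
  sigma <- rep(NA_real_, n_atoms)
  epsilon <- rep(NA_real_, n_atoms)
  for (nm in names(raw)) {
    i <- suppressWarnings(as.integer(nm))
    if (is.na(i) || i < 1 || i > n_atoms) {
      stop_dbfe("parameterization", sprintf("LJ sidecar index '%s' out of range", nm))
    }
    sigma[i] <- as.numeric(raw[[nm]]$sigma)
    epsilon[i] <- as.numeric(raw[[nm]]$epsilon)
  }
  miss <- which(is.na(sigma) | is.na(epsilon))
  if (length(miss)) {
    stop_dbfe("parameterization",
              sprintf("missing LJ parameters for atom(s): %s",
                      paste(miss, collapse = ", ")))
  }
  list(sigma = sigma, epsilon = epsilon)
}

# parse CONECT records from raw PDB lines (bio3d does not expose them)
parse_conect <- function(lines, n) {
  con <- grep("^CONECT", lines, value = TRUE)
  out <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(substring(
      ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2) {
      for (j in flds[-1]) {
        a <- min(flds[1], j); b <- max(flds[1], j)
        out[[paste(a, b)]] <- c(a, b)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m <- m[m[, 1] >= 1 & m[, 2] <= n, , drop = FALSE]
  unname(m)
}

#' Read a molecular topology from file
#'
#' Receptor and complex topologies are read from PDB (CONECT records
#' honored); ligand topologies from SDF (one connected molecule required).
#' Lennard-Jones parameters are not stored in these formats and must be
#' supplied through a JSON sidecar (see [read_lj_sidecar()]); by default a
#' file named `<path>.lj.json` next to the structure is used.
#'
#' @param path Structure file (`.pdb` for receptor/complex, `.sdf` for
#'   ligand).
#' @param role One of `"receptor"`, `"ligand"`, `"complex"`.
#' @param lj Either a path to a JSON sidecar, a list with `sigma` and
#'   `epsilon` vectors, or `NULL` to use `<path>.lj.json`.
#' @param receptor_atom_count Required for `role = "complex"`.
#' @return A validated `"dbfe_topology"`.
#' @export
read_topology <- function(path, role = c("receptor", "ligand", "complex"),
                          lj = NULL, receptor_atom_count = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_dbfe("format", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") {
    stop_dbfe("format", "MOL2 input is not supported; convert the ligand to SDF")
  }
  if (role %in% c("receptor", "complex")) {
    if (ext != "pdb") {
      stop_dbfe("format", sprintf("%s topology must be a PDB file, got .%s", role, ext))
    }
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop_dbfe("format",
                      sprintf("unreadable PDB file %s: %s", path, conditionMessage(e))))
    atoms <- pdb$atom
    nm <- trimws(atoms$elety)
    el <- trimws(atoms$elesy)
    el[is.na(el) | el == ""] <- substr(gsub("[0-9]", "", nm[is.na(el) | el == ""]), 1, 1)
    bonds <- parse_conect(readLines(path), length(nm))
  } else {
    if (ext != "sdf") {
      stop_dbfe("format", sprintf("ligand topology must be an SDF file, got .%s", ext))
    }
    mol <- read_sdf_molecule(path)
    nm <- mol$names; el <- mol$elements; bonds <- mol$bonds
    # ligand must be a single connected molecule
    if (length(el) > 1) {
      comp <- connected_components(length(el), bonds)
      if (max(comp) > 1) {
        stop_dbfe("format", "ligand SDF contains disconnected components")
      }
    }
  }
  n <- length(nm)
  if (is.null(lj)) lj <- paste0(path, ".lj.json")
  if (is.character(lj)) lj <- read_lj_sidecar(lj, n)
  if (length(lj$sigma) != n || length(lj$epsilon) != n) {
    stop_dbfe("parameterization",
              sprintf("LJ parameter count (%d) does not match atom count (%d)",
                      length(lj$sigma), n))
  }
  dbfe_topology(atom_names = nm, elements = el, lj_sigma = lj$sigma,
                lj_epsilon = lj$epsilon, bonds = bonds, role = role,
                receptor_atom_count = receptor_atom_count)
}

# minimal V2000 SDF molecule reader used when ChemmineR is unavailable;
# with ChemmineR installed the parsed blocks come from read.SDFset.
read_sdf_molecule <- function(path) {
  if (requireNamespace("ChemmineR", quietly = TRUE)) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                    error = function(e) NULL)
    if (!is.null(sdf) && length(sdf) >= 1) {
      ab <- ChemmineR::atomblock(sdf[[1]])
      bb <- ChemmineR::bondblock(sdf[[1]])
      el <- gsub("_.*$", "", rownames(ab))
      bonds <- if (NROW(bb) > 0) {
        matrix(as.integer(as.matrix(bb[, 1:2, drop = FALSE])), ncol = 2)
      } else matrix(integer(0), ncol = 2)
      return(list(names = rownames(ab), elements = el, bonds = bonds,
                  coords = unname(as.matrix(ab[, 1:3, drop = FALSE]))))
    }
  }
  lines <- readLines(path)
  if (length(lines) < 4) stop_dbfe("format", sprintf("unreadable SDF file: %s", path))
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4 + na + nb) {
    stop_dbfe("format", sprintf("malformed SDF counts line in %s", path))
  }
  atom_lines <- lines[5:(4 + na)]
  el <- trimws(substr(atom_lines, 32, 34))
  coords <- t(vapply(atom_lines, function(l) {
    as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30)))
  }, numeric(3)))
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
  } else matrix(integer(0), ncol = 2)
  list(names = paste0(el, seq_len(na)), elements = el, bonds = bonds,
       coords = unname(coords))
}

connected_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- vector("list", n)
  if (NROW(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
      adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
    }
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][comp[adj[[v]]] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
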