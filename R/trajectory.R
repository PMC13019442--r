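#' Construct a trajectory ensemble
#'
#' An ordered collection of frames sharing one topology, with provenance of
#' the independent runs it was pooled from.
#'
#' @param topology A `"dbfe_topology"`.
#' @param frames List of `N x 3` coordinate matrices (Angstrom).
#' @param source_runs Character vector of run identifiers, one per frame
#'   (recycled from a single id).
#' @param indices Optional original frame indices (0-based positions in the
#'   source trajectory); defaults to `0:(n-1)`.
#' @return Object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(topology, frames, source_runs = "run1",
                                indices = NULL) {
  stopifnot(inherits(topology, "dbfe_topology"))
  if (length(frames) < 1) stop_dbfe("empty_trajectory", "ensemble needs at least one frame")
  na <- n_atoms(topology)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3 || !all(is.finite(f))) {
      stop_dbfe("topology",
                sprintf("every frame must be a finite %d x 3 matrix", na))
    }
  }
  if (length(source_runs) == 1) source_runs <- rep(source_runs, length(frames))
  if (length(source_runs) != length(frames)) {
    stop_dbfe("parameter", "source_runs must have one id per frame")
  }
  if (is.null(indices)) indices <- seq_along(frames) - 1L
  structure(list(topology = topology, frames = frames,
                 source_runs = as.character(source_runs),
                 indices = as.integer(indices)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory ensemble: %d frames, %d atoms (%s), %d run(s)\n",
              length(x$frames), n_atoms(x$topology), x$topology$role,
              length(unique(x$source_runs))))
  invisible(x)
}

#' @export
length.trajectory_ensemble <- function(x) length(x$frames)

# subset an ensemble by frame positions, keeping provenance
ensemble_subset <- function(ensemble, keep) {
  trajectory_ensemble(ensemble$topology, ensemble$frames[keep],
                      ensemble$source_runs[keep], ensemble$indices[keep])
}

#' Read trajectory frames from file(s)
#'
#' Supported formats: the package's plain-text multi-frame XYZ format
#' (`.xyz`, see [write_trajectory_xyz()]) and binary DCD (`.dcd`, read via
#' the bio3d adapter). Multiple files for the same topology are
#' concatenated in order with run provenance recorded per file.
#'
#' @param paths Character vector of trajectory file paths.
#' @param topology The matching `"dbfe_topology"`.
#' @return A `"trajectory_ensemble"` with frames in file order and
#'   `source_runs` naming the originating file of each frame.
#' @export
read_trajectory <- function(paths, topology) {
  frames <- list(); runs <- character(0)
  for (path in paths) {
    if (!file.exists(path)) stop_dbfe("format", sprintf("file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    fr <- switch(ext,
      xyz = read_xyz_frames(path),
      dcd = read_dcd_frames(path),
      stop_dbfe("format", sprintf("unsupported trajectory format: .%s", ext))
    )
    if (!length(fr)) stop_dbfe("empty_trajectory", sprintf("no frames in %s", path))
    na <- n_atoms(topology)
    for (f in fr) {
      if (nrow(f) != na) {
        stop_dbfe("topology",
                  sprintf("%s has %d-atom frames but topology has %d atoms",
                          path, nrow(f), na))
      }
    }
    frames <- c(frames, fr)
    runs <- c(runs, rep(basename(path), length(fr)))
  }
  trajectory_ensemble(topology, frames, runs)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1 || i + 1L + na > nl) {
      stop_dbfe("format", sprintf("malformed XYZ block at line %d of %s", i, path))
    }
    block <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop_dbfe("format", sprintf("non-numeric coordinates near line %d of %s", i, path))
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  frames
}

read_dcd_frames <- function(path) {
  dcd <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                  error = function(e) stop_dbfe("format",
                    sprintf("unreadable DCD file %s: %s", path, conditionMessage(e))))
  lapply(seq_len(nrow(dcd)), function(i) matrix(dcd[i, ], ncol = 3, byrow = TRUE))
}

#' Write frames in the plain-text multi-frame XYZ format
#'
#' Each frame is a block: atom count line, comment line (`frame <i>`), then
#' one `element x y z` line per atom with coordinates printed to 1e-6
#' Angstrom.
#'
#' @param ensemble A `"trajectory_ensemble"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(ensemble, path) {
  el <- ensemble$topology$elements
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ensemble$frames)) {
    f <- ensemble$frames[[k]]
    writeLines(c(sprintf("%d", nrow(f)), sprintf("frame %d", ensemble$indices[k]),
                 sprintf("%s %.6f %.6f %.6f", el, f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}
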