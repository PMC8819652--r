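#' Multi-chain trajectory container
#'
#' Time-ordered coordinates of one or more chains in a periodic cubic box.
#' Coordinates are stored as an array `n_frames x n_atoms x 3` in Angstrom;
#' times in ns must be strictly increasing and uniformly spaced.
#'
#' @param times frame times, ns
#' @param coords array `n_frames x n_atoms x 3`, A
#' @param box_edge cubic box edge, A (scalar)
#' @param chain_id integer or factor chain label per atom
#' @param masses atomic masses, Da (default 1)
#' @param element element symbol per atom (default `"H"`)
#' @param wrapped logical: are coordinates wrapped into the box?
#' @return object of class `"chain_ensemble_trajectory"`
#' @export
chain_ensemble_trajectory <- function(times, coords, box_edge, chain_id,
                                      masses = NULL, element = NULL,
                                      wrapped = TRUE) {
  d <- dim(coords)
  stopifnot(length(d) == 3L, d[3] == 3L, d[1] == length(times),
            length(chain_id) == d[2], box_edge > 0, all(is.finite(coords)))
  dt <- diff(times)
  if (length(dt) > 0) {
    stopifnot(all(dt > 0))
    if (max(dt) - min(dt) > 1e-9 * max(dt)) {
      stop("frame times must be uniformly spaced")
    }
  }
  if (is.null(masses)) masses <- rep(1, d[2])
  if (is.null(element)) element <- rep("H", d[2])
  structure(list(times = times, coords = coords, box_edge = box_edge,
                 chain_id = as.integer(factor(chain_id)),
                 masses = masses, element = element, wrapped = wrapped),
            class = "chain_ensemble_trajectory")
}

#' @export
print.chain_ensemble_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<chain_ensemble_trajectory> %d frames, %d atoms, ",
                     "%d chains, box %.1f A, dt %.4g ns (%s)\n"),
              dim(x$coords)[1], dim(x$coords)[2],
              length(unique(x$chain_id)), x$box_edge,
              if (length(x$times) > 1) diff(x$times)[1] else NA,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Wrap coordinates into the periodic box
#'
#' @param traj a [chain_ensemble_trajectory()]
#' @return trajectory with all coordinates folded into `[0, box_edge)`
#' @export
wrap_trajectory <- function(traj) {
  traj$coords <- traj$coords %% traj$box_edge
  traj$wrapped <- TRUE
  traj
}

#' Unwrap a periodic trajectory into continuous paths
#'
#' Restores continuity across the periodic boundary by accumulating
#' minimum-image frame-to-frame displacements per atom.  Refuses input whose
#' frame-to-frame displacement reaches half the box edge (undersampled).
#'
#' @param traj a [chain_ensemble_trajectory()]
#' @return trajectory with continuous (unwrapped) coordinates
#' @export
unwrap_trajectory <- function(traj) {
  L <- traj$box_edge
  x <- traj$coords
  n <- dim(x)[1]
  if (n < 2) { traj$wrapped <- FALSE; return(traj) }
  d <- x[-1, , , drop = FALSE] - x[-n, , , drop = FALSE]
  d <- d - L * round(d / L)
  if (max(abs(d)) >= L / 2 - 1e-9) {
    stop("frame-to-frame displacement >= box_edge/2: trajectory undersampled,",
         " cannot unwrap unambiguously")
  }
  out <- x
  for (k in 2:n) out[k, , ] <- out[k - 1, , ] + d[k - 1, , ]
  traj$coords <- out
  traj$wrapped <- FALSE
  traj
}

#' Read and write the XYZ-with-box trajectory dialect
#'
#' Plain-text extended XYZ: per frame an atom count line, a comment line
#' `time=<ns> box=<A>`, then `element chain mass x y z` rows in Angstrom.
#'
#' @param traj a [chain_ensemble_trajectory()]
#' @param path file path
#' @return `read_xyz_trajectory()` returns the trajectory;
#'   `write_xyz_trajectory()` returns `path` invisibly
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  n_at <- dim(traj$coords)[2]
  for (k in seq_along(traj$times)) {
    writeLines(as.character(n_at), con)
    writeLines(sprintf("time=%.9g box=%.9g wrapped=%d", traj$times[k],
                       traj$box_edge, as.integer(traj$wrapped)), con)
    writeLines(sprintf("%s %d %.9g %.9g %.9g %.9g",
                       traj$element, traj$chain_id, traj$masses,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("corrupt trajectory file '", path,
                              "': fewer than 2 lines")
  pos <- 1L; frame <- 0L
  coords <- list(); times <- numeric(0); box <- NA; wrapped <- TRUE
  meta <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n_at <- suppressWarnings(as.integer(lines[pos]))
    frame <- frame + 1L
    if (is.na(n_at) || pos + 1L + n_at > length(lines)) {
      stop("corrupt trajectory file '", path, "' at frame ", frame,
           " (line ", pos, ")")
    }
    hdr <- lines[pos + 1L]
    tm <- as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", hdr))
    bx <- as.numeric(sub(".*box=([-0-9.eE+]+).*", "\\1", hdr))
    wr <- grepl("wrapped=1", hdr)
    body <- lines[(pos + 2L):(pos + 1L + n_at)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) != 6L)) {
      stop("corrupt trajectory file '", path, "' at frame ", frame,
           ": malformed atom record")
    }
    m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
    xyz <- suppressWarnings(matrix(as.numeric(m[, 4:6]), ncol = 3))
    if (any(!is.finite(xyz))) {
      stop("corrupt trajectory file '", path, "' at frame ", frame,
           ": non-numeric coordinates")
    }
    if (is.null(meta)) meta <- list(element = m[, 1],
                                    chain = as.integer(m[, 2]),
                                    mass = as.numeric(m[, 3]))
    times <- c(times, tm); box <- bx; wrapped <- wr
    coords[[frame]] <- xyz
    pos <- pos + 2L + n_at
  }
  arr <- array(NA_real_, c(length(times), nrow(coords[[1]]), 3))
  for (k in seq_along(coords)) arr[k, , ] <- coords[[k]]
  chain_ensemble_trajectory(times, arr, box, meta$chain, meta$mass,
                            meta$element, wrapped = wrapped)
}

# per-frame, per-chain mass-weighted center of mass: n_frames x n_chains x 3
.chain_coms <- function(traj) {
  ids <- sort(unique(traj$chain_id))
  n_f <- dim(traj$coords)[1]
  out <- array(NA_real_, c(n_f, length(ids), 3))
  for (j in seq_along(ids)) {
    sel <- traj$chain_id == ids[j]
    mw <- traj$masses[sel] / sum(traj$masses[sel])
    for (ax in 1:3) {
      sl <- traj$coords[, sel, ax, drop = FALSE]
      dim(sl) <- dim(sl)[1:2]
      out[, j, ax] <- as.vector(sl %*% mw)
    }
  }
  out
}
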