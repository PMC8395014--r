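#' Trajectory container
#'
#' Holds a coordinate tensor (`n_frames x n_atoms x 3`, Angstrom) aligned to
#' the atom order of an [md_structure()], together with per-frame times (ns)
#' and a replicate id.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`.
#' @param times Numeric vector of frame times in ns (default `1..n * dt`).
#' @param dt Frame spacing in ns, used when `times` is `NULL`.
#' @param replicate Integer replicate id.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, times = NULL, dt = 1, replicate = 1L) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  n <- dim(coords)[1]
  if (n < 1) stop("trajectory must have at least one frame")
  if (is.null(times)) times <- seq_len(n) * dt
  stopifnot(length(times) == n)
  structure(list(coords = coords, times = as.numeric(times),
                 replicate = as.integer(replicate)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("md_trajectory: replicate %d, %d frames x %d atoms, %.4g-%.4g ns\n",
              x$replicate, d[1], d[2], x$times[1], x$times[d[1]]))
  invisible(x)
}

#' Number of frames
#' @param trajectory An `md_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

## Trailing analysis window --------------------------------------------------

#' Frame indices of a trailing analysis window
#'
#' Selects the last `floor(window_ns / dt)` frames (fractional frames round
#' down), or the last `floor(frac * n_frames)` frames. With both `NULL` the
#' whole trajectory is used, so trailing-window and whole-trajectory
#' statistics coincide.
#'
#' @param trajectory An `md_trajectory`.
#' @param window_ns Trailing duration in ns, or `NULL`.
#' @param frac Trailing fraction of frames in (0, 1], or `NULL`.
#' @return Integer vector of frame indices.
#' @export
window_frames <- function(trajectory, window_ns = NULL, frac = NULL) {
  n <- n_frames(trajectory)
  if (is.null(window_ns) && is.null(frac)) return(seq_len(n))
  if (!is.null(window_ns)) {
    dt <- if (n > 1) stats::median(diff(trajectory$times)) else trajectory$times[1]
    k <- floor(window_ns / dt)
  } else {
    k <- floor(frac * n)
  }
  if (k < 1) stop("analysis window selects no frames")
  if (k > n) stop("analysis window is longer than the trajectory")
  seq.int(n - k + 1L, n)
}

## Trajectory I/O ------------------------------------------------------------

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory An `md_trajectory`.
#' @param structure The matching `md_structure` (atom order and names).
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(trajectory, structure, path) {
  stopifnot(dim(trajectory$coords)[2] == n_atoms(structure))
  nf <- n_frames(trajectory)
  blocks <- vapply(seq_len(nf), function(t) {
    paste(c(sprintf("MODEL     %4d", t),
            .pdb_atom_lines(structure, trajectory$coords[t, , ]),
            "ENDMDL"), collapse = "\n")
  }, character(1))
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Write a trajectory as a whitespace XYZ file
#'
#' Classic XYZ: per frame an atom count line, a comment line carrying the
#' frame time, then `element x y z` records (6 decimals).
#'
#' @inheritParams write_trajectory_pdb
#' @export
write_trajectory_xyz <- function(trajectory, structure, path) {
  stopifnot(dim(trajectory$coords)[2] == n_atoms(structure))
  na <- n_atoms(structure)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(trajectory))) {
    xyz <- trajectory$coords[t, , ]
    writeLines(c(sprintf("%d", na),
                 sprintf("t= %.6f ns replicate= %d",
                         trajectory$times[t], trajectory$replicate),
                 sprintf("%-2s %14.6f %14.6f %14.6f",
                         structure$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}

.read_traj_pdb <- function(path, structure, dt, replicate) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0 || ncol(xyz) == 0) stop("empty trajectory file: ", path)
  na <- ncol(xyz) / 3
  if (na != n_atoms(structure)) {
    stop(sprintf("atom-count mismatch at frame 1 of %s: %d vs %d expected",
                 path, na, n_atoms(structure)))
  }
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
  }
  md_trajectory(coords, dt = dt, replicate = replicate)
}

.read_traj_xyz <- function(path, structure, dt, replicate) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  na_ref <- n_atoms(structure)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  t <- 0L
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    t <- t + 1L
    if (is.na(na)) stop(sprintf("malformed XYZ atom count at frame %d", t))
    if (na != na_ref) {
      stop(sprintf("atom-count mismatch at frame %d of %s: %d vs %d expected",
                   t, path, na, na_ref))
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t= *([0-9.eE+-]+)", comment))[[1]]
    times[t] <- if (length(tm) == 2) as.numeric(tm[2]) else t * dt
    body <- lines[(i + 2L):(i + 1L + na)]
    if (length(body) != na || anyNA(body)) {
      stop(sprintf("truncated XYZ frame %d", t))
    }
    m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"), function(f) {
      as.numeric(f[2:4])
    }))
    frames[[t]] <- m
    i <- i + 2L + na
  }
  coords <- array(NA_real_, dim = c(length(frames), na_ref, 3))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  md_trajectory(coords, times = times, replicate = replicate)
}

#' Read replicate trajectories
#'
#' Reads one trajectory per file; multi-model PDB (`.pdb`) and per-frame
#' whitespace XYZ (`.xyz`) are supported. Frame times come from XYZ metadata
#' when present, otherwise a uniform `dt` spacing.
#'
#' @param paths Character vector of trajectory files (one replicate each).
#' @param structure The matching `md_structure`.
#' @param dt Frame spacing in ns used when the file carries no times.
#' @return List of `md_trajectory`, replicate ids in file order.
#' @export
read_trajectory <- function(paths, structure, dt = 1) {
  lapply(seq_along(paths), function(r) {
    path <- paths[r]
    if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
      .read_traj_xyz(path, structure, dt, r)
    } else {
      .read_traj_pdb(path, structure, dt, r)
    }
  })
}
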