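# Trajectory container and file formats (MTRAJ text dialect, DCD).

#' Build a trajectory
#'
#' @param top a `mem_topology`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param box per-frame orthorhombic box: `n_frames x 3` matrix or a length-3
#'   vector recycled to all frames (Angstrom).
#' @param dt frame spacing in ps (> 0).
#' @param start_time time of the first frame in ps.
#' @return object of class `mem_trajectory` with elements `topology`,
#'   `coords`, `box`, `times`, `dt`, `n_frames`.
#' @export
trajectory <- function(top, coords, box, dt, start_time = 0) {
  stopifnot(inherits(top, "mem_topology"))
  check_scalar_number(dt, "dt", positive = TRUE)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort("`coords` must be an n_atoms x 3 x n_frames array.")
  }
  if (dim(coords)[1] != top$n_atoms) {
    abort(sprintf("`coords` has %d atoms but topology has %d.",
                  dim(coords)[1], top$n_atoms))
  }
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L) {
    abort("`box` must be n_frames x 3 (or a length-3 vector).")
  }
  if (any(box <= 0)) abort("Box lengths must be > 0.")
  structure(
    list(topology = top, coords = coords, box = box,
         times = start_time + dt * (seq_len(n_frames) - 1),
         dt = dt, n_frames = n_frames),
    class = "mem_trajectory"
  )
}

#' @export
print.mem_trajectory <- function(x, ...) {
  cat(sprintf("<mem_trajectory> %d frames x %d atoms, dt = %g ps, span %g ps\n",
              x$n_frames, dim(x$coords)[1], x$dt,
              x$times[x$n_frames] - x$times[1]))
  invisible(x)
}

# Coordinates of one frame as an n_atoms x 3 matrix (drop-safe).
frame_coords <- function(traj, frame_index) {
  matrix(traj$coords[, , frame_index], ncol = 3L)
}

#' Read a trajectory file
#'
#' Supports the binary CHARMM/NAMD DCD dialect (via bio3d's reader) and the
#' MTRAJ plain-text dialect (header `#mtraj v1 natoms=<N> dt_ps=<dt>`, then per
#' frame one `box Lx Ly Lz` line followed by `atom_id x y z` lines).
#'
#' @param top the `mem_topology` the frames belong to; atom counts must match.
#' @param path trajectory file; format from extension (`.dcd` vs anything
#'   else = MTRAJ text).
#' @param dt frame spacing in ps; overrides any file metadata. For MTRAJ
#'   files, defaults to the header value.
#' @return a `mem_trajectory`.
#' @export
read_trajectory <- function(top, path, dt = NULL) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    read_trajectory_dcd(top, path, dt)
  } else {
    read_trajectory_mtraj(top, path, dt)
  }
}

read_trajectory_dcd <- function(top, path, dt) {
  if (is.null(dt)) abort("`dt` (ps) is required for DCD input.")
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- bio3d::read.dcd(path, verbose = FALSE, cell = TRUE)
  n_atoms <- ncol(xyz) / 3L
  if (n_atoms != top$n_atoms) {
    abort(sprintf("DCD has %d atoms per frame but topology has %d (frame 1).",
                  n_atoms, top$n_atoms))
  }
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  trajectory(top, coords, box = cell[, 1:3, drop = FALSE], dt = dt)
}

read_trajectory_mtraj <- function(top, path, dt) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#mtraj v1 ", lines[1])) {
    abort("Not an MTRAJ file: missing '#mtraj v1' header.")
  }
  hdr <- lines[1]
  natoms <- as.integer(sub(".*natoms=([0-9]+).*", "\\1", hdr))
  dt_hdr <- as.numeric(sub(".*dt_ps=([0-9.eE+-]+).*", "\\1", hdr))
  if (is.null(dt)) dt <- dt_hdr
  if (natoms != top$n_atoms) {
    abort(sprintf("MTRAJ header natoms=%d but topology has %d atoms.",
                  natoms, top$n_atoms))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  per_frame <- natoms + 1L
  if (length(body) %% per_frame != 0L) {
    abort(sprintf("Truncated MTRAJ file: %d lines is not a multiple of %d (frame %d incomplete).",
                  length(body), per_frame, length(body) %/% per_frame + 1L))
  }
  n_frames <- length(body) %/% per_frame
  coords <- array(NA_real_, c(natoms, 3L, n_frames))
  box <- matrix(NA_real_, n_frames, 3L)
  for (f in seq_len(n_frames)) {
    block <- body[((f - 1L) * per_frame + 1L):(f * per_frame)]
    if (!grepl("^box ", block[1])) {
      abort(sprintf("Frame %d: expected 'box' line, got '%s'.", f, block[1]))
    }
    box[f, ] <- as.numeric(strsplit(trimws(block[1]), "\\s+")[[1]][2:4])
    fields <- strsplit(trimws(block[-1]), "\\s+")
    nf <- lengths(fields)
    if (any(nf != 4L)) {
      abort(sprintf("Frame %d: malformed atom line (%d fields).", f, nf[nf != 4L][1]))
    }
    m <- matrix(as.numeric(unlist(fields)), ncol = 4L, byrow = TRUE)
    ord <- order(m[, 1])
    coords[, , f] <- m[ord, 2:4]
  }
  trajectory(top, coords, box, dt = dt)
}

#' Write a trajectory in the MTRAJ text dialect
#'
#' @param traj a `mem_trajectory`.
#' @param path output file.
#' @param digits decimal places for coordinates (>= 4 per the dialect).
#' @return `path`, invisibly.
#' @export
write_trajectory_mtraj <- function(traj, path, digits = 6L) {
  stopifnot(inherits(traj, "mem_trajectory"))
  if (digits < 4L) abort("MTRAJ requires >= 4 decimal places.")
  ids <- traj$topology$atoms$atom_id
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%d %.", digits, "f %.", digits, "f %.", digits, "f")
  writeLines(sprintf("#mtraj v1 natoms=%d dt_ps=%g", traj$topology$n_atoms,
                     traj$dt), con)
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("box %.6f %.6f %.6f", traj$box[f, 1], traj$box[f, 2],
                       traj$box[f, 3]), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(fmt, ids, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as a CHARMM-dialect DCD file
#'
#' Little-endian binary DCD with a per-frame unit-cell block (orthorhombic),
#' readable by standard MD tooling.
#'
#' @param traj a `mem_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "mem_trajectory"))
  n_atoms <- traj$topology$n_atoms
  n_frames <- traj$n_frames
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header record: "CORD" + 20 control integers
  icntrl <- integer(20)
  icntrl[1] <- n_frames   # NFILE
  icntrl[2] <- 1L         # ISTART
  icntrl[3] <- 1L         # NSAVC
  icntrl[4] <- n_frames   # NSTEP
  icntrl[11] <- 1L        # unit-cell block present
  icntrl[20] <- 24L       # CHARMM version stamp
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(icntrl)
  wint(84L)
  # title record
  title <- formatC("memlipid trajectory", width = 80L, flag = "-")
  wint(80L + 4L)
  wint(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wint(80L + 4L)
  # natom record
  wint(4L)
  wint(n_atoms)
  wint(4L)
  for (f in seq_len(n_frames)) {
    # unit cell: {a, cos(gamma), b, cos(beta), cos(alpha), c}
    u <- c(traj$box[f, 1], 0, traj$box[f, 2], 0, 0, traj$box[f, 3])
    wint(48L)
    writeBin(as.numeric(u), con, size = 8L, endian = "little")
    wint(48L)
    xyz <- frame_coords(traj, f)
    for (k in 1:3) {
      wint(4L * n_atoms)
      writeBin(as.numeric(xyz[, k]), con, size = 4L, endian = "little")
      wint(4L * n_atoms)
    }
  }
  invisible(path)
}
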