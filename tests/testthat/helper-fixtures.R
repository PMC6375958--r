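# Shared builders and independent brute-force oracles.

# Quiet topology constructor for toy systems built in code.
toy_topology <- function(atoms, ...) {
  suppressWarnings(topology(atoms, ...))
}

# One-frame (or multi-frame) trajectory from an atom table and coordinate
# array; coords may be an n x 3 matrix (single frame).
toy_trajectory <- function(atoms, coords, box = c(100, 100, 100), dt = 10,
                           ...) {
  top <- toy_topology(atoms, ...)
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, c(nrow(coords), 3L, 1L))
  }
  trajectory(top, coords, box = box, dt = dt)
}

# Atom-table helpers ---------------------------------------------------------

protein_atom_row <- function(id, name, resname, resnum, chain = "A",
                             element = substr(name, 1, 1)) {
  data.frame(atom_id = id, atom_name = name, element = element,
             resname = resname, resnum = resnum, chain = chain)
}

lipid_bead_rows <- function(ids, resnums, species = "POPA", chain = "L") {
  data.frame(atom_id = ids, atom_name = "P", element = "P",
             resname = species, resnum = resnums, chain = chain)
}

# Build a contact_series directly from a residues x lipids x frames logical
# array (unit-testing the event logic without any geometry).
manual_series <- function(arr, dt = 10, species = NULL) {
  np <- dim(arr)[1]; nl <- dim(arr)[2]
  if (is.null(species)) species <- rep("POPA", nl)
  structure(
    list(
      contact = arr,
      residues = tibble::tibble(chain = "A", resnum = seq_len(np),
                                resname = "ARG"),
      lipids = tibble::tibble(chain = "L", resnum = seq_len(nl),
                              resname = species),
      times = dt * (seq_len(dim(arr)[3]) - 1),
      dt = dt,
      params = contact_params()
    ),
    class = "contact_series"
  )
}

series_from_pattern <- function(pattern, dt = 10) {
  manual_series(array(as.logical(pattern), c(1, 1, length(pattern))), dt = dt)
}

# Ideal alpha-helix C-alpha trace along a given axis (unit vector).
ideal_helix_ca <- function(n = 12, axis = c(1, 0, 0), radius = 2.3,
                           rise = 1.5, turn = 100 * pi / 180) {
  t <- seq_len(n)
  local <- cbind(rise * t, radius * cos(turn * t), radius * sin(turn * t))
  axis <- axis / sqrt(sum(axis^2))
  # rotate local x onto axis
  if (all(abs(axis - c(1, 0, 0)) < 1e-12)) return(local)
  v <- c(1, 0, 0)
  w <- axis
  u <- pracma_cross(v, w)
  s <- sqrt(sum(u^2)); cc <- sum(v * w)
  if (s < 1e-12) return(local %*% diag(c(sign(cc), 1, 1)))
  u <- u / s
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(acos(cc)) * K + (1 - cc) * (K %*% K)
  local %*% t(R)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
         byrow = TRUE)
}

# Independent brute-force oracles --------------------------------------------

# All-pairs residue x lipid contact scan, minimum image in x/y, plain loops.
bf_frame_contacts <- function(traj, frame_index, d_cut = 4) {
  a <- traj$topology$atoms
  xyz <- matrix(traj$coords[, , frame_index], ncol = 3)
  box <- traj$box[frame_index, ]
  pres <- unique(a[a$role == "protein", c("chain", "resnum")])
  pres <- pres[order(pres$chain, pres$resnum), ]
  lres <- unique(a[!(a$role %in% c("protein", "other")), c("chain", "resnum")])
  lres <- lres[order(lres$chain, lres$resnum), ]
  out <- matrix(FALSE, nrow(pres), nrow(lres))
  for (i in seq_len(nrow(pres))) {
    prow <- which(a$chain == pres$chain[i] & a$resnum == pres$resnum[i] &
                    a$is_heavy)
    for (j in seq_len(nrow(lres))) {
      lrow <- which(a$chain == lres$chain[j] & a$resnum == lres$resnum[j] &
                      a$is_headgroup & a$is_heavy)
      hit <- FALSE
      for (p in prow) {
        for (l in lrow) {
          dx <- xyz[p, 1] - xyz[l, 1]; dx <- dx - box[1] * round(dx / box[1])
          dy <- xyz[p, 2] - xyz[l, 2]; dy <- dy - box[2] * round(dy / box[2])
          dz <- xyz[p, 3] - xyz[l, 3]
          if (dx^2 + dy^2 + dz^2 <= d_cut^2) { hit <- TRUE; break }
        }
        if (hit) break
      }
      out[i, j] <- hit
    }
  }
  out
}

# Position-by-position motif matcher written independently of scan_motif.
bf_motif_scan <- function(seq, elements, offset = 0) {
  chars <- strsplit(seq, "")[[1]]
  W <- length(elements)
  hits <- integer(0)
  for (i in seq_len(max(0, length(chars) - W + 1))) {
    ok <- TRUE
    for (k in seq_len(W)) {
      if (!(chars[i + k - 1] %in% elements[[k]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, offset + i)
  }
  hits
}

# Random small membrane system for oracle-equivalence checks.
random_membrane_traj <- function(n_res = 5, n_lip = 6, n_frames = 4,
                                 box = c(40, 40, 80)) {
  atoms <- list()
  id <- 0
  for (r in seq_len(n_res)) {
    atoms[[r]] <- data.frame(
      atom_id = id + 1:2, atom_name = c("CA", "CB"), element = "C",
      resname = "ARG", resnum = r, chain = "A"
    )
    id <- id + 2
  }
  atoms[[n_res + 1]] <- lipid_bead_rows(id + seq_len(n_lip), seq_len(n_lip))
  atab <- do.call(rbind, atoms)
  n_atoms <- nrow(atab)
  co <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    co[, 1, f] <- runif(n_atoms, -box[1] / 2, box[1] / 2)
    co[, 2, f] <- runif(n_atoms, -box[2] / 2, box[2] / 2)
    co[, 3, f] <- runif(n_atoms, 15, 22)
  }
  toy_trajectory(atab, co, box = box)
}
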