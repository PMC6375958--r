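# Deterministic synthetic bilayer + peptide trajectory generator.
#
# Lipids are single-bead headgroups (atom "P") on two z planes; peptide
# residues are a backbone bead (CA) plus an interfacial side bead (CB).
# Free lipids perform seeded periodic 2D random walks; lipids bound by a
# scripted or stochastic rule are placed within the contact radius of their
# partner residue, and every unbound lipid is kept outside 1.5x the contact
# radius of every rule residue, so scheduled contact patterns are recovered
# exactly by the geometric contact criterion.
#
# All randomness comes from a 32-bit linear congruential generator advanced
# in exact double arithmetic, with per-lipid substreams; the recurrence and
# draw schedule are recorded in the fixture manifest so any language can
# replay them.

LCG_A <- 1664525
LCG_C <- 1013904223
LCG_M <- 2^32

lcg_step <- function(s) (LCG_A * s + LCG_C) %% LCG_M
lcg_unif <- function(s) (s + 0.5) / LCG_M

lipid_stream_init <- function(seed, lipid_index) {
  s <- (seed + 2654435761 * lipid_index) %% LCG_M
  lcg_step(lcg_step(s))
}

# geometry constants of the pseudo-atom representation
SYNTH_Z_PLANE <- 18      # |z| of each leaflet's P plane (Angstrom)
SYNTH_DZ_SIDE <- 2       # side-bead height above the proximal plane
SYNTH_DZ_CA <- 5.5       # backbone-bead height above the proximal plane

#' Lay out a synthetic peptide at the bilayer interface
#'
#' Residue anchors along a straight in-plane line with fixed spacing, the
#' side bead sitting 2 Angstrom above (upper leaflet) or below (lower) the
#' lipid phosphate plane.
#'
#' @param sequence one-letter amino-acid string.
#' @param chain chain id.
#' @param start_resnum number of the first residue.
#' @param center in-plane `c(x, y)` of the peptide midpoint.
#' @param spacing anchor spacing in Angstrom (default 1.5, a helical rise).
#' @param leaflet `"upper"` or `"lower"`.
#' @param direction in-plane unit direction of the peptide axis.
#' @return tibble of residue anchors (`chain`, `resnum`, `resname`, `code`,
#'   `x`, `y`, `leaflet`).
#' @export
synth_peptide <- function(sequence, chain = "A", start_resnum = 1L,
                          center = c(0, 0), spacing = 1.5,
                          leaflet = c("upper", "lower"),
                          direction = c(1, 0)) {
  leaflet <- match.arg(leaflet)
  codes <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(codes, AA1)
  if (length(bad)) abort(paste0("Unknown residue code: ", bad[1]))
  n <- length(codes)
  three <- names(AA3TO1)[match(codes, AA3TO1)]
  t <- (seq_len(n) - (n + 1) / 2) * spacing
  dirv <- direction / sqrt(sum(direction^2))
  tibble(
    chain = chain, resnum = start_resnum + seq_len(n) - 1L,
    resname = three, code = codes,
    x = center[1] + t * dirv[1], y = center[2] + t * dirv[2],
    leaflet = leaflet
  )
}

#' Specification for a synthetic bilayer trajectory
#'
#' Defaults mirror a symmetric two-leaflet PC/PA bilayer with 183 POPC and
#' 25 POPA per leaflet (12% PA) in a 120 x 120 Angstrom patch, 10 ps frame
#' spacing, and a lateral diffusion step of 0.15 Angstrom/frame (equivalent
#' to a POPC-like lateral diffusion coefficient of ~8 um^2/s at this
#' spacing).
#'
#' @param n_popc,n_popa lipids per leaflet.
#' @param box `c(Lx, Ly, Lz)` in Angstrom.
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing in ps.
#' @param sigma per-frame in-plane Gaussian step (Angstrom).
#' @param peptides tibble from [synth_peptide()] (rows may be concatenated
#'   with [dplyr::bind_rows()]); may be empty.
#' @param binding list of binding rules; each rule is a list with `chain`,
#'   `resnum`, `lipid` (lipid residue number), and either
#'   `intervals` (two-column matrix of first/last frame, 1-based, scripted
#'   mode) or `p_bind`/`p_unbind` (per-frame probabilities, stochastic mode).
#' @param d_contact contact radius the schedule is built against (Angstrom).
#' @param seed integer seed (0 <= seed < 2^31).
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_popc = 183L, n_popa = 25L, box = c(120, 120, 76),
                       n_frames = 100L, dt = 10, sigma = 0.15,
                       peptides = synth_peptide("FRNEVAVLRKTRHVNILLFMGYMTKDNLAIVTQWCEG",
                                                chain = "A", start_resnum = 390L,
                                                center = c(0, -30)),
                       binding = list(), d_contact = 4.0, seed = 1L) {
  if (n_popc < 0 || n_popa < 0) abort("Lipid counts must be >= 0.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  check_scalar_number(dt, "dt", positive = TRUE)
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  n_per_leaflet <- n_popc + n_popa
  if (n_per_leaflet > 0 && box[1] * box[2] / n_per_leaflet < 60) {
    abort("Box too small: area per lipid below 60 Angstrom^2.")
  }
  for (b in binding) {
    if (!all(c("chain", "resnum", "lipid") %in% names(b))) {
      abort("Each binding rule needs `chain`, `resnum`, `lipid`.")
    }
    if (!is.null(b$intervals)) {
      iv <- matrix(b$intervals, ncol = 2)
      if (any(iv[, 1] > iv[, 2]) || any(iv < 1) || any(iv > n_frames)) {
        abort("Scripted intervals must satisfy 1 <= start <= end <= n_frames.")
      }
      if (nrow(iv) > 1) {
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
          abort(sprintf("Overlapping scripted intervals for residue %s:%d / lipid %d.",
                        b$chain, b$resnum, b$lipid))
        }
      }
    } else if (is.null(b$p_bind) || is.null(b$p_unbind)) {
      abort("Binding rule needs either `intervals` or `p_bind` + `p_unbind`.")
    }
  }
  structure(
    list(n_popc = as.integer(n_popc), n_popa = as.integer(n_popa),
         box = box, n_frames = as.integer(n_frames), dt = dt, sigma = sigma,
         peptides = peptides, binding = binding, d_contact = d_contact,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' @param spec a [synth_spec()].
#' @return list with `topology` (`mem_topology`), `trajectory`
#'   (`mem_trajectory`), and `ground_truth`: list with `schedule` (realized
#'   bound intervals: `chain`, `resnum`, `lipid`, `start_frame`,
#'   `end_frame`), `leaflets`, `occupancy` (per rule residue), `global_fractions`,
#'   `seed`, `rng`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  pep <- spec$peptides
  n_pep <- if (is.null(pep)) 0L else nrow(pep)
  n_per <- spec$n_popc + spec$n_popa
  n_lip <- 2L * n_per

  # ---- topology ----------------------------------------------------------
  atoms <- list()
  if (n_pep > 0) {
    z_side <- ifelse(pep$leaflet == "upper",
                     SYNTH_Z_PLANE + SYNTH_DZ_SIDE,
                     -(SYNTH_Z_PLANE + SYNTH_DZ_SIDE))
    z_ca <- ifelse(pep$leaflet == "upper",
                   SYNTH_Z_PLANE + SYNTH_DZ_CA,
                   -(SYNTH_Z_PLANE + SYNTH_DZ_CA))
    atoms[[1]] <- tibble(
      atom_name = rep(c("CA", "CB"), n_pep),
      element = "C",
      resname = rep(pep$resname, each = 2L),
      resnum = rep(pep$resnum, each = 2L),
      chain = rep(pep$chain, each = 2L)
    )
    pep_xyz <- matrix(NA_real_, 2L * n_pep, 3L)
    pep_xyz[, 1] <- rep(pep$x, each = 2L)
    pep_xyz[, 2] <- rep(pep$y, each = 2L)
    pep_xyz[seq(1, 2 * n_pep, 2), 3] <- z_ca
    pep_xyz[seq(2, 2 * n_pep, 2), 3] <- z_side
  } else {
    pep_xyz <- matrix(numeric(0), 0L, 3L)
  }
  lip_species <- rep(c(rep("POPC", spec$n_popc), rep("POPA", spec$n_popa)), 2L)
  lip_leaflet <- rep(c("upper", "lower"), each = n_per)
  if (n_lip > 0) {
    atoms[[length(atoms) + 1L]] <- tibble(
      atom_name = "P", element = "P",
      resname = lip_species, resnum = seq_len(n_lip), chain = "L"
    )
  }
  atab <- bind_rows(atoms)
  if (!nrow(atab)) abort("Spec yields an empty system.")
  atab$atom_id <- seq_len(nrow(atab))
  top <- topology(atab)

  # ---- binding rules -----------------------------------------------------
  rules <- spec$binding
  pep_key <- if (n_pep) paste(pep$chain, pep$resnum) else character(0)
  rule_res <- integer(0)    # peptide row per rule
  for (b in rules) {
    i <- match(paste(b$chain, b$resnum), pep_key)
    if (is.na(i)) abort(sprintf("Binding rule references unknown residue %s:%d.",
                                b$chain, b$resnum))
    if (b$lipid < 1 || b$lipid > n_lip) {
      abort(sprintf("Binding rule references unknown lipid %d.", b$lipid))
    }
    if (lip_leaflet[b$lipid] != pep$leaflet[i]) {
      abort(sprintf("Lipid %d is in the %s leaflet but residue %s:%d faces the %s leaflet.",
                    b$lipid, lip_leaflet[b$lipid], b$chain, b$resnum, pep$leaflet[i]))
    }
    rule_res <- c(rule_res, i)
  }
  rule_lip <- vapply(rules, function(b) as.integer(b$lipid), integer(1))
  stochastic <- vapply(rules, function(b) is.null(b$intervals), logical(1))
  if (anyDuplicated(rule_lip[stochastic]) ||
      any(rule_lip[stochastic] %in% rule_lip[!stochastic])) {
    abort("A stochastic-rule lipid may not appear in any other rule.")
  }
  # scripted per-frame partner: 0 = free, else rule index; one lipid may be
  # handed between residues as long as its scheduled frames never overlap
  sched_partner <- matrix(0L, n_lip, spec$n_frames)
  for (k in seq_along(rules)) {
    if (stochastic[k]) next
    iv <- matrix(rules[[k]]$intervals, ncol = 2)
    for (r in seq_len(nrow(iv))) {
      span <- iv[r, 1]:iv[r, 2]
      clash <- sched_partner[rule_lip[k], span] != 0L
      if (any(clash)) {
        abort(sprintf("Lipid %d is scheduled to two residues at frame %d.",
                      rule_lip[k], span[clash][1]))
      }
      sched_partner[rule_lip[k], span] <- k
    }
  }

  # placement geometry
  d_c <- spec$d_contact
  xy_bound_max <- sqrt((0.8 * d_c)^2 - SYNTH_DZ_SIDE^2)
  if (!is.finite(xy_bound_max) || xy_bound_max <= 0) {
    abort("Contact radius too small for the side-bead height.")
  }
  xy_excl <- sqrt((1.5 * d_c)^2 - SYNTH_DZ_SIDE^2)
  Lx <- spec$box[1]; Ly <- spec$box[2]

  # ---- simulate ----------------------------------------------------------
  s <- vapply(seq_len(n_lip), function(l) lipid_stream_init(spec$seed, l),
              numeric(1))
  pos <- matrix(NA_real_, n_lip, 2L)
  coords <- array(NA_real_, c(nrow(atab), 3L, spec$n_frames))
  lip_rows <- n_pep * 2L + seq_len(n_lip)
  z_lip <- ifelse(lip_leaflet == "upper", SYNTH_Z_PLANE, -SYNTH_Z_PLANE)
  sto_state <- rep(FALSE, length(rules))          # bound flag per stochastic rule
  bound_now <- integer(n_lip)                     # rule index or 0
  realized <- vector("list", length(rules))       # list of c(start, end)
  run_start <- rep(NA_integer_, length(rules))
  sto_idx <- which(stochastic)
  sto_lip <- rule_lip[sto_idx]

  draw2 <- function() {
    s <<- lcg_step(s); u1 <- lcg_unif(s)
    s <<- lcg_step(s); u2 <- lcg_unif(s)
    cbind(u1, u2)
  }

  for (f in seq_len(spec$n_frames)) {
    # stochastic transition draw (1 uniform for every stochastic-rule lipid)
    if (length(sto_idx)) {
      s[sto_lip] <- lcg_step(s[sto_lip])
      u0 <- lcg_unif(s[sto_lip])
      for (q in seq_along(sto_idx)) {
        k <- sto_idx[q]
        if (f == 1L) next   # start free; draw consumed for schedule regularity
        if (sto_state[q]) {
          if (u0[q] < rules[[k]]$p_unbind) sto_state[q] <- FALSE
        } else {
          if (u0[q] < rules[[k]]$p_bind) sto_state[q] <- TRUE
        }
      }
    }
    u <- draw2()
    # who is bound this frame?
    bound_now[] <- 0L
    bound_now <- sched_partner[, f]
    if (length(sto_idx)) {
      bound_now[sto_lip[sto_state]] <- sto_idx[sto_state]
    }
    conflict <- which(sched_partner[, f] > 0L & seq_len(n_lip) %in% sto_lip)
    if (length(conflict)) abort("Lipid scheduled and stochastic simultaneously.")

    is_bound <- bound_now > 0L
    # bound placement
    if (any(is_bound)) {
      bl <- which(is_bound)
      kk <- bound_now[bl]
      ax <- pep$x[rule_res[kk]]; ay <- pep$y[rule_res[kk]]
      ang <- 2 * pi * u[bl, 1]
      rad <- xy_bound_max * sqrt(u[bl, 2])
      pos[bl, 1] <- ax + rad * cos(ang)
      pos[bl, 2] <- ay + rad * sin(ang)
    }
    # free motion
    fr <- which(!is_bound)
    if (length(fr)) {
      if (f == 1L) {
        init <- is.na(pos[fr, 1])
        pos[fr, 1] <- u[fr, 1] * Lx - Lx / 2
        pos[fr, 2] <- u[fr, 2] * Ly - Ly / 2
      } else {
        step_r <- spec$sigma * sqrt(-2 * log(u[fr, 1]))
        pos[fr, 1] <- pos[fr, 1] + step_r * cos(2 * pi * u[fr, 2])
        pos[fr, 2] <- pos[fr, 2] + step_r * sin(2 * pi * u[fr, 2])
      }
      # wrap into the box
      pos[fr, 1] <- min_image(pos[fr, 1], Lx)
      pos[fr, 2] <- min_image(pos[fr, 2], Ly)
      # exclusion zone around every rule residue (proximal leaflet only)
      if (length(rules)) {
        for (k in seq_along(rules)) {
          i <- rule_res[k]
          same_leaf <- lip_leaflet[fr] == pep$leaflet[i]
          not_self <- bound_now[fr] != k
          cand <- fr[same_leaf & not_self]
          if (!length(cand)) next
          dx <- min_image(pos[cand, 1] - pep$x[i], Lx)
          dy <- min_image(pos[cand, 2] - pep$y[i], Ly)
          d <- sqrt(dx * dx + dy * dy)
          close_in <- d < xy_excl
          if (any(close_in)) {
            ci <- cand[close_in]
            dcl <- pmax(d[close_in], 1e-9)
            scale <- (xy_excl * 1.001) / dcl
            pos[ci, 1] <- min_image(pep$x[i] + dx[close_in] * scale, Lx)
            pos[ci, 2] <- min_image(pep$y[i] + dy[close_in] * scale, Ly)
          }
        }
      }
    }
    # realized-schedule bookkeeping
    for (k in seq_along(rules)) {
      b_now <- any(bound_now == k)
      if (b_now && is.na(run_start[k])) run_start[k] <- f
      if (!b_now && !is.na(run_start[k])) {
        realized[[k]] <- c(realized[[k]], list(c(run_start[k], f - 1L)))
        run_start[k] <- NA_integer_
      }
    }
    # write frame
    if (n_pep) coords[seq_len(2L * n_pep), , f] <- pep_xyz
    if (n_lip) {
      coords[lip_rows, 1, f] <- pos[, 1]
      coords[lip_rows, 2, f] <- pos[, 2]
      coords[lip_rows, 3, f] <- z_lip
    }
  }
  for (k in seq_along(rules)) {
    if (!is.na(run_start[k])) {
      realized[[k]] <- c(realized[[k]], list(c(run_start[k], spec$n_frames)))
    }
  }

  traj <- trajectory(top, coords, box = spec$box, dt = spec$dt)

  sched_rows <- list()
  for (k in seq_along(rules)) {
    for (iv in realized[[k]]) {
      sched_rows[[length(sched_rows) + 1L]] <- tibble(
        chain = rules[[k]]$chain, resnum = as.integer(rules[[k]]$resnum),
        lipid = rule_lip[k], species = lip_species[rule_lip[k]],
        mode = if (stochastic[k]) "stochastic" else "scripted",
        start_frame = iv[1], end_frame = iv[2]
      )
    }
  }
  schedule <- if (length(sched_rows)) bind_rows(sched_rows) else
    tibble(chain = character(), resnum = integer(), lipid = integer(),
           species = character(), mode = character(),
           start_frame = integer(), end_frame = integer())
  occupancy <- schedule |>
    group_by(.data$chain, .data$resnum) |>
    summarise(frames_bound = sum(.data$end_frame - .data$start_frame + 1L),
              .groups = "drop") |>
    mutate(occupancy = .data$frames_bound / spec$n_frames)

  gt <- list(
    schedule = schedule,
    leaflets = tibble(resnum = seq_len(n_lip), resname = lip_species,
                      leaflet = lip_leaflet),
    occupancy = occupancy,
    global_fractions = if (n_lip) c(
      POPC = 2 * spec$n_popc / n_lip, POPA = 2 * spec$n_popa / n_lip
    ) else c(POPC = NA_real_, POPA = NA_real_),
    seed = spec$seed,
    rng = paste0(
      "lcg32: s' = (1664525*s + 1013904223) mod 2^32; u = (s'+0.5)/2^32; ",
      "per-lipid state = lcg(lcg((seed + 2654435761*lipid_index) mod 2^32)); ",
      "frame 1: x = u1*Lx - Lx/2, y = u2*Ly - Ly/2; later frames (free): ",
      "r = sigma*sqrt(-2*ln u1), dx = r*cos(2*pi*u2), dy = r*sin(2*pi*u2); ",
      "stochastic-rule lipids draw one extra leading uniform per frame"
    )
  )
  list(topology = top, trajectory = traj, ground_truth = gt, spec = spec)
}

#' Write a synthetic fixture to disk
#'
#' Emits `topology.pdb`, `traj.mtraj` and `manifest.json` (schedule, seed and
#' RNG recurrence) into a directory; [read_fixture()] restores them.
#'
#' @param sim result of [synth_generate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_topology_pdb(sim$topology, frame_coords(sim$trajectory, 1L),
                     file.path(dir, "topology.pdb"))
  write_trajectory_mtraj(sim$trajectory, file.path(dir, "traj.mtraj"))
  manifest <- list(
    seed = sim$ground_truth$seed,
    rng = sim$ground_truth$rng,
    dt_ps = sim$spec$dt,
    sigma = sim$spec$sigma,
    box = sim$spec$box,
    n_popc_per_leaflet = sim$spec$n_popc,
    n_popa_per_leaflet = sim$spec$n_popa,
    n_frames = sim$spec$n_frames,
    d_contact = sim$spec$d_contact,
    schedule = sim$ground_truth$schedule,
    leaflets = sim$ground_truth$leaflets,
    occupancy = sim$ground_truth$occupancy,
    global_fractions = as.list(sim$ground_truth$global_fractions)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a synthetic fixture
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `topology`, `trajectory`, `manifest`.
#' @export
read_fixture <- function(dir) {
  top <- read_topology(file.path(dir, "topology.pdb"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  traj <- read_trajectory(top, file.path(dir, "traj.mtraj"),
                          dt = manifest$dt_ps)
  list(topology = top, trajectory = traj, manifest = manifest)
}
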