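# Salt bridges, multivalency, shared-lipid episodes, helix orientation,
# spine collinearity, inter-chain independence.

BASIC_N_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"), HSE = c("ND1", "NE2"),
  HSP = c("ND1", "NE2")
)

PHOSPHATE_O_ATOMS <- c("O11", "O12", "O13", "O14", "OP1", "OP2", "OP3", "OP4")

#' Salt-bridge events between basic side chains and lipid phosphates
#'
#' An event is a maximal run of frames in which any side-chain nitrogen of a
#' basic residue (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) lies within `d_sb` of
#' any phosphate oxygen of a lipid. The default cutoff matches the 4 Angstrom
#' heavy-atom contact criterion.
#'
#' @param traj a `mem_trajectory`.
#' @param d_sb N...O distance cutoff in Angstrom (default 4.0).
#' @param donor_atoms named list residue name -> nitrogen atom names
#'   (defaults above).
#' @param acceptor_atoms lipid oxygen atom names (defaults to the phosphate
#'   oxygens).
#' @return tibble of events: `chain`, `resnum`, `resname`, `lipid_id`,
#'   `species`, `n_atom`, `o_atom` (closest pair at event onset), `t_i_ps`,
#'   `t_f_ps`, `n_frames`. Attribute `dt`.
#' @export
salt_bridges <- function(traj, d_sb = 4.0, donor_atoms = BASIC_N_ATOMS,
                         acceptor_atoms = PHOSPHATE_O_ATOMS) {
  stopifnot(inherits(traj, "mem_trajectory"))
  if (d_sb < 0) abort("`d_sb` must be >= 0.")
  a <- traj$topology$atoms
  don <- rep(FALSE, nrow(a))
  for (rn in names(donor_atoms)) {
    don <- don | (a$role == "protein" & toupper(a$resname) == rn &
                    a$atom_name %in% donor_atoms[[rn]])
  }
  acc <- !(a$role %in% c("protein", "other")) & a$atom_name %in% acceptor_atoms
  empty <- tibble(chain = character(), resnum = integer(), resname = character(),
                  lipid_id = character(), species = character(),
                  n_atom = character(), o_atom = character(),
                  t_i_ps = numeric(), t_f_ps = numeric(), n_frames = integer())
  attr(empty, "dt") <- traj$dt
  if (!any(don)) {
    warn("No basic-residue side-chain nitrogens in topology.")
    return(empty)
  }
  if (!any(acc)) {
    warn("No lipid phosphate oxygens in topology.")
    return(empty)
  }
  drows <- which(don); arows <- which(acc)
  dres <- unique(a[drows, c("chain", "resnum", "resname")])
  ares <- unique(a[arows, c("chain", "resnum", "resname")])
  dmap <- match(paste(a$chain[drows], a$resnum[drows]),
                paste(dres$chain, dres$resnum))
  amap <- match(paste(a$chain[arows], a$resnum[arows]),
                paste(ares$chain, ares$resnum))
  np <- nrow(dres); nl <- nrow(ares); nf <- traj$n_frames
  act <- array(FALSE, c(np, nl, nf))
  best_pair <- vector("list", np * nl)   # closest N/O pair seen per couple
  best_d2 <- rep(Inf, np * nl)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d2 <- pair_dist2_xy_mic(xyz[drows, , drop = FALSE],
                            xyz[arows, , drop = FALSE], traj$box[f, ])
    hit <- d2 <= d_sb^2
    if (!any(hit)) next
    idx <- which(hit, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      ri <- dmap[idx[k, 1]]; li <- amap[idx[k, 2]]
      act[ri, li, f] <- TRUE
      pos <- (li - 1L) * np + ri
      if (d2[idx[k, 1], idx[k, 2]] < best_d2[pos]) {
        best_d2[pos] <- d2[idx[k, 1], idx[k, 2]]
        best_pair[[pos]] <- c(a$atom_name[drows[idx[k, 1]]],
                              a$atom_name[arows[idx[k, 2]]])
      }
    }
  }
  rows <- list()
  for (ri in seq_len(np)) {
    for (li in seq_len(nl)) {
      v <- act[ri, li, ]
      if (!any(v)) next
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        pr <- best_pair[[(li - 1L) * np + ri]] %||% c(NA_character_, NA_character_)
        rows[[length(rows) + 1L]] <- tibble(
          chain = dres$chain[ri], resnum = dres$resnum[ri],
          resname = dres$resname[ri],
          lipid_id = paste0(ares$resname[li], ":", ares$chain[li], ":",
                            ares$resnum[li]),
          species = ares$resname[li],
          n_atom = pr[1], o_atom = pr[2],
          t_i_ps = traj$times[starts[j]], t_f_ps = traj$times[ends[j]],
          n_frames = ends[j] - starts[j] + 1L
        )
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty
  attr(out, "dt") <- traj$dt
  out
}

#' Multivalent intervals: one lipid engaging several residues at once
#'
#' Interval algebra over the per-lipid salt-bridge events: for each lipid,
#' frames during which at least `min_residues` distinct residues hold a
#' simultaneous salt bridge are collapsed into intervals of constant partner
#' set.
#'
#' @param events a [salt_bridges()] table (attribute `dt` required).
#' @param min_residues minimum simultaneous partners (default 2).
#' @return tibble: `lipid_id`, `t_start_ps`, `t_end_ps`, `n_frames`,
#'   `n_residues`, `residues` (comma-joined `chain:resnum` labels).
#' @export
multivalent_episodes <- function(events, min_residues = 2L) {
  dt <- attr(events, "dt")
  if (is.null(dt)) abort("`events` must carry a `dt` attribute (from salt_bridges()).")
  out <- tibble(lipid_id = character(), t_start_ps = numeric(),
                t_end_ps = numeric(), n_frames = integer(),
                n_residues = integer(), residues = character())
  if (!nrow(events)) return(out)
  rows <- list()
  for (lid in unique(events$lipid_id)) {
    ev <- events |> filter(.data$lipid_id == lid)
    t0 <- min(ev$t_i_ps); t1 <- max(ev$t_f_ps)
    frames <- seq(t0, t1, by = dt)
    labels <- paste0(ev$chain, ":", ev$resnum)
    active <- matrix(FALSE, length(frames), nrow(ev))
    for (k in seq_len(nrow(ev))) {
      active[, k] <- frames >= ev$t_i_ps[k] & frames <= ev$t_f_ps[k]
    }
    set_key <- apply(active, 1, function(z) {
      paste(sort(unique(labels[z])), collapse = ",")
    })
    cnt <- vapply(strsplit(set_key, ","), function(z) sum(nzchar(z)), integer(1))
    ok <- cnt >= min_residues
    key <- ifelse(ok, set_key, "")
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(nzchar(r$values))) {
      rows[[length(rows) + 1L]] <- tibble(
        lipid_id = lid,
        t_start_ps = frames[starts[j]], t_end_ps = frames[ends[j]],
        n_frames = ends[j] - starts[j] + 1L,
        n_residues = cnt[starts[j]],
        residues = r$values[j]
      )
    }
  }
  if (length(rows)) bind_rows(rows) else out
}

#' Shared-lipid episodes across named regions
#'
#' Tracks, for every lipid, which protein regions it contacts over time:
#' consecutive frames with an identical set of contacted regions are
#' collapsed into windows. Lipids whose windows span two or more regions at
#' once are the "shared" lipids that bridge distant parts of the protein.
#'
#' @param series a [contact_series()].
#' @param regions named list of residue-number vectors (default
#'   [raf_regions()]).
#' @return tibble: `lipid_id`, `species`, `t_start_ps`, `t_end_ps`,
#'   `n_frames`, `regions` (comma-joined), `n_regions`, plus attribute
#'   `ranking`: per-lipid total multi-region time, decreasing.
#' @export
shared_lipid_regions <- function(series, regions = raf_regions()) {
  stopifnot(inherits(series, "contact_series"))
  res <- series$residues
  reg_idx <- lapply(regions, function(rr) which(res$resnum %in% rr))
  arr <- series$contact
  nl <- dim(arr)[2]; nf <- dim(arr)[3]
  rows <- list()
  for (li in seq_len(nl)) {
    key <- character(nf)
    for (f in seq_len(nf)) {
      hit <- vapply(reg_idx, function(ix) {
        length(ix) > 0 && any(arr[ix, li, f])
      }, logical(1))
      key[f] <- paste(names(regions)[hit], collapse = ",")
    }
    if (!any(nzchar(key))) next
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(nzchar(r$values))) {
      nreg <- length(strsplit(r$values[j], ",")[[1]])
      rows[[length(rows) + 1L]] <- tibble(
        lipid_id = paste0(series$lipids$resname[li], ":",
                          series$lipids$chain[li], ":",
                          series$lipids$resnum[li]),
        species = series$lipids$resname[li],
        t_start_ps = series$times[starts[j]],
        t_end_ps = series$times[ends[j]],
        n_frames = ends[j] - starts[j] + 1L,
        regions = r$values[j],
        n_regions = nreg
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    lipid_id = character(), species = character(), t_start_ps = numeric(),
    t_end_ps = numeric(), n_frames = integer(), regions = character(),
    n_regions = integer()
  )
  ranking <- out |>
    filter(.data$n_regions >= 2L) |>
    group_by(.data$lipid_id) |>
    summarise(multi_region_frames = sum(.data$n_frames),
              multi_region_ps = sum(.data$n_frames) * series$dt,
              .groups = "drop") |>
    arrange(dplyr::desc(.data$multi_region_frames))
  attr(out, "ranking") <- ranking
  attr(out, "dt") <- series$dt
  out
}

#' Helix orientation relative to the membrane normal
#'
#' Per frame, the helix axis is the dominant direction of the best-fit line
#' through the C-alpha positions of the helix span; the tilt angle is
#' `theta = acos(|axis . z|)` in degrees, folded into [0, 90] (a helix lying
#' flat on the membrane has theta ~ 90).
#'
#' @param traj a `mem_trajectory`.
#' @param helix_resnums residue numbers of the helix span (>= 4 C-alpha
#'   atoms required). Default 391:408, the alphaC span harbouring the
#'   polybasic cluster.
#' @param chain optional chain filter.
#' @return an `orientation_series` tibble: `frame`, `time_ps`, `theta_deg`.
#' @export
helix_orientation <- function(traj, helix_resnums = 391:408, chain = NULL) {
  stopifnot(inherits(traj, "mem_trajectory"))
  ids <- select_atoms(traj$topology, chain = chain, resnum = helix_resnums,
                      atom_name = "CA")
  if (length(ids) < 4L) {
    abort(sprintf("Helix span yields %d C-alpha atoms; >= 4 required.",
                  length(ids)))
  }
  rows <- match(ids, traj$topology$atoms$atom_id)
  theta <- vapply(seq_len(traj$n_frames), function(f) {
    pts <- frame_coords(traj, f)[rows, , drop = FALSE]
    v <- fit_line3(pts)$direction
    acos(min(1, abs(v[3]))) * 180 / pi
  }, numeric(1))
  out <- tibble(frame = seq_len(traj$n_frames), time_ps = traj$times,
                theta_deg = theta)
  class(out) <- c("orientation_series", class(out))
  out
}

#' Collinearity of the regulatory-spine residues
#'
#' Per frame, side-chain heavy-atom centroids of the spine residues are fit
#' with a line; the reported value is the RMS perpendicular deviation of the
#' centroids from that line (0 for perfectly collinear).
#'
#' @param traj a `mem_trajectory`.
#' @param spine_resnums spine residue numbers. Default `c(397, 408, 466,
#'   487)`, the classic four-residue regulatory spine; set `extended = TRUE`
#'   to add W342.
#' @param chain optional chain filter.
#' @param extended add residue 342 to the spine set.
#' @return tibble: `frame`, `time_ps`, `rms_dev` (Angstrom).
#' @export
spine_collinearity <- function(traj, spine_resnums = c(397L, 408L, 466L, 487L),
                               chain = NULL, extended = FALSE) {
  stopifnot(inherits(traj, "mem_trajectory"))
  if (extended) spine_resnums <- sort(unique(c(spine_resnums, 342L)))
  a <- traj$topology$atoms
  backbone <- c("N", "CA", "C", "O", "OXT", "HA", "HN")
  res_rows <- lapply(spine_resnums, function(rn) {
    sel <- a$role == "protein" & a$resnum == rn & a$is_heavy &
      !(a$atom_name %in% backbone)
    if (!is.null(chain)) sel <- sel & a$chain %in% chain
    rr <- which(sel)
    if (!length(rr)) {
      rname <- unique(a$resname[a$resnum == rn & a$role == "protein"])
      if (length(rname) && any(toupper(rname) == "GLY")) {
        abort(sprintf("Residue %d is glycine: no side-chain atoms for the spine.", rn))
      }
      abort(sprintf("Residue %d has no side-chain heavy atoms.", rn))
    }
    rr
  })
  if (length(res_rows) < 3L) abort("Spine needs >= 3 residues.")
  out <- vapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    ctr <- t(vapply(res_rows, function(rr) {
      colMeans(xyz[rr, , drop = FALSE])
    }, numeric(3)))
    fit <- fit_line3(ctr)
    rms_point_line(ctr, fit$center, fit$direction)
  }, numeric(1))
  tibble(frame = seq_len(traj$n_frames), time_ps = traj$times, rms_dev = out)
}

#' Minimum inter-chain heavy-atom distances
#'
#' Verifies that protein copies behave as independent replicas: per frame and
#' chain pair, the minimum heavy-atom distance, flagged when it drops below
#' the contact cutoff.
#'
#' @param traj a `mem_trajectory`.
#' @param chains chains to compare (default: all protein chains).
#' @param d_cut flagging cutoff in Angstrom (default 4.0).
#' @return tibble: `frame`, `time_ps`, `chain_a`, `chain_b`, `min_dist`,
#'   `flagged`.
#' @export
interchain_independence <- function(traj, chains = NULL, d_cut = 4.0) {
  stopifnot(inherits(traj, "mem_trajectory"))
  a <- traj$topology$atoms
  chains <- chains %||% sort(unique(a$chain[a$role == "protein"]))
  if (length(chains) < 2L) abort("Need >= 2 protein chains to compare.")
  rows_by_chain <- lapply(chains, function(ch) {
    which(a$role == "protein" & a$chain == ch & a$is_heavy)
  })
  pairs <- utils::combn(seq_along(chains), 2)
  out <- list()
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      d2 <- pair_dist2_xy_mic(xyz[rows_by_chain[[i]], , drop = FALSE],
                              xyz[rows_by_chain[[j]], , drop = FALSE],
                              traj$box[f, ])
      md <- sqrt(min(d2))
      out[[length(out) + 1L]] <- tibble(
        frame = f, time_ps = traj$times[f],
        chain_a = chains[i], chain_b = chains[j],
        min_dist = md, flagged = md < d_cut
      )
    }
  }
  bind_rows(out)
}
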