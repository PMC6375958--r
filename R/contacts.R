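# Residue-lipid contact detection and contact-probability summaries.
#
# A contact is declared when any heavy atom of a protein residue lies within
# d_cut (default 4 Angstrom) of any heavy atom of a lipid headgroup, using
# 3D distance with minimum-image wrapping in the bilayer plane (x, y).

#' Contact criterion parameters
#'
#' @param d_cut distance cutoff in Angstrom (> 0). Default 4.0.
#' @param heavy_only restrict the protein side to heavy atoms (default TRUE;
#'   the lipid side is always headgroup heavy atoms).
#' @return a `contact_params` list.
#' @export
contact_params <- function(d_cut = 4.0, heavy_only = TRUE) {
  check_scalar_number(d_cut, "d_cut", positive = TRUE)
  structure(list(d_cut = d_cut, heavy_only = heavy_only),
            class = "contact_params")
}

# Precompute index structures mapping residues/lipids to atom rows.
contact_groups <- function(top, params) {
  a <- top$atoms
  prot <- a$role == "protein" & (!params$heavy_only | a$is_heavy)
  lip <- a$is_headgroup & a$is_heavy
  if (!any(prot)) abort("No protein atoms selected for contact analysis.")
  if (!any(lip)) abort("No lipid headgroup atoms in topology.")
  pa <- a[prot, ]
  la <- a[lip, ]
  pres <- unique(pa[, c("chain", "resnum", "resname")])
  pres <- pres[order(pres$chain, pres$resnum), ]
  lres <- unique(la[, c("chain", "resnum", "resname")])
  lres <- lres[order(lres$chain, lres$resnum), ]
  pkey <- paste(pa$chain, pa$resnum)
  lkey <- paste(la$chain, la$resnum)
  # check every protein residue retains >= 1 atom
  all_prot_res <- top$residues[top$residues$role == "protein", ]
  missing <- setdiff(paste(all_prot_res$chain, all_prot_res$resnum), unique(pkey))
  if (length(missing)) {
    abort(paste0("Protein residue(s) with zero heavy atoms: ",
                 paste(missing, collapse = ", ")))
  }
  list(
    prot_rows = which(prot), lip_rows = which(lip),
    pmap = match(pkey, paste(pres$chain, pres$resnum)),
    lmap = match(lkey, paste(lres$chain, lres$resnum)),
    residues = as_tibble(pres), lipids = as_tibble(lres)
  )
}

# residue x lipid logical matrix for one frame's coordinates.
contacts_one_frame <- function(xyz, box, grp, d_cut) {
  d2 <- pair_dist2_xy_mic(xyz[grp$prot_rows, , drop = FALSE],
                          xyz[grp$lip_rows, , drop = FALSE], box)
  hit <- d2 <= d_cut^2
  np <- nrow(grp$residues)
  nl <- nrow(grp$lipids)
  A <- matrix(0, np, length(grp$prot_rows))
  A[cbind(grp$pmap, seq_along(grp$pmap))] <- 1
  B <- matrix(0, length(grp$lip_rows), nl)
  B[cbind(seq_along(grp$lmap), grp$lmap)] <- 1
  (A %*% hit %*% B) > 0
}

#' Residue-lipid contacts in a single frame
#'
#' @param traj a `mem_trajectory`.
#' @param params a [contact_params()].
#' @param frame_index 1-based frame.
#' @return logical matrix (protein residues x lipids) with dimnames
#'   `chain:resnum`.
#' @export
frame_contacts <- function(traj, params = contact_params(), frame_index = 1L) {
  stopifnot(inherits(traj, "mem_trajectory"))
  grp <- contact_groups(traj$topology, params)
  m <- contacts_one_frame(frame_coords(traj, frame_index),
                          traj$box[frame_index, ], grp, params$d_cut)
  dimnames(m) <- list(paste0(grp$residues$chain, ":", grp$residues$resnum),
                      paste0(grp$lipids$chain, ":", grp$lipids$resnum))
  m
}

#' Per-frame residue-lipid contact series
#'
#' The boolean contact record underlying all dwell-time and probability
#' statistics: one entry per (protein residue, lipid, frame).
#'
#' @inheritParams frame_contacts
#' @param frames integer vector of frames to include (default all).
#' @return object of class `contact_series`: list with `contact` (logical
#'   array residues x lipids x frames), `residues`, `lipids` (tibbles),
#'   `times` (ps), `dt` (ps).
#' @export
contact_series <- function(traj, params = contact_params(), frames = NULL) {
  stopifnot(inherits(traj, "mem_trajectory"))
  frames <- frames %||% seq_len(traj$n_frames)
  grp <- contact_groups(traj$topology, params)
  np <- nrow(grp$residues); nl <- nrow(grp$lipids)
  arr <- array(FALSE, c(np, nl, length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[i]
    arr[, , i] <- contacts_one_frame(frame_coords(traj, f), traj$box[f, ],
                                     grp, params$d_cut)
  }
  structure(
    list(contact = arr, residues = grp$residues, lipids = grp$lipids,
         times = traj$times[frames], dt = traj$dt, params = params),
    class = "contact_series"
  )
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d residues x %d lipids x %d frames (dt = %g ps)\n",
              dim(x$contact)[1], dim(x$contact)[2], dim(x$contact)[3], x$dt))
  invisible(x)
}

#' Per-residue contact probabilities
#'
#' Fraction of frames a residue touches at least one lipid (and, per species,
#' at least one lipid of that species). When the system contains several
#' copies of the same peptide, pass `chain_groups` to average probabilities
#' positionally across the copies, as one would over independent replicas.
#'
#' @param series a [contact_series()].
#' @param chain_groups optional list of character vectors of chain ids; chains
#'   within a group must have equal residue counts and are averaged by
#'   sequence position (not residue number, so renumbered copies group fine).
#' @return a `contact_summary` tibble: `chain`, `position`, `resnum`,
#'   `resname`, `p_contact`, and one `p_<species>` column per lipid species.
#'   Attribute `n_frames` records the averaging window.
#' @export
contact_probability <- function(series, chain_groups = NULL) {
  stopifnot(inherits(series, "contact_series"))
  arr <- series$contact
  species <- sort(unique(series$lipids$resname))
  occupancy <- function(a) {
    m <- apply(a, c(1, 3), any)
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(a)[1])
    m
  }
  p <- rowMeans(occupancy(arr))
  out <- series$residues |> mutate(p_contact = p)
  for (sp in species) {
    sel <- series$lipids$resname == sp
    out[[paste0("p_", sp)]] <- rowMeans(occupancy(arr[, sel, , drop = FALSE]))
  }
  out <- out |>
    group_by(.data$chain) |>
    mutate(position = rank(.data$resnum)) |>
    ungroup()

  if (!is.null(chain_groups)) {
    pieces <- list()
    grouped <- unlist(chain_groups)
    if (anyDuplicated(grouped)) abort("A chain appears in more than one group.")
    pcols <- c("p_contact", paste0("p_", species))
    for (g in chain_groups) {
      sub <- out |> filter(.data$chain %in% g)
      lens <- sub |> group_by(.data$chain) |> summarise(n = n())
      if (length(unique(lens$n)) != 1L) {
        abort(paste0("Chains ", paste(g, collapse = ","),
                     " have unequal residue counts; cannot group."))
      }
      first_chain <- sort(g)[1]
      ref <- sub |> filter(.data$chain == first_chain)
      avg <- sub |>
        group_by(.data$position) |>
        summarise(dplyr::across(dplyr::all_of(pcols), mean), .groups = "drop")
      piece <- ref |> select(-dplyr::all_of(pcols)) |>
        left_join(avg, by = "position") |>
        mutate(chain = paste(sort(g), collapse = "+"))
      pieces[[length(pieces) + 1L]] <- piece
    }
    rest <- out |> filter(!.data$chain %in% grouped)
    out <- bind_rows(pieces, list(rest)) |> arrange(.data$chain, .data$resnum)
  }
  out <- out |> select("chain", "position", "resnum", "resname",
                       "p_contact", dplyr::starts_with("p_"))
  attr(out, "n_frames") <- dim(arr)[3]
  attr(out, "dt") <- series$dt
  class(out) <- c("contact_summary", class(out))
  out
}

#' Residues in stable membrane contact
#'
#' Residues whose contact probability strictly exceeds a threshold, e.g. the
#' classic "in contact for >50% of the simulation length" set (or >80% for
#' the most persistent interface).
#'
#' @param summary a [contact_probability()] result.
#' @param threshold fraction in (0, 1); strict `>` comparison.
#' @return tibble subset of `summary`.
#' @export
stable_residues <- function(summary, threshold = 0.5) {
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  as_tibble(summary) |> filter(.data$p_contact > threshold)
}

#' Canonical cRaf kinase-domain membrane-contact regions
#'
#' The three membrane-interacting regions of the cRaf kinase domain in the
#' crystal-structure author numbering: the N-terminal acidic region (NtA,
#' 340-342), the polybasic cluster of the alphaC-helix (391, 398-401) and the
#' activation segment (AS, 462-463 and 494-497).
#'
#' @return named list of residue-number vectors.
#' @export
raf_regions <- function() {
  list(NtA = 340:342,
       basic = c(391L, 398L, 399L, 400L, 401L),
       AS = c(462L, 463L, 494:497))
}

#' Summarise contact probabilities by named region
#'
#' @param summary a [contact_probability()] result.
#' @param regions named list of residue-number vectors; defaults to
#'   [raf_regions()]. Overlapping regions are each evaluated independently.
#' @param stable_threshold threshold for each region's stable-member set.
#' @return tibble: `region`, `n_residues`, `mean_p`, `stable` (list column of
#'   stable member labels `chain:resnum`).
#' @export
region_summary <- function(summary, regions = raf_regions(),
                           stable_threshold = 0.5) {
  s <- as_tibble(summary)
  rows <- lapply(names(regions), function(nm) {
    sub <- s |> filter(.data$resnum %in% regions[[nm]])
    missing <- setdiff(regions[[nm]], sub$resnum)
    if (length(missing)) {
      abort(sprintf("Region '%s' references absent residue(s): %s", nm,
                    paste(missing, collapse = ", ")))
    }
    stab <- sub |> filter(.data$p_contact > stable_threshold)
    tibble(region = nm, n_residues = nrow(sub), mean_p = mean(sub$p_contact),
           stable = list(residue_labels(stab)))
  })
  bind_rows(rows)
}
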