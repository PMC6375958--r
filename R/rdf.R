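# In-plane 2D radial distribution functions and lipid-species enrichment.

#' 2D radial distribution function of lipid phosphorus
#'
#' In-plane g(r) of lipid P atoms of one species around reference protein
#' atoms. Distances are xy-projected with minimum-image wrapping; per frame,
#' pair counts are binned and normalised by the ideal-gas expectation
#' `rho * 2 pi r dr` computed from the instantaneous box area, so a uniform
#' lipid field gives g = 1. Profiles are averaged over reference atoms and
#' frames.
#'
#' @param traj a `mem_trajectory`.
#' @param ref_atoms integer atom ids (e.g. from [select_atoms()]); reference
#'   points for the profile.
#' @param species lipid species of the target P atoms (default `"POPA"`).
#' @param leaflet `"auto"` (leaflet whose P plane is nearest the references,
#'   the only leaflet geometrically reachable at short range), `"upper"`,
#'   `"lower"`, or `"both"`.
#' @param r_max largest distance (Angstrom); must be below half the smallest
#'   in-plane box edge.
#' @param dr bin width (Angstrom). Default 0.2.
#' @param window optional `c(t_start, t_end)` in ps restricting the frames.
#' @return an `rdf_profile`: tibble `r` (bin centers), `g`, plus attributes
#'   `dr`, `species`, `leaflet`, `n_ref`, `n_frames`, `window`,
#'   `mean_density`.
#' @export
rdf2d <- function(traj, ref_atoms, species = "POPA",
                  leaflet = c("auto", "upper", "lower", "both"),
                  r_max = 12, dr = 0.2, window = NULL) {
  stopifnot(inherits(traj, "mem_trajectory"))
  leaflet <- match.arg(leaflet)
  check_scalar_number(r_max, "r_max", positive = TRUE)
  check_scalar_number(dr, "dr", positive = TRUE)
  if (r_max >= min(traj$box[, 1:2]) / 2) {
    abort("`r_max` must be below half the smallest in-plane box edge.")
  }
  if (!length(ref_atoms)) abort("`ref_atoms` is empty.")
  a <- traj$topology$atoms
  ref_rows <- match(ref_atoms, a$atom_id)
  if (anyNA(ref_rows)) abort("Unknown atom id in `ref_atoms`.")
  frames <- seq_len(traj$n_frames)
  if (!is.null(window)) {
    frames <- which(traj$times >= window[1] & traj$times <= window[2])
    if (!length(frames)) abort("`window` selects no frames.")
  }
  lf <- assign_leaflets(traj, frames[1])
  tgt <- a$resname == species & a$atom_name == "P"
  if (!any(tgt)) abort(sprintf("No %s phosphorus atoms in topology.", species))
  tgt_tab <- a[tgt, c("chain", "resnum")]
  tgt_leaflet <- lf$leaflet[match(paste(tgt_tab$chain, tgt_tab$resnum),
                                  paste(lf$chain, lf$resnum))]
  scope <- switch(leaflet,
    both = rep(TRUE, sum(tgt)),
    upper = tgt_leaflet == "upper",
    lower = tgt_leaflet == "lower",
    auto = {
      xyz1 <- frame_coords(traj, frames[1])
      ref_z <- mean(xyz1[ref_rows, 3])
      planes <- tapply(lf$z, lf$leaflet, mean)
      tgt_leaflet == names(planes)[which.min(abs(planes - ref_z))]
    })
  tgt_rows <- which(tgt)[scope]
  if (!length(tgt_rows)) {
    abort(sprintf("No %s lipids in the selected leaflet.", species))
  }
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  expected <- numeric(nb)
  centers <- (head(breaks, -1L) + breaks[-1L]) / 2
  dens_acc <- 0
  for (f in frames) {
    xyz <- frame_coords(traj, f)
    box <- traj$box[f, ]
    dx <- min_image(outer(xyz[ref_rows, 1], xyz[tgt_rows, 1], "-"), box[1])
    dy <- min_image(outer(xyz[ref_rows, 2], xyz[tgt_rows, 2], "-"), box[2])
    r <- sqrt(dx * dx + dy * dy)
    r <- r[r < r_max]
    if (length(r)) {
      counts <- counts + tabulate(pmin(floor(r / dr) + 1L, nb), nbins = nb)
    }
    rho <- length(tgt_rows) / (box[1] * box[2])
    dens_acc <- dens_acc + rho
    expected <- expected + length(ref_rows) * rho * 2 * pi * centers * dr
  }
  out <- tibble(r = centers, g = ifelse(expected > 0, counts / expected, NA_real_))
  attr(out, "dr") <- dr
  attr(out, "species") <- species
  attr(out, "leaflet") <- leaflet
  attr(out, "n_ref") <- length(ref_rows)
  attr(out, "n_frames") <- length(frames)
  attr(out, "window") <- window
  attr(out, "mean_density") <- dens_acc / length(frames)
  attr(out, "counts") <- counts
  class(out) <- c("rdf_profile", class(out))
  out
}

#' Time-block convergence of the 2D RDF
#'
#' One profile per time block plus the full-window profile; convergence is
#' summarised as the largest absolute deviation of each block profile from
#' the full profile.
#'
#' @inheritParams rdf2d
#' @param blocks list of `c(t_start, t_end)` windows in ps.
#' @return list with `full` (an `rdf_profile`), `blocks` (named list of
#'   profiles) and `metric` (tibble `block`, `max_abs_dev`).
#' @export
rdf_convergence <- function(traj, ref_atoms, species = "POPA",
                            leaflet = "auto", r_max = 12, dr = 0.2,
                            blocks = list()) {
  if (!length(blocks)) abort("`blocks` must contain at least one window.")
  for (b in blocks) {
    if (diff(b) <= 0) abort("Zero- or negative-length time block.")
  }
  full <- rdf2d(traj, ref_atoms, species, leaflet, r_max, dr, window = NULL)
  labels <- vapply(blocks, function(b) sprintf("%g-%g ps", b[1], b[2]),
                   character(1))
  profs <- lapply(blocks, function(b) {
    rdf2d(traj, ref_atoms, species, leaflet, r_max, dr, window = b)
  })
  names(profs) <- labels
  metric <- tibble(
    block = labels,
    max_abs_dev = unname(vapply(profs, function(p) {
      max(abs(p$g - full$g), na.rm = TRUE)
    }, numeric(1)))
  )
  list(full = full, blocks = profs, metric = metric)
}

#' Local lipid-species enrichment near a residue set
#'
#' Tests whether one lipid species is over-represented among the lipids in
#' contact with a region (e.g. anionic PA around a polybasic cluster). A
#' lipid is "near" in a frame when it contacts at least one region residue
#' under the standard contact criterion. The local fraction is the ratio of
#' frame-averaged counts (near lipids of the species over all near lipids);
#' the global fraction comes from the topology's species counts.
#'
#' @param traj a `mem_trajectory`.
#' @param region_resnums residue numbers defining the region.
#' @param params a [contact_params()].
#' @param species species of interest (default `"POPA"`).
#' @param chain optional chain filter for the region residues.
#' @return an `enrichment_result`: list with `local_fraction`,
#'   `global_fraction`, `mean_near`, `mean_near_species`, `n_frames`,
#'   `undefined` (TRUE when no lipid is ever near).
#' @export
enrichment <- function(traj, region_resnums, params = contact_params(),
                       species = "POPA", chain = NULL) {
  stopifnot(inherits(traj, "mem_trajectory"))
  series <- contact_series(traj, params)
  res <- series$residues
  keep <- res$resnum %in% region_resnums
  if (!is.null(chain)) keep <- keep & res$chain %in% chain
  if (!any(keep)) abort("Region selects no protein residues.")
  sub <- series$contact[keep, , , drop = FALSE]
  near <- apply(sub, c(2, 3), any)          # lipid x frame
  if (is.null(dim(near))) near <- matrix(near, nrow = dim(sub)[2])
  sp_sel <- series$lipids$resname == species
  n_near <- colSums(near)
  n_near_sp <- colSums(near[sp_sel, , drop = FALSE])
  lip_counts <- table(traj$topology$residues$role)
  lip_species <- setdiff(names(lip_counts), c("protein", "other"))
  global <- unname(lip_counts[species] / sum(lip_counts[lip_species]))
  undefined <- mean(n_near) == 0
  structure(
    list(
      local_fraction = if (undefined) NA_real_ else mean(n_near_sp) / mean(n_near),
      global_fraction = as.numeric(global),
      mean_near = mean(n_near),
      mean_near_species = mean(n_near_sp),
      n_frames = length(n_near),
      species = species,
      undefined = undefined
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> %s local fraction %.3f vs global %.3f (%.1f lipids near on average)\n",
              x$species, x$local_fraction, x$global_fraction, x$mean_near))
  if (x$undefined) cat("  [undefined: no lipid ever near the region]\n")
  invisible(x)
}
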