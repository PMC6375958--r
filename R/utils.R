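# Internal helpers shared across modules.

# Three-letter -> one-letter amino-acid codes (standard 20 + common variants).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  HSD = "H", HSE = "H", HSP = "H"
)

AA1 <- sort(unique(unname(AA3TO1)))

aa_three_to_one <- function(resname) {
  out <- AA3TO1[toupper(resname)]
  unname(out)
}

is_protein_resname <- function(resname) {
  toupper(resname) %in% names(AA3TO1)
}

#' Minimum-image displacement in the bilayer plane
#'
#' Wraps displacement components into `[-L/2, L/2)` for the periodic x and y
#' directions; z is left untouched (the bilayer normal is treated as
#' non-periodic for all in-plane analyses).
#'
#' @param d numeric vector or matrix of displacements.
#' @param box_len box edge length(s) in Angstrom, recycled against `d`.
#' @return displacements wrapped to the nearest periodic image.
#' @keywords internal
#' @noRd
min_image <- function(d, box_len) {
  d - box_len * round(d / box_len)
}

# Pairwise squared distances between coordinate sets a (n x 3) and b (m x 3)
# with minimum-image wrapping in x and y only.
pair_dist2_xy_mic <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- outer(a[, 3], b[, 3], "-")
  dx * dx + dy * dy + dz * dz
}

# Best-fit line through points (n x 3): returns list(center, direction).
fit_line3 <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(center = ctr, direction = sv$v[, 1])
}

# RMS perpendicular distance of points from a line.
rms_point_line <- function(pts, center, direction) {
  rel <- sweep(pts, 2, center)
  proj <- rel %*% direction
  perp <- rel - proj %*% t(direction)
  sqrt(mean(rowSums(perp^2)))
}

# "chain:resnum" labels; empty tables give character(0), not ":".
residue_labels <- function(df) {
  if (!nrow(df)) return(character(0))
  paste0(df$chain, ":", df$resnum)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
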