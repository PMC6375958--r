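# Topology: atoms, residues, lipid species roles, headgroup definitions.

#' Default lipid headgroup atom sets
#'
#' Heavy-atom names of the solvent-exposed headgroup of each supported lipid
#' species, in CHARMM36 nomenclature. For phosphatidylcholine (POPC) the set
#' is phosphate plus choline; for phosphatidic acid (POPA) it is the phosphate
#' group alone. The contact criterion only ever examines these atoms.
#'
#' @return named list of character vectors, one per lipid residue name.
#' @export
#' @examples
#' default_headgroups()$POPA
default_headgroups <- function() {
  list(
    POPC = c("N", "C11", "C12", "C13", "C14", "C15",
             "P", "O11", "O12", "O13", "O14"),
    POPA = c("P", "O11", "O12", "O13", "O14")
  )
}

#' Build a topology from an atom table
#'
#' Constructs the topology container used by every analysis. Atom roles are
#' assigned from residue names: standard amino acids become `protein`, residue
#' names with a headgroup definition become their own species (e.g. `POPC`,
#' `POPA`), anything else is `other` (with a warning, since such residues are
#' invisible to the lipid analyses).
#'
#' @param atoms data frame with columns `atom_id`, `atom_name`, `element`,
#'   `resname`, `resnum`, `chain`. `element` may contain empty strings, in
#'   which case a leading-character heuristic on `atom_name` is used (with a
#'   warning).
#' @param headgroups named list of headgroup atom-name sets; defaults to
#'   [default_headgroups()]. Override to redefine what counts as "headgroup"
#'   (e.g. to include glycerol carbons) or to register extra lipid species.
#' @return an object of class `mem_topology` with elements `atoms`
#'   (tibble including `is_heavy`, `role`, `is_headgroup`), `residues`
#'   (one row per residue) and `headgroups`.
#' @export
topology <- function(atoms, headgroups = default_headgroups()) {
  atoms <- as_tibble(atoms)
  required <- c("atom_id", "atom_name", "element", "resname", "resnum", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("`atoms` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(atoms$atom_id)) {
    dup <- atoms$atom_id[duplicated(atoms$atom_id)][1]
    abort(sprintf("Duplicate atom_id %s in topology.", dup))
  }
  elem <- toupper(trimws(atoms$element))
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {
    warn("Element column empty for some atoms; using atom-name heuristic for hydrogen detection.")
    nm <- toupper(trimws(atoms$atom_name[blank]))
    # leading digits (e.g. "1HB2") precede the element character in PDB names
    nm <- sub("^[0-9]+", "", nm)
    elem[blank] <- ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
  }
  atoms$element <- elem
  atoms$is_heavy <- elem != "H"

  role <- rep("other", nrow(atoms))
  role[is_protein_resname(atoms$resname)] <- "protein"
  for (sp in names(headgroups)) {
    role[toupper(atoms$resname) == toupper(sp)] <- sp
  }
  unknown <- unique(atoms$resname[role == "other"])
  if (length(unknown)) {
    warn(paste0("Residue name(s) without role, treated as 'other': ",
                paste(unknown, collapse = ", ")))
  }
  atoms$role <- role
  atoms$is_headgroup <- FALSE
  for (sp in names(headgroups)) {
    sel <- role == sp & atoms$atom_name %in% headgroups[[sp]]
    atoms$is_headgroup[sel] <- TRUE
  }

  residues <- atoms |>
    distinct(.data$chain, .data$resnum, .data$resname, .data$role) |>
    arrange(.data$chain, .data$resnum)

  structure(
    list(atoms = atoms, residues = residues, headgroups = headgroups,
         n_atoms = nrow(atoms)),
    class = "mem_topology"
  )
}

#' @export
print.mem_topology <- function(x, ...) {
  tab <- table(x$residues$role)
  cat(sprintf("<mem_topology> %d atoms, %d residues (%s)\n",
              x$n_atoms, nrow(x$residues),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and classifies residues into
#' protein, lipid species and other. Hydrogens are flagged from the element
#' column when present, otherwise from a leading-H atom-name heuristic with a
#' warning.
#'
#' @param path PDB file.
#' @inheritParams topology
#' @return a `mem_topology`; the file's coordinates are attached as attribute
#'   `coords` (n_atoms x 3 matrix) for convenience.
#' @export
read_topology <- function(path, headgroups = default_headgroups()) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    atom_id = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
    resname = trimws(at$resid),
    resnum = as.integer(at$resno),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  )
  top <- topology(atoms, headgroups = headgroups)
  attr(top, "coords") <- cbind(at$x, at$y, at$z)
  top
}

#' Write a topology + coordinates as a PDB file
#'
#' @param top a `mem_topology`.
#' @param coords n_atoms x 3 coordinate matrix (Angstrom); defaults to the
#'   coordinates attached by [read_topology()] if present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(top, coords = attr(top, "coords"), path) {
  stopifnot(inherits(top, "mem_topology"))
  if (is.null(coords) || nrow(coords) != top$n_atoms) {
    abort("`coords` must be an n_atoms x 3 matrix.")
  }
  a <- top$atoms
  # strict v3.3 columns (resName 18-21 so 4-character lipid names survive a
  # round trip; element right-justified in 77-78)
  nm <- ifelse(nchar(a$atom_name) < 4L,
               sprintf(" %-3s", a$atom_name), a$atom_name)
  lines <- sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$role == "protein", "ATOM", "HETATM"),
                   a$atom_id, nm, a$resname, a$chain, a$resnum,
                   coords[, 1], coords[, 2], coords[, 3], 1, 0,
                   formatC(a$element, width = 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Resolve an atom selection on a topology
#'
#' Deterministic selection: filters are combined with AND, and the result is
#' always ordered by `atom_id`. All filters are optional; omitting them all
#' selects every atom.
#'
#' @param top a `mem_topology`.
#' @param chain,resname,atom_name character filters (any of the given values).
#' @param resnum integer vector of residue numbers (ranges via `:`).
#' @param heavy_only if `TRUE`, drop hydrogens.
#' @param headgroup_only if `TRUE`, keep only lipid headgroup atoms.
#' @return integer vector of atom ids (possibly empty), ordered.
#' @export
select_atoms <- function(top, chain = NULL, resnum = NULL, resname = NULL,
                         atom_name = NULL, heavy_only = FALSE,
                         headgroup_only = FALSE) {
  stopifnot(inherits(top, "mem_topology"))
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resnum)) keep <- keep & a$resnum %in% resnum
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (heavy_only) keep <- keep & a$is_heavy
  if (headgroup_only) keep <- keep & a$is_headgroup
  sort(a$atom_id[keep])
}

#' Assign lipids to bilayer leaflets
#'
#' Each lipid's phosphorus z coordinate is compared with the bilayer midplane
#' (mean z over all lipid P atoms in the frame). Lipids at or above the
#' midplane are `upper` (ties go up, a documented rule), the rest `lower`.
#'
#' @param traj a `mem_trajectory`.
#' @param frame_index frame to use (1-based).
#' @return tibble with `chain`, `resnum`, `resname`, `z` and `leaflet`.
#' @export
assign_leaflets <- function(traj, frame_index = 1L) {
  stopifnot(inherits(traj, "mem_trajectory"))
  top <- traj$topology
  lip <- top$residues |> filter(!.data$role %in% c("protein", "other"))
  if (nrow(lip) == 0L) abort("Topology contains no lipid residues.")
  xyz <- traj$coords[, , frame_index]
  a <- top$atoms
  z <- vapply(seq_len(nrow(lip)), function(i) {
    sel <- a$chain == lip$chain[i] & a$resnum == lip$resnum[i] &
      a$atom_name == "P"
    if (!any(sel)) {
      abort(sprintf("Lipid %s %s:%d has no P atom; cannot assign leaflet.",
                    lip$resname[i], lip$chain[i], lip$resnum[i]))
    }
    mean(xyz[which(sel), 3])
  }, numeric(1))
  mid <- mean(z)
  lip |>
    mutate(z = z, leaflet = ifelse(z >= mid, "upper", "lower")) |>
    select("chain", "resnum", "resname", "z", "leaflet")
}
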