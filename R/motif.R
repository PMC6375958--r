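# Polybasic membrane-interaction motif scanning and composition
# classification of membrane-binding residue sets.

#' Compile a sequence motif pattern
#'
#' Patterns are whitespace-separated elements: a fixed one-letter residue
#' (`R`), an alternative set (`[RK]`), the wildcard `x`, or a wildcard repeat
#' (`x{4}`). The pattern expands to a fixed length.
#'
#' @param spec pattern string, e.g. `"R x E x{4} [RK] [KR] T R"`.
#' @param name optional label.
#' @return object of class `motif_pattern`: list with `elements` (list of
#'   allowed-character vectors), `length`, `name`, `spec`.
#' @export
#' @examples
#' motif_pattern("R x E x{4} [RK] [KR] T R", name = "raf_strict")
motif_pattern <- function(spec, name = NULL) {
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  elements <- list()
  for (tk in toks) {
    if (grepl("^x\\{\\d+\\}$", tk)) {
      nrep <- as.integer(sub("^x\\{(\\d+)\\}$", "\\1", tk))
      elements <- c(elements, rep(list(AA1), nrep))
    } else if (tk == "x") {
      elements <- c(elements, list(AA1))
    } else if (grepl("^\\[[A-Z]+\\]$", tk)) {
      elements <- c(elements, list(strsplit(gsub("\\[|\\]", "", tk), "")[[1]]))
    } else if (grepl("^[A-Z]$", tk) && tk %in% AA1) {
      elements <- c(elements, list(tk))
    } else {
      abort(sprintf("Cannot parse pattern element '%s'.", tk))
    }
  }
  bad <- setdiff(unlist(elements), AA1)
  if (length(bad)) {
    abort(paste0("Pattern uses non-standard code(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(elements = elements, length = length(elements),
                 name = name %||% spec, spec = spec),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (length %d): %s\n", x$name, x$length, x$spec))
  invisible(x)
}

#' Shipped motif presets
#'
#' Two forms of the conserved Raf-family polybasic membrane-interaction
#' consensus: the strict form `R x E x{4} [RK] [KR] T R` (default elsewhere)
#' and a relaxed form `[RK] x E x{4} [RK] [KR] [TLQ] R` admitting the wider
#' cross-kinase variation.
#'
#' @param name `"raf_strict"` or `"raf_relaxed"`.
#' @return a [motif_pattern()].
#' @export
motif_preset <- function(name = c("raf_strict", "raf_relaxed")) {
  name <- match.arg(name)
  switch(name,
    raf_strict = motif_pattern("R x E x{4} [RK] [KR] T R", name = "raf_strict"),
    raf_relaxed = motif_pattern("[RK] x E x{4} [RK] [KR] [TLQ] R",
                                name = "raf_relaxed")
  )
}

#' Scan sequences for a motif
#'
#' Reports all (possibly overlapping) matches, left to right. Positions are
#' reported in a caller-supplied numbering: `offset + 1`-based index, so a
#' segment whose first residue is numbered 390 uses `offset = 389`.
#'
#' @param sequences character vector of amino-acid sequences (one-letter
#'   codes), optionally named.
#' @param pattern a [motif_pattern()]; default the strict Raf preset.
#' @param offset integer added to 1-based positions (>= 0).
#' @return tibble: `seq_id`, `start`, `end`, `match`.
#' @export
#' @examples
#' scan_motif("FRNEVAVLRKTRHVNILLFMGYMTKDNLAIVTQWCEG", offset = 389)
scan_motif <- function(sequences, pattern = motif_preset("raf_strict"),
                       offset = 0L) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (offset < 0) abort("`offset` must be >= 0.")
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  ids[ids == ""] <- paste0("seq", which(ids == ""))
  rows <- list()
  for (s in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[[s]]), "")[[1]]
    bad <- which(!chars %in% AA1)
    if (length(bad)) {
      abort(sprintf("Sequence '%s' has non-standard residue '%s' at position %d.",
                    ids[s], chars[bad[1]], bad[1]))
    }
    L <- length(chars); W <- pattern$length
    if (L >= W) {
      # per-position allowed mask, then AND across the window
      ok_pos <- vapply(seq_len(W), function(k) {
        chars %in% pattern$elements[[k]]
      }, logical(L))
      if (is.null(dim(ok_pos))) ok_pos <- matrix(ok_pos, nrow = L)
      for (i in seq_len(L - W + 1L)) {
        if (all(ok_pos[cbind(i:(i + W - 1L), seq_len(W))])) {
          rows[[length(rows) + 1L]] <- tibble(
            seq_id = ids[s],
            start = offset + i,
            end = offset + i + W - 1L,
            match = paste(chars[i:(i + W - 1L)], collapse = "")
          )
        }
      }
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(seq_id = character(), start = integer(), end = integer(),
           match = character())
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @return named character vector suitable for [scan_motif()].
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("Not a FASTA file: no '>' headers.")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(z) {
    gsub("\\s", "", paste(z, collapse = ""))
  }, character(1))
  setNames(unname(seqs), ids)
}

# composition classes
BASIC_AA <- c("R", "K", "H")
AROMATIC_AA <- c("F", "W", "Y")
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "P")

#' Classify a membrane-interacting residue set by composition
#'
#' Membrane-binding surfaces fall into three recurring composition groups:
#' (1) largely positively charged, (2) positive plus aromatic/hydrophobic,
#' and (3) polar/aromatic/hydrophobic with little charge. The group is
#' assigned from the basic and aromatic+hydrophobic fractions: group 1 when
#' the basic fraction is at least `basic_high` and aromatic+hydrophobic below
#' `apolar_low`; group 2 when basic is at least `basic_low` and
#' aromatic+hydrophobic at least `apolar_low`; group 3 otherwise. Histidine
#' counts as basic.
#'
#' @param residues character vector of one-letter codes (a multiset; order
#'   does not matter).
#' @param basic_high,basic_low,apolar_low classification thresholds
#'   (defaults 0.6, 0.25, 0.25 — calibrated so the classic examples of each
#'   group land correctly).
#' @return a `residue_classification`: list with `fractions` (basic,
#'   aromatic, hydrophobic, polar_other; summing to 1), `group`, `n`.
#' @export
#' @examples
#' classify_residues(c("K", "K", "K", "Y", "W", "N"))  # group 2
classify_residues <- function(residues, basic_high = 0.6, basic_low = 0.25,
                              apolar_low = 0.25) {
  residues <- toupper(residues)
  if (!length(residues)) abort("`residues` must be nonempty.")
  bad <- setdiff(residues, AA1)
  if (length(bad)) {
    abort(paste0("Unknown residue code(s): ", paste(bad, collapse = ", ")))
  }
  n <- length(residues)
  f_basic <- mean(residues %in% BASIC_AA)
  f_arom <- mean(residues %in% AROMATIC_AA)
  f_hyd <- mean(residues %in% HYDROPHOBIC_AA)
  f_other <- 1 - f_basic - f_arom - f_hyd
  apolar <- f_arom + f_hyd
  group <- if (f_basic >= basic_high && apolar < apolar_low) {
    1L
  } else if (f_basic >= basic_low && apolar >= apolar_low) {
    2L
  } else {
    3L
  }
  structure(
    list(fractions = c(basic = f_basic, aromatic = f_arom,
                       hydrophobic = f_hyd, polar_other = f_other),
         group = group, n = n),
    class = "residue_classification"
  )
}

#' @export
print.residue_classification <- function(x, ...) {
  cat(sprintf("<residue_classification> group %d (n = %d): basic %.2f, aromatic %.2f, hydrophobic %.2f, polar/other %.2f\n",
              x$group, x$n, x$fractions["basic"], x$fractions["aromatic"],
              x$fractions["hydrophobic"], x$fractions["polar_other"]))
  invisible(x)
}

#' Compact interface code for a membrane-contacting residue set
#'
#' Renders an ordered residue set as a compact string: contiguous residues
#' are concatenated, a gap of one residue becomes `"."`, and a gap of two or
#' more becomes `".."` — the conventional shorthand for membrane-interacting
#' surfaces assembled from several sequence segments.
#'
#' @param resnums integer residue numbers (strictly increasing after
#'   sorting; duplicates are an error).
#' @param codes one-letter codes, same length as `resnums`.
#' @return a single string.
#' @export
#' @examples
#' interface_code(c(340, 341, 342, 391), c("Y", "Y", "W", "R"))
interface_code <- function(resnums, codes) {
  if (length(resnums) != length(codes)) {
    abort("`resnums` and `codes` must have equal length.")
  }
  if (!length(resnums)) abort("Empty residue set.")
  if (anyDuplicated(resnums)) {
    abort(sprintf("Duplicate residue number %s.",
                  resnums[duplicated(resnums)][1]))
  }
  ord <- order(resnums)
  resnums <- resnums[ord]; codes <- toupper(codes[ord])
  out <- codes[1]
  if (length(resnums) > 1L) {
    for (i in 2:length(resnums)) {
      gap <- resnums[i] - resnums[i - 1L] - 1L
      sep <- if (gap == 0L) "" else if (gap == 1L) "." else ".."
      out <- paste0(out, sep, codes[i])
    }
  }
  out
}
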