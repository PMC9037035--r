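# Two-partner complex container and interface geometry.

#' Construct a Complex from an atom table
#'
#' Low-level constructor. `atoms` must carry columns `id`, `atom_name`,
#' `element`, `x`, `y`, `z`, `resname`, `resno`, `chain`, `vdw_radius`,
#' `partial_charge`. Chain sets must be disjoint and non-empty and every
#' atom must belong to exactly one side.
#'
#' @param atoms data.frame of atoms.
#' @param receptor_chains character vector of receptor chain ids.
#' @param partner_chains character vector of binding-partner chain ids.
#' @return object of class `"Complex"`.
#' @export
new_complex <- function(atoms, receptor_chains, partner_chains) {
  receptor_chains <- unique(as.character(receptor_chains))
  partner_chains <- unique(as.character(partner_chains))
  if (length(receptor_chains) == 0L || length(partner_chains) == 0L)
    stop("receptor and partner chain sets must be non-empty", call. = FALSE)
  if (length(intersect(receptor_chains, partner_chains)) > 0L)
    stop("receptor and partner chain sets must be disjoint", call. = FALSE)
  required <- c("id", "atom_name", "element", "x", "y", "z",
                "resname", "resno", "chain", "vdw_radius", "partial_charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(atoms$vdw_radius <= 0))
    stop("all van der Waals radii must be positive", call. = FALSE)
  side <- ifelse(atoms$chain %in% receptor_chains, "receptor",
                 ifelse(atoms$chain %in% partner_chains, "partner", NA))
  if (anyNA(side))
    stop("atoms present on chains outside both chain sets: ",
         paste(unique(atoms$chain[is.na(side)]), collapse = ", "),
         call. = FALSE)
  atoms$side <- side
  atoms$is_heavy <- .normalize_element(atoms$element) != "H"
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms,
         receptor_chains = receptor_chains,
         partner_chains = partner_chains),
    class = "Complex")
}

#' @export
print.Complex <- function(x, ...) {
  cat("Complex:", nrow(x$atoms), "atoms |",
      "receptor chains:", paste(x$receptor_chains, collapse = ","), "|",
      "partner chains:", paste(x$partner_chains, collapse = ","), "\n")
  invisible(x)
}

#' Extract one side of a Complex
#'
#' @param complex a `Complex`.
#' @param side `"receptor"` or `"partner"`.
#' @param heavy_only drop hydrogens?
#' @return the atom data.frame of that side.
#' @export
complex_side <- function(complex, side = c("receptor", "partner"),
                         heavy_only = FALSE) {
  side <- match.arg(side)
  at <- complex$atoms[complex$atoms$side == side, , drop = FALSE]
  if (heavy_only) at <- at[at$is_heavy, , drop = FALSE]
  rownames(at) <- NULL
  at
}

# Squared cross-distance matrix between two n x 3 coordinate matrices.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# Residue label in the "ARG87"-style used by interaction criteria.
residue_label <- function(resname, resno) paste0(toupper(resname), resno)

.water_residues <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a two-partner complex from PDB coordinates
#'
#' Reads ATOM/HETATM records (first MODEL only, waters discarded) of the
#' named chains, assigns Bondi van der Waals radii and residue-template
#' partial charges, and returns a [new_complex()] object. Parsing is
#' delegated to \pkg{bio3d}; records are pre-validated so a malformed
#' coordinate field fails with its line number and an element symbol absent
#' from the parameter table fails naming the element.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param receptor_chains chain ids forming the receptor side.
#' @param partner_chains chain ids forming the binding-partner side.
#' @return a `Complex`.
#' @export
parse_complex <- function(pdb, receptor_chains, partner_chains) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec_idx) == 0L)
    stop("no ATOM/HETATM records found: not PDB-format text", call. = FALSE)
  # keep MODEL 1 only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    end1 <- grep("^ENDMDL", lines)[1]
    if (!is.na(end1)) rec_idx <- rec_idx[rec_idx < end1]
  }
  for (i in rec_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("unparseable coordinate record at line ", i,
           ": fewer than 54 columns", call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("unparseable coordinate record at line ", i,
           ": non-numeric coordinate field", call. = FALSE)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb_obj <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  at <- pdb_obj$atom
  at <- at[!(toupper(at$resid) %in% .water_residues), , drop = FALSE]

  receptor_chains <- unique(as.character(receptor_chains))
  partner_chains <- unique(as.character(partner_chains))
  wanted <- c(receptor_chains, partner_chains)
  absent <- setdiff(wanted, unique(at$chain))
  if (length(absent) > 0L)
    stop("configuration error: chain(s) not present in the structure: ",
         paste(absent, collapse = ", "), call. = FALSE)
  at <- at[at$chain %in% wanted, , drop = FALSE]

  element <- at$elesy
  if (is.null(element) || all(is.na(element) | trimws(element) == ""))
    element <- bio3d::atom2ele(at$elety)
  blank <- is.na(element) | trimws(element) == ""
  if (any(blank)) element[blank] <- bio3d::atom2ele(at$elety[blank])

  ep <- element_params(element)  # errors on unknown elements, naming them
  atoms <- data.frame(
    id = at$eleno,
    atom_name = trimws(at$elety),
    element = .normalize_element(element),
    x = at$x, y = at$y, z = at$z,
    resname = toupper(trimws(at$resid)),
    resno = at$resno,
    chain = as.character(at$chain),
    vdw_radius = ep$vdw_radius,
    stringsAsFactors = FALSE)
  atoms$partial_charge <- assign_partial_charges(atoms$resname,
                                                 atoms$atom_name,
                                                 atoms$element)
  new_complex(atoms, receptor_chains, partner_chains)
}

#' Interface residues of the receptor side
#'
#' A receptor residue is at the interface when at least one of its heavy
#' atoms lies within `cutoff` of any partner heavy atom. This geometric rule
#' keeps interface extraction self-contained (no external interface server);
#' the default 4.5 Angstrom is a conventional heavy-atom contact distance.
#'
#' @param complex a `Complex`.
#' @param cutoff heavy-atom distance cutoff (Angstrom, > 0).
#' @return data.frame with columns `chain`, `resno`, `resname`, `label`,
#'   sorted by (chain, resno).
#' @export
interface_residues <- function(complex, cutoff = 4.5) {
  stopifnot(inherits(complex, "Complex"), cutoff > 0)
  rec <- complex_side(complex, "receptor", heavy_only = TRUE)
  par <- complex_side(complex, "partner", heavy_only = TRUE)
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), label = character(),
                      stringsAsFactors = FALSE)
  if (nrow(rec) == 0L || nrow(par) == 0L) return(empty)
  d2 <- cross_dist2(atom_coords(rec), atom_coords(par))
  near <- apply(d2, 1L, min) <= cutoff^2
  if (!any(near)) return(empty)
  hit <- unique(rec[near, c("chain", "resno", "resname")])
  hit <- hit[order(hit$chain, hit$resno), , drop = FALSE]
  hit$label <- residue_label(hit$resname, hit$resno)
  rownames(hit) <- NULL
  hit
}
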