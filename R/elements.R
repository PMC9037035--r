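# Per-element parameter tables used across the package.
#
# vdw_radius: Bondi van der Waals radii (Angstrom).
# mass: standard atomic weight (g/mol).
# electronegativity: Pauling scale.
# polarizability: static dipole polarizability (A^3).
# lj_epsilon: Lennard-Jones well depth (kcal/mol); pair well depths are
#   geometric means. These are declared stand-in parameters for a simplified
#   potential, not a validated force field.
.element_table <- data.frame(
  element           = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "SE", "B"),
  vdw_radius        = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98, 1.90, 1.92),
  mass              = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
                        35.45, 79.904, 126.904, 78.971, 10.81),
  electronegativity = c(2.20, 2.55, 3.04, 3.44, 2.58, 2.19, 3.98, 3.16, 2.96, 2.66, 2.55, 2.04),
  polarizability    = c(0.667, 1.76, 1.10, 0.802, 2.90, 3.63, 0.557, 2.18, 3.05, 5.35, 3.77, 3.03),
  lj_epsilon        = c(0.015, 0.070, 0.170, 0.210, 0.250, 0.200, 0.061,
                        0.276, 0.389, 0.550, 0.290, 0.180),
  stringsAsFactors  = FALSE
)

.normalize_element <- function(element) {
  el <- toupper(trimws(element))
  # strip charge annotations sometimes present in PDB element columns
  gsub("[^A-Z]", "", el)
}

#' Look up per-element parameters
#'
#' Returns the rows of the internal element parameter table (Bondi radius,
#' mass, Pauling electronegativity, polarizability, Lennard-Jones well depth)
#' for a vector of element symbols. Unknown symbols are an error naming the
#' offending element, so malformed structures fail loudly at parse time.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return data.frame with one row per input element.
#' @export
element_params <- function(element) {
  el <- .normalize_element(element)
  idx <- match(el, .element_table$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (not in the radius/charge assignment table)", call. = FALSE)
  }
  out <- .element_table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Residue-template partial charges (elementary charge units) for protein
# heavy atoms. Coarse, amide/carboxylate/guanidinium-flavoured values; any
# atom not covered falls back to a per-element default. A declared stand-in:
# the potential needs plausible polarity, not a validated charge set.
.backbone_charges <- c(N = -0.42, CA = 0.02, C = 0.60, O = -0.57, OXT = -0.57)

.sidechain_charges <- list(
  ARG = c(CG = 0.00, CD = 0.20, NE = -0.45, CZ = 0.65, NH1 = 0.20, NH2 = 0.20),
  LYS = c(CG = 0.00, CD = 0.00, CE = 0.25, NZ = 0.35),
  ASP = c(CG = 0.60, OD1 = -0.70, OD2 = -0.70),
  GLU = c(CG = 0.00, CD = 0.60, OE1 = -0.70, OE2 = -0.70),
  ASN = c(CG = 0.55, OD1 = -0.55, ND2 = -0.60),
  GLN = c(CG = 0.00, CD = 0.55, OE1 = -0.55, NE2 = -0.60),
  HIS = c(CG = 0.10, ND1 = -0.50, CD2 = 0.10, CE1 = 0.30, NE2 = -0.50),
  SER = c(OG = -0.55),
  THR = c(OG1 = -0.55, CG2 = 0.00),
  TYR = c(CZ = 0.30, OH = -0.50),
  TRP = c(NE1 = -0.35),
  CYS = c(SG = -0.30),
  MET = c(SD = -0.25, CE = 0.05)
)

.default_charge_by_element <- c(
  H = 0.10, C = 0.00, N = -0.35, O = -0.45, S = -0.20, P = 0.40,
  F = -0.10, CL = -0.10, BR = -0.10, I = -0.10, SE = -0.20, B = 0.00
)

#' Assign residue-template partial charges
#'
#' Per-atom partial charges from a protein residue template (backbone amide,
#' carboxylate, guanidinium, hydroxyl groups), falling back to a per-element
#' default for atoms outside the template. Units: elementary charge.
#'
#' @param resname 3-letter residue codes.
#' @param atom_name PDB atom names (e.g. "CA", "OD1").
#' @param element element symbols, used for the fallback.
#' @return numeric vector of partial charges.
#' @export
assign_partial_charges <- function(resname, atom_name, element) {
  n <- length(atom_name)
  stopifnot(length(resname) == n, length(element) == n)
  el <- .normalize_element(element)
  q <- unname(.default_charge_by_element[el])
  q[is.na(q)] <- 0
  an <- toupper(trimws(atom_name))
  rn <- toupper(trimws(resname))
  bb <- match(an, names(.backbone_charges))
  q[!is.na(bb)] <- .backbone_charges[bb[!is.na(bb)]]
  for (res in unique(rn)) {
    tmpl <- .sidechain_charges[[res]]
    if (is.null(tmpl)) next
    i <- which(rn == res)
    hit <- match(an[i], names(tmpl))
    q[i[!is.na(hit)]] <- tmpl[hit[!is.na(hit)]]
  }
  q
}
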