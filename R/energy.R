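# Frozen virtual alanine scanning with a simplified pairwise potential.
#
# The potential is a declared stand-in: Lennard-Jones 6-12 on Bondi radii
# (pair minimum at r_i + r_j, well depth the geometric mean of per-element
# depths) plus Coulomb with a distance-dependent dielectric eps(r) = 4r and
# residue-template partial charges. Absolute kcal/mol values are not
# comparable to any commercial scoring function; what the scan preserves is
# the procedure: identical frozen coordinates for wild type and mutant, no
# minimization, side chain truncated beyond C-beta.

#' Parameters of the simplified scanning potential
#'
#' @param interaction_cutoff pairwise interaction cutoff (Angstrom).
#' @param hot_spot_threshold delta-affinity at or above which a residue is
#'   called a hot spot (kcal/mol). Default 4.0.
#' @param coulomb_constant electrostatic conversion factor
#'   (kcal mol-1 A e-2).
#' @param dielectric_slope the distance-dependent dielectric is
#'   `eps(r) = dielectric_slope * r`.
#' @return object of class `"EnergyParams"`.
#' @export
energy_params <- function(interaction_cutoff = 10,
                          hot_spot_threshold = 4,
                          coulomb_constant = 332.0637,
                          dielectric_slope = 4) {
  stopifnot(interaction_cutoff > 0, hot_spot_threshold > 0,
            coulomb_constant > 0, dielectric_slope > 0)
  structure(list(interaction_cutoff = interaction_cutoff,
                 hot_spot_threshold = hot_spot_threshold,
                 coulomb_constant = coulomb_constant,
                 dielectric_slope = dielectric_slope),
            class = "EnergyParams")
}

# Pairwise interaction energy matrix (kcal/mol) between two atom tables.
# LJ 6-12 with r_min = r_i + r_j, eps_ij = sqrt(eps_i * eps_j), plus
# Coulomb q_i q_j * k / (slope * r^2). Zero beyond the cutoff.
pair_energy_matrix <- function(atoms_a, atoms_b, params = energy_params()) {
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L)
    return(matrix(0, nrow(atoms_a), nrow(atoms_b)))
  d2 <- cross_dist2(atom_coords(atoms_a), atom_coords(atoms_b))
  d <- sqrt(d2)
  eps_a <- element_params(atoms_a$element)$lj_epsilon
  eps_b <- element_params(atoms_b$element)$lj_epsilon
  eps <- sqrt(outer(eps_a, eps_b))
  rmin <- outer(atoms_a$vdw_radius, atoms_b$vdw_radius, "+")
  sr6 <- (rmin / d)^6
  e_lj <- eps * (sr6^2 - 2 * sr6)
  e_coul <- params$coulomb_constant *
    outer(atoms_a$partial_charge, atoms_b$partial_charge) /
    (params$dielectric_slope * d2)
  e <- e_lj + e_coul
  e[d > params$interaction_cutoff] <- 0
  e
}

#' Binding energy of a complex under the simplified potential
#'
#' Sum of pairwise receptor-partner terms within the interaction cutoff.
#' More negative is more favourable.
#'
#' @param complex a `Complex`.
#' @param params an [energy_params()] object.
#' @return scalar energy (kcal/mol).
#' @export
binding_energy <- function(complex, params = energy_params()) {
  rec <- complex_side(complex, "receptor")
  par <- complex_side(complex, "partner")
  sum(pair_energy_matrix(rec, par, params))
}

# Atom names retained by the virtual side-chain truncation: backbone,
# C-beta, and their hydrogens.
.alanine_keep <- c("N", "CA", "C", "O", "OXT", "CB",
                   "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3",
                   "HB", "HB1", "HB2", "HB3")

#' Frozen virtual alanine scan of one receptor residue
#'
#' Virtually mutates the residue to alanine by deleting its side-chain atoms
#' beyond C-beta, with every remaining coordinate frozen: no minimization,
#' no rotation about the CA-CB bond, no hydrogen rebuilding. The reported
#' delta affinity is the binding-energy loss
#' `E_bind(wild type) - E_bind(truncated)`, which under a pairwise potential
#' is exactly the summed interaction of the deleted atoms with the partner
#' side. Glycine and alanine are defined to score 0 (nothing to truncate).
#'
#' @param complex a `Complex`.
#' @param chain,resno receptor residue to scan.
#' @param params an [energy_params()] object; its `hot_spot_threshold` sets
#'   the hot-spot flag.
#' @return one-row data.frame: `chain`, `resno`, `resname`, `label`,
#'   `delta_affinity` (kcal/mol), `is_hot_spot`.
#' @export
alanine_scan <- function(complex, chain, resno, params = energy_params()) {
  stopifnot(inherits(complex, "Complex"))
  if (!(chain %in% complex$receptor_chains))
    stop("residue lookup error: chain ", chain,
         " is not a receptor chain", call. = FALSE)
  at <- complex$atoms
  sel <- at$chain == chain & at$resno == resno
  if (!any(sel))
    stop("residue lookup error: no residue ", resno,
         " on chain ", chain, call. = FALSE)
  resname <- at$resname[sel][1]
  res <- data.frame(chain = chain, resno = as.integer(resno),
                    resname = resname,
                    label = residue_label(resname, resno),
                    stringsAsFactors = FALSE)
  if (resname %in% c("GLY", "ALA")) {
    res$delta_affinity <- 0
  } else {
    removed <- at[sel & !(toupper(at$atom_name) %in% .alanine_keep), ,
                  drop = FALSE]
    partner <- complex_side(complex, "partner")
    res$delta_affinity <- sum(pair_energy_matrix(removed, partner, params))
  }
  res$is_hot_spot <- res$delta_affinity >= params$hot_spot_threshold
  res
}

#' Alanine-scan every interface residue of the receptor
#'
#' Convenience wrapper: finds interface residues at `interface_cutoff` and
#' runs [alanine_scan()] on each.
#'
#' @inheritParams alanine_scan
#' @param interface_cutoff heavy-atom interface distance (Angstrom).
#' @return data.frame of per-residue scan results, sorted by (chain, resno).
#' @export
scan_interface <- function(complex, params = energy_params(),
                           interface_cutoff = 4.5) {
  iface <- interface_residues(complex, interface_cutoff)
  if (nrow(iface) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), label = character(),
                      delta_affinity = numeric(), is_hot_spot = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(iface)), function(i)
    alanine_scan(complex, iface$chain[i], iface$resno[i], params)))
  rownames(out) <- NULL
  out
}

#' Call hot spots from alanine-scan results
#'
#' Residues whose delta affinity meets or exceeds the threshold (default
#' 4 kcal/mol) are hot spots.
#'
#' @param scan data.frame from [alanine_scan()] / [scan_interface()].
#' @param threshold kcal/mol, > 0.
#' @return the hot-spot subset, sorted by (chain, resno).
#' @export
call_hot_spots <- function(scan, threshold = 4) {
  stopifnot(threshold > 0)
  if (nrow(scan) == 0L) return(scan)
  hs <- scan[scan$delta_affinity >= threshold, , drop = FALSE]
  hs <- hs[order(hs$chain, hs$resno), , drop = FALSE]
  rownames(hs) <- NULL
  hs
}
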