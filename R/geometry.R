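# Per-pose interaction profiling: geometric hydrogen bonds, attractive van
# der Waals contacts, and Shrake-Rupley buried surface area.

#' Geometric parameters for pose profiling
#'
#' @param hbond_distance_cutoff donor-acceptor heavy-atom distance cutoff
#'   (Angstrom). Default 3.5.
#' @param hbond_angle_cutoff D-H...A angle cutoff (degrees), applied only
#'   when explicit hydrogens are present. Default 120.
#' @param vdw_ratio_window attractive-contact window on
#'   `d / (r_i + r_j)`: pairs inside count as favourable packing; below is
#'   a clash, above is no contact. Default `c(0.89, 1.30)`.
#' @param sasa_probe_radius solvent probe radius (Angstrom). Default 1.4.
#' @param sasa_points points of the deterministic golden-spiral lattice per
#'   atom. Default 960.
#' @return object of class `"GeometryParams"`.
#' @export
geometry_params <- function(hbond_distance_cutoff = 3.5,
                            hbond_angle_cutoff = 120,
                            vdw_ratio_window = c(0.89, 1.30),
                            sasa_probe_radius = 1.4,
                            sasa_points = 960) {
  stopifnot(hbond_distance_cutoff > 0, hbond_angle_cutoff > 0,
            length(vdw_ratio_window) == 2L, all(vdw_ratio_window > 0),
            vdw_ratio_window[1] < vdw_ratio_window[2],
            sasa_probe_radius > 0, sasa_points >= 8)
  structure(list(hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 vdw_ratio_window = vdw_ratio_window,
                 sasa_probe_radius = sasa_probe_radius,
                 sasa_points = as.integer(sasa_points)),
            class = "GeometryParams")
}

.as_receptor_atoms <- function(receptor) {
  if (inherits(receptor, "Complex")) complex_side(receptor, "receptor")
  else receptor
}

#' Build a ligand atom table
#'
#' Convenience constructor for free (non-protein) atom sets: assigns Bondi
#' radii from the element and zero partial charge unless given.
#'
#' @param element element symbols.
#' @param coords n x 3 matrix of coordinates (Angstrom).
#' @param atom_name optional atom names (defaults to element + index).
#' @return atom data.frame compatible with the profiling functions.
#' @export
ligand_atoms <- function(element, coords, atom_name = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  stopifnot(length(element) == nrow(coords))
  el <- .normalize_element(element)
  ep <- element_params(el)
  if (is.null(atom_name)) atom_name <- paste0(el, seq_along(el))
  data.frame(id = seq_along(el), atom_name = atom_name, element = el,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             resname = "LIG", resno = 1L, chain = "X",
             vdw_radius = ep$vdw_radius, partial_charge = 0,
             is_heavy = el != "H", stringsAsFactors = FALSE)
}

.polar_elements <- c("N", "O", "S")

# Hydrogens covalently attached to each atom of a table (same table),
# inferred by distance < 1.25 A. Returns list of coordinate matrices.
.attached_hydrogens <- function(atoms) {
  el <- .normalize_element(atoms$element)
  h <- which(el == "H")
  out <- vector("list", nrow(atoms))
  if (length(h) == 0L) return(out)
  heavy <- which(el != "H")
  if (length(heavy) == 0L) return(out)
  d2 <- cross_dist2(atom_coords(atoms[heavy, , drop = FALSE]),
                    atom_coords(atoms[h, , drop = FALSE]))
  for (j in seq_along(h)) {
    i <- which.min(d2[, j])
    if (d2[i, j] < 1.25^2) {
      k <- heavy[i]
      out[[k]] <- rbind(out[[k]], as.numeric(atoms[h[j], c("x", "y", "z")]))
    }
  }
  out
}

.dha_angle <- function(d_xyz, h_xyz, a_xyz) {
  v1 <- d_xyz - h_xyz
  v2 <- a_xyz - h_xyz
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect geometric hydrogen bonds between receptor and ligand
#'
#' Enumerates polar heavy-atom pairs (N/O/S on either side, donors and
#' acceptors treated symmetrically) with donor-acceptor distance at or below
#' the cutoff. When explicit hydrogens are attached to a candidate donor,
#' the D-H...A angle must additionally meet the angle cutoff; with no
#' hydrogens on either atom the criterion is distance-only, which is the
#' common convention for crystal structures deposited without protons.
#'
#' @param receptor a `Complex` (receptor side is used) or an atom table.
#' @param ligand ligand atom table (see [ligand_atoms()]); must be
#'   non-empty.
#' @param params a [geometry_params()] object.
#' @return data.frame with one row per hydrogen bond: receptor residue
#'   (`chain`, `resno`, `resname`, `label`), `receptor_atom`, `ligand_atom`,
#'   `donor_side`, `distance`, `angle` (NA when no hydrogens).
#' @export
detect_hbonds <- function(receptor, ligand, params = geometry_params()) {
  rec <- .as_receptor_atoms(receptor)
  if (is.null(ligand) || nrow(ligand) == 0L)
    stop("ligand atom set is empty", call. = FALSE)
  rec_h <- .attached_hydrogens(rec)
  lig_h <- .attached_hydrogens(ligand)
  rp <- which(.normalize_element(rec$element) %in% .polar_elements)
  lp <- which(.normalize_element(ligand$element) %in% .polar_elements)
  out <- data.frame(chain = character(), resno = integer(),
                    resname = character(), label = character(),
                    receptor_atom = character(), ligand_atom = character(),
                    donor_side = character(), distance = numeric(),
                    angle = numeric(), stringsAsFactors = FALSE)
  if (length(rp) == 0L || length(lp) == 0L) return(out)
  d2 <- cross_dist2(atom_coords(rec[rp, , drop = FALSE]),
                    atom_coords(ligand[lp, , drop = FALSE]))
  cut2 <- params$hbond_distance_cutoff^2
  hits <- which(d2 <= cut2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(out)
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    i <- rp[hits[k, 1]]; j <- lp[hits[k, 2]]
    ri <- as.numeric(rec[i, c("x", "y", "z")])
    lj <- as.numeric(ligand[j, c("x", "y", "z")])
    dist <- sqrt(sum((ri - lj)^2))
    hi <- rec_h[[i]]; hj <- lig_h[[j]]
    angle <- NA_real_; donor <- NA_character_; ok <- FALSE
    if (is.null(hi) && is.null(hj)) {
      ok <- TRUE; donor <- "ligand"   # convention when protons are absent
    } else {
      best <- -Inf
      if (!is.null(hi)) for (m in seq_len(nrow(hi))) {
        a <- .dha_angle(ri, hi[m, ], lj)
        if (a > best) { best <- a; donor <- "receptor" }
      }
      if (!is.null(hj)) for (m in seq_len(nrow(hj))) {
        a <- .dha_angle(lj, hj[m, ], ri)
        if (a > best) { best <- a; donor <- "ligand" }
      }
      if (best >= params$hbond_angle_cutoff) { ok <- TRUE; angle <- best }
    }
    if (!ok) return(NULL)
    data.frame(chain = rec$chain[i], resno = rec$resno[i],
               resname = rec$resname[i],
               label = residue_label(rec$resname[i], rec$resno[i]),
               receptor_atom = rec$atom_name[i],
               ligand_atom = ligand$atom_name[j],
               donor_side = donor, distance = dist, angle = angle,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(out)
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno, out$receptor_atom, out$ligand_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count attractive van der Waals contacts
#'
#' A heavy-atom receptor-ligand pair counts as an attractive contact when
#' its distance over the sum of Bondi radii falls inside the ratio window
#' (default `[0.89, 1.30]`): near-van-der-Waals packing, excluding clashes
#' and distant pairs.
#'
#' @inheritParams detect_hbonds
#' @return list with `count` (integer) and `by_residue` (data.frame
#'   `chain`, `resno`, `resname`, `label`, `contacts`).
#' @export
count_attractive_vdw <- function(receptor, ligand,
                                 params = geometry_params()) {
  rec <- .as_receptor_atoms(receptor)
  rec <- rec[.normalize_element(rec$element) != "H", , drop = FALSE]
  lig <- ligand[.normalize_element(ligand$element) != "H", , drop = FALSE]
  empty <- data.frame(chain = character(), resno = integer(),
                      resname = character(), label = character(),
                      contacts = integer(), stringsAsFactors = FALSE)
  if (nrow(rec) == 0L || nrow(lig) == 0L)
    return(list(count = 0L, by_residue = empty))
  d <- sqrt(cross_dist2(atom_coords(rec), atom_coords(lig)))
  ratio <- d / outer(rec$vdw_radius, lig$vdw_radius, "+")
  w <- params$vdw_ratio_window
  inside <- ratio >= w[1] & ratio <= w[2]
  per_atom <- rowSums(inside)
  if (sum(per_atom) == 0L) return(list(count = 0L, by_residue = empty))
  key <- paste(rec$chain, rec$resno, sep = "\r")
  counts <- tapply(per_atom, key, sum)
  first <- rec[!duplicated(key), , drop = FALSE]
  first_key <- key[!duplicated(key)]
  by_res <- data.frame(chain = first$chain, resno = first$resno,
                       resname = first$resname,
                       label = residue_label(first$resname, first$resno),
                       contacts = as.integer(counts[first_key]),
                       stringsAsFactors = FALSE)
  by_res <- by_res[by_res$contacts > 0L, , drop = FALSE]
  by_res <- by_res[order(by_res$chain, by_res$resno), , drop = FALSE]
  rownames(by_res) <- NULL
  list(count = as.integer(sum(per_atom)), by_residue = by_res)
}

# Deterministic golden-spiral (Fibonacci) unit lattice, n x 3.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA over heavy atoms, using a fixed deterministic golden-spiral
#' lattice (bit-stable across runs, unlike random sampling) on spheres of
#' radius `vdw + probe`.
#'
#' @param atoms atom table with `vdw_radius` and coordinates.
#' @param params a [geometry_params()] object.
#' @return numeric vector of per-atom SASA (Angstrom^2) for the heavy atoms,
#'   with total as attribute; sum with `sum()`.
#' @export
sasa_atoms <- function(atoms, params = geometry_params()) {
  at <- atoms[.normalize_element(atoms$element) != "H", , drop = FALSE]
  n <- nrow(at)
  if (n == 0L) return(numeric(0))
  pts <- golden_spiral_points(params$sasa_points)
  xyz <- atom_coords(at)
  rr <- at$vdw_radius + params$sasa_probe_radius
  d2 <- cross_dist2(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    sp <- pts * rr[i]
    sp <- sweep(sp, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj >= rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * mean(exposed)
  }
  out
}

#' Buried surface area of a receptor-ligand pose
#'
#' `BSA = SASA(receptor) + SASA(ligand) - SASA(complex)`: the total area
#' buried on both partners (two-sided convention). Clamped at zero against
#' lattice discretization noise.
#'
#' @inheritParams detect_hbonds
#' @return scalar BSA (Angstrom^2).
#' @export
buried_surface_area <- function(receptor, ligand,
                                params = geometry_params()) {
  rec <- .as_receptor_atoms(receptor)
  common <- c("x", "y", "z", "element", "vdw_radius")
  both <- rbind(rec[, common, drop = FALSE], ligand[, common, drop = FALSE])
  bsa <- sum(sasa_atoms(rec, params)) + sum(sasa_atoms(ligand, params)) -
    sum(sasa_atoms(both, params))
  max(bsa, 0)
}

#' Profile a docked pose
#'
#' Aggregates hydrogen bonds, attractive van der Waals contacts and buried
#' surface area into one record; the docking score is an externally computed
#' quantity and is only carried through.
#'
#' @inheritParams detect_hbonds
#' @param docking_score ingested docking score (kcal/mol) or NA.
#' @param molecule_id identifier for the pose.
#' @return object of class `"PoseProfile"`: a list with `molecule_id`,
#'   `hbonds` (data.frame), `hbond_residues` (residue labels),
#'   `vdw_contact_count`, `vdw_by_residue`, `vdw_residues`, `bsa`,
#'   `docking_score`.
#' @export
profile_pose <- function(receptor, ligand, params = geometry_params(),
                         docking_score = NA_real_, molecule_id = "pose") {
  if (is.null(ligand) || nrow(ligand) == 0L)
    stop("ligand atom set is empty", call. = FALSE)
  hb <- detect_hbonds(receptor, ligand, params)
  vdw <- count_attractive_vdw(receptor, ligand, params)
  structure(list(
    molecule_id = molecule_id,
    hbonds = hb,
    hbond_residues = unique(hb$label),
    vdw_contact_count = vdw$count,
    vdw_by_residue = vdw$by_residue,
    vdw_residues = vdw$by_residue$label,
    bsa = buried_surface_area(receptor, ligand, params),
    docking_score = docking_score), class = "PoseProfile")
}

#' @export
print.PoseProfile <- function(x, ...) {
  cat("PoseProfile", x$molecule_id, "|",
      length(x$hbond_residues), "H-bond residue(s):",
      paste(x$hbond_residues, collapse = ","), "|",
      x$vdw_contact_count, "attractive VDW contact(s) |",
      "BSA", round(x$bsa, 1), "A^2 |",
      "docking score", x$docking_score, "\n")
  invisible(x)
}
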