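# Fixture builders and independent brute-force oracles. The oracles use
# plain scalar double loops so they share no code path with the vectorized
# implementations they check.

# Random free atom set (elements C/N/O/S) in a box.
random_atoms <- function(n, seed, box = 12, elements = c("C", "N", "O", "S")) {
  set.seed(seed)
  ligand_atoms(sample(elements, n, replace = TRUE),
               matrix(runif(3 * n, 0, box), n, 3))
}

# Assemble a Complex from two free atom tables (chains A and B). Receptor
# atoms are grouped into residues of `res_size` consecutive atoms.
two_chain_complex <- function(rec, lig, res_size = 4) {
  rec$chain <- "A"
  rec$resno <- (seq_len(nrow(rec)) - 1) %/% res_size + 1L
  rec$resname <- "VAL"
  lig$chain <- "B"
  lig$resno <- 1L
  lig$resname <- "LIG"
  atoms <- rbind(rec, lig)
  atoms$id <- seq_len(nrow(atoms))
  new_complex(atoms, "A", "B")
}

# A receptor residue with a real side chain (beyond C-beta) plus backbone,
# positioned explicitly, with partner atoms nearby. Used by alanine-scan
# tests; returns the complex and the names of the removable atoms.
scan_fixture <- function(sidechain_xyz = matrix(c(0, 0, 0), 1),
                         partner_xyz = matrix(c(3.5, 0, 0), 1),
                         partner_elements = "O",
                         resname = "GLN") {
  ns <- nrow(sidechain_xyz)
  rec <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", paste0("CG", seq_len(ns))),
    element = c("N", "C", "C", "O", "C", rep("C", ns)),
    x = c(-30, -29, -28, -27, -26, sidechain_xyz[, 1]),
    y = c(0, 0, 0, 0, 0, sidechain_xyz[, 2]),
    z = c(0, 0, 0, 0, 0, sidechain_xyz[, 3]),
    resname = resname, resno = 1L, chain = "A",
    stringsAsFactors = FALSE)
  np <- nrow(partner_xyz)
  lig <- data.frame(
    atom_name = paste0("P", seq_len(np)),
    element = partner_elements,
    x = partner_xyz[, 1], y = partner_xyz[, 2], z = partner_xyz[, 3],
    resname = "LIG", resno = 1L, chain = "B",
    stringsAsFactors = FALSE)
  atoms <- rbind(rec, lig)
  atoms$id <- seq_len(nrow(atoms))
  ep <- element_params(atoms$element)
  atoms$vdw_radius <- ep$vdw_radius
  atoms$partial_charge <- assign_partial_charges(atoms$resname,
                                                 atoms$atom_name,
                                                 atoms$element)
  new_complex(atoms, "A", "B")
}

# Scalar pairwise energy term, written independently of pair_energy_matrix.
oracle_pair_energy <- function(a, b, params = energy_params()) {
  total <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    dx <- a$x[i] - b$x[j]; dy <- a$y[i] - b$y[j]; dz <- a$z[i] - b$z[j]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (r > params$interaction_cutoff) next
    ei <- element_params(a$element[i])$lj_epsilon
    ej <- element_params(b$element[j])$lj_epsilon
    rmin <- a$vdw_radius[i] + b$vdw_radius[j]
    lj <- sqrt(ei * ej) * ((rmin / r)^12 - 2 * (rmin / r)^6)
    coul <- params$coulomb_constant * a$partial_charge[i] *
      b$partial_charge[j] / (params$dielectric_slope * r^2)
    total <- total + lj + coul
  }
  total
}

# Exhaustive O(n^2) interface-residue scan.
oracle_interface <- function(cx, cutoff) {
  rec <- complex_side(cx, "receptor", heavy_only = TRUE)
  par <- complex_side(cx, "partner", heavy_only = TRUE)
  hits <- character(0)
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(par))) {
    d <- sqrt((rec$x[i] - par$x[j])^2 + (rec$y[i] - par$y[j])^2 +
                (rec$z[i] - par$z[j])^2)
    if (d <= cutoff)
      hits <- c(hits, paste(rec$chain[i], rec$resno[i]))
  }
  sort(unique(hits))
}

# Exhaustive hydrogen-bond enumeration (distance-only; fixtures carry no
# explicit hydrogens).
oracle_hbonds <- function(rec, lig, cutoff = 3.5) {
  polar <- c("N", "O", "S")
  out <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (!(rec$element[i] %in% polar)) next
    for (j in seq_len(nrow(lig))) {
      if (!(lig$element[j] %in% polar)) next
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff)
        out <- c(out, paste(rec$resno[i], rec$atom_name[i],
                            lig$atom_name[j]))
    }
  }
  sort(out)
}

# Exhaustive attractive-contact count.
oracle_vdw_count <- function(rec, lig, window = c(0.89, 1.30)) {
  count <- 0
  for (i in seq_len(nrow(rec))) {
    if (rec$element[i] == "H") next
    for (j in seq_len(nrow(lig))) {
      if (lig$element[j] == "H") next
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      ratio <- d / (rec$vdw_radius[i] + lig$vdw_radius[j])
      if (ratio >= window[1] && ratio <= window[2]) count <- count + 1
    }
  }
  as.integer(count)
}

# Random rigid transformation (proper rotation + translation).
apply_rigid <- function(atoms, seed) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3)
  qr_out <- qr(q)
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- runif(3, -20, 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
  atoms$x <- xyz[, 1] + t_vec[1]
  atoms$y <- xyz[, 2] + t_vec[2]
  atoms$z <- xyz[, 3] + t_vec[3]
  atoms
}

rigid_complex <- function(cx, seed) {
  atoms <- apply_rigid(cx$atoms, seed)
  new_complex(atoms, cx$receptor_chains, cx$partner_chains)
}

# Minimal two-chain PDB text fixture: n atoms per chain, valid fixed-width
# records.
toy_pdb_text <- function(n_per_chain = 10, element_override = NULL) {
  fmt <- function(serial, name, res, chain, resno, x, y, z, el)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, chain, resno, x, y, z, el)
  lines <- character(0)
  serial <- 0
  for (chain in c("A", "B")) {
    for (i in seq_len(n_per_chain)) {
      serial <- serial + 1
      el <- if (!is.null(element_override) && serial == 1) element_override
            else c("C", "N", "O")[(i %% 3) + 1]
      x <- if (chain == "A") i * 2 else i * 2 + 3
      lines <- c(lines, fmt(serial, paste0(el, i), "GLY", chain, i,
                            x, 0, 0, el))
    }
  }
  c(lines, "END")
}
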