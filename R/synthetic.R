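# Synthetic-data generators with machine-readable ground-truth ledgers.
# Every generator returns the truth it planted alongside the data, and all
# downstream recovery tests assert against that ledger. The geometry is not
# physically realistic protein structure and is not meant to be: residues
# are laid out sparsely so each planted interaction is provably the only
# interaction its atoms make.

#' Specification of a toy two-chain complex
#'
#' @param n_receptor_residues number of receptor residues (chain A).
#' @param planted_hbond_residues residue numbers that receive exactly one
#'   planted hydrogen bond (a ligand oxygen 2.65 Angstrom from the residue's
#'   backbone nitrogen: inside the 3.5 Angstrom H-bond cutoff but below the
#'   attractive-VDW ratio window, so it never also counts as a contact).
#' @param planted_contact_counts named integer vector
#'   (names = residue numbers) of attractive VDW contacts to plant (ligand
#'   carbons at exactly the sum of Bondi radii from the residue's C-beta);
#'   at most 8 per residue.
#' @param ligand_atom_count minimum ligand atom count; inert carbons are
#'   added far from the receptor to reach it.
#' @param seed integer seed (placement of inert atoms).
#' @return object of class `"ComplexSpec"`.
#' @export
toy_complex_spec <- function(n_receptor_residues = 4,
                             planted_hbond_residues = integer(0),
                             planted_contact_counts = integer(0),
                             ligand_atom_count = 1,
                             seed = 1) {
  planted_hbond_residues <- as.integer(planted_hbond_residues)
  if (length(planted_contact_counts) > 0 &&
      is.null(names(planted_contact_counts)))
    stop("planted_contact_counts must be named by residue number",
         call. = FALSE)
  cc_res <- as.integer(names(planted_contact_counts))
  if (any(planted_hbond_residues > n_receptor_residues) ||
      any(planted_hbond_residues < 1) ||
      any(cc_res > n_receptor_residues) || any(cc_res < 1))
    stop("planted residues outside 1..n_receptor_residues", call. = FALSE)
  if (any(planted_contact_counts < 0) || any(planted_contact_counts > 8))
    stop("infeasible spec: planted contact counts must be in 0..8 ",
         "(placements would overlap)", call. = FALSE)
  structure(list(n_receptor_residues = as.integer(n_receptor_residues),
                 planted_hbond_residues = planted_hbond_residues,
                 planted_contact_counts = planted_contact_counts,
                 ligand_atom_count = as.integer(ligand_atom_count),
                 seed = as.integer(seed)),
            class = "ComplexSpec")
}

.toy_residue_names <- c("LEU", "SER", "THR", "VAL", "PHE", "ASN", "GLN",
                        "ILE")

#' Generate a toy two-chain complex with planted interactions
#'
#' Receptor residues (chain A) are spaced 12 Angstrom apart with their
#' backbone nitrogen exposed near the z = 0 plane and all other atoms moved
#' to z = 20, so a planted hydrogen bond touches only that nitrogen and a
#' planted contact touches only that C-beta. The partner/ligand atoms form
#' chain B. The returned truth ledger records exactly what profiling should
#' recover.
#'
#' @param spec a [toy_complex_spec()].
#' @return list: `complex` (a `Complex`, chains A/B), `receptor` and
#'   `ligand` atom tables, and `truth` (ledger with `hbond_residues`,
#'   `vdw_counts` named by residue label, `vdw_total`).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "ComplexSpec"))
  set.seed(spec$seed)
  n <- spec$n_receptor_residues
  rec_rows <- list()
  for (i in seq_len(n)) {
    resname <- .toy_residue_names[(i - 1) %% length(.toy_residue_names) + 1]
    x0 <- 12 * i
    rec_rows[[i]] <- data.frame(
      atom_name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = c(x0, x0, x0, x0, x0),
      y = c(0, 0, 1.5, 3.0, -1.5),
      z = c(0, 20, 20, 20, 20),
      resname = resname, resno = i, chain = "A",
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec_rows)

  lig_rows <- list()
  truth_hb <- character(0)
  truth_vdw <- integer(0)
  res_label <- function(i)
    residue_label(rec$resname[rec$resno == i][1], i)
  for (i in spec$planted_hbond_residues) {
    # 2.65 A below the backbone N: H-bond range, sub-window ratio 0.863
    lig_rows[[length(lig_rows) + 1L]] <- data.frame(
      atom_name = paste0("O", i), element = "O",
      x = 12 * i, y = -2.65, z = 0, stringsAsFactors = FALSE)
    truth_hb <- c(truth_hb, res_label(i))
  }
  r_cc <- 2 * 1.70  # C-C Bondi radius sum: ratio exactly 1 (mid-window)
  for (nm in names(spec$planted_contact_counts)) {
    i <- as.integer(nm)
    cnt <- spec$planted_contact_counts[[nm]]
    if (cnt == 0) next
    cb <- c(12 * i, -1.5, 20)
    for (k in seq_len(cnt)) {
      ang <- 2 * pi * (k - 1) / 8
      u <- c(0.35 * sin(ang), -1, 0.35 * cos(ang))
      u <- u / sqrt(sum(u^2))
      p <- cb + r_cc * u
      lig_rows[[length(lig_rows) + 1L]] <- data.frame(
        atom_name = paste0("C", i, "_", k), element = "C",
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
    truth_vdw[res_label(i)] <- cnt
  }
  n_planted <- length(lig_rows)
  if (n_planted < spec$ligand_atom_count) {
    extra <- spec$ligand_atom_count - n_planted
    for (k in seq_len(extra)) {
      lig_rows[[length(lig_rows) + 1L]] <- data.frame(
        atom_name = paste0("CX", k), element = "C",
        x = 12 * k + stats::runif(1, -1, 1), y = stats::runif(1, -1, 1),
        z = -60, stringsAsFactors = FALSE)
    }
  }
  lig <- do.call(rbind, lig_rows)
  lig$resname <- "LIG"; lig$resno <- 1L; lig$chain <- "B"

  atoms <- rbind(rec, lig)
  atoms$id <- seq_len(nrow(atoms))
  ep <- element_params(atoms$element)
  atoms$vdw_radius <- ep$vdw_radius
  atoms$partial_charge <- assign_partial_charges(atoms$resname,
                                                 atoms$atom_name,
                                                 atoms$element)
  cx <- new_complex(atoms, "A", "B")
  list(complex = cx,
       receptor = complex_side(cx, "receptor"),
       ligand = complex_side(cx, "partner"),
       truth = list(hbond_residues = truth_hb,
                    vdw_counts = truth_vdw,
                    vdw_total = sum(truth_vdw)))
}

#' Generate pose records with known Best/Worst structure
#'
#' Draws records inside the Best region, the Worst region, or the gap
#' between them (per the given fractions), so [label_best_worst()] must
#' recover the planted labels exactly.
#'
#' @param n number of records.
#' @param best_fraction,worst_fraction fractions of records planted in each
#'   region (sum at most 1); the remainder lands in the gap.
#' @param thresholds a [label_thresholds()] object.
#' @param seed integer seed.
#' @return list: `records` (pose-record data.frame) and `truth` (planted
#'   label vector).
#' @export
make_pose_table <- function(n, best_fraction = 68 / 137,
                            worst_fraction = 69 / 137,
                            thresholds = label_thresholds(), seed = 1) {
  stopifnot(best_fraction >= 0, worst_fraction >= 0,
            best_fraction + worst_fraction <= 1 + 1e-12)
  set.seed(as.integer(seed))
  n_best <- round(n * best_fraction)
  n_worst <- round(n * worst_fraction)
  n_best <- min(n_best, n); n_worst <- min(n_worst, n - n_best)
  n_mid <- n - n_best - n_worst
  b <- thresholds$best; w <- thresholds$worst
  gap_lo <- b$score_below; gap_hi <- w$score_at_least
  draw <- function(m, region) {
    if (m == 0) return(NULL)
    switch(region,
      Best = data.frame(
        docking_score = stats::runif(m, b$score_below - 5,
                                     b$score_below - 0.1),
        vdw_contacts = sample(b$vdw_at_least:(b$vdw_at_least + 250), m,
                              replace = TRUE),
        bsa = stats::runif(m, b$bsa_at_least, b$bsa_at_least + 350)),
      Worst = data.frame(
        docking_score = stats::runif(m, w$score_at_least,
                                     w$score_at_least + 1),
        vdw_contacts = sample(0:w$vdw_at_most, m, replace = TRUE),
        bsa = stats::runif(m, max(0, w$bsa_at_most - 300), w$bsa_at_most)),
      neither = data.frame(
        docking_score = stats::runif(m, gap_lo + 0.1, gap_hi - 0.1),
        vdw_contacts = sample((w$vdw_at_most + 1):(b$vdw_at_least - 1), m,
                              replace = TRUE),
        bsa = stats::runif(m, w$bsa_at_most + 1, b$bsa_at_least - 1)))
  }
  recs <- rbind(draw(n_best, "Best"), draw(n_worst, "Worst"),
                draw(n_mid, "neither"))
  truth <- rep(c("Best", "Worst", "neither"), c(n_best, n_worst, n_mid))
  ord <- sample.int(n)
  recs <- recs[ord, , drop = FALSE]
  truth <- truth[ord]
  recs <- cbind(molecule_id = sprintf("SYN%05d", seq_len(n)), recs,
                stringsAsFactors = FALSE)
  rownames(recs) <- NULL
  list(records = recs, truth = truth)
}

#' Specification of a planted-signal learning set
#'
#' Defaults emulate the reference learning-set geometry: 68 Best and 69 Worst
#' molecules described by 206 descriptors. `n_informative` descriptors
#' separate the classes by `effect_size` pooled standard deviations; the
#' rest are pure standard-normal noise.
#'
#' @param n_best,n_worst class sizes.
#' @param n_descriptors total descriptors.
#' @param n_informative descriptors carrying the class shift
#'   (<= n_descriptors).
#' @param effect_size class-mean separation in pooled SDs (>= 0).
#' @param seed integer seed.
#' @return object of class `"LearningSetSpec"`.
#' @export
learning_set_spec <- function(n_best = 68, n_worst = 69,
                              n_descriptors = 206, n_informative = 3,
                              effect_size = 2, seed = 1) {
  stopifnot(n_informative <= n_descriptors, effect_size >= 0,
            n_best >= 1, n_worst >= 1)
  structure(list(n_best = as.integer(n_best), n_worst = as.integer(n_worst),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "LearningSetSpec")
}

#' Generate a labeled learning set with a planted Best/Worst separation
#'
#' Worst rows are standard normal in every descriptor; Best rows are shifted
#' by the effect size in the informative descriptors only (unit SD in both
#' classes, so the shift is in pooled-SD units and scale-free).
#'
#' @param spec a [learning_set_spec()].
#' @return a labeled [descriptor_table()]; `truth` attribute lists the
#'   informative descriptor names, class sizes and effect size.
#' @export
make_learning_set <- function(spec) {
  stopifnot(inherits(spec, "LearningSetSpec"))
  set.seed(spec$seed)
  p <- spec$n_descriptors
  nb <- spec$n_best; nw <- spec$n_worst
  informative <- sample.int(p, spec$n_informative)
  vals <- matrix(stats::rnorm((nb + nw) * p), nb + nw, p)
  vals[seq_len(nb), informative] <- vals[seq_len(nb), informative] +
    spec$effect_size
  colnames(vals) <- sprintf("d%03d", seq_len(p))
  ids <- c(sprintf("BEST%03d", seq_len(nb)), sprintf("WORST%03d", seq_len(nw)))
  label <- rep(c("Best", "Worst"), c(nb, nw))
  tab <- descriptor_table(ids, vals, label)
  attr(tab, "truth") <- list(
    informative = colnames(vals)[sort(informative)],
    n_best = nb, n_worst = nw, effect_size = spec$effect_size,
    seed = spec$seed)
  tab
}

#' Write a Complex to a PDB file
#'
#' Serializes the atom table as standard fixed-width ATOM records (via
#' \pkg{bio3d}), so synthetic complexes can round-trip through
#' [parse_complex()] and feed the command-line tools.
#'
#' @param complex a `Complex`.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "Complex"))
  at <- complex$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atom_coords(at))),
                   resno = at$resno, resid = at$resname,
                   chain = at$chain, elety = at$atom_name,
                   eleno = at$id, elesy = at$element)
  invisible(path)
}
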