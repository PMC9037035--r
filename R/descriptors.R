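# Open 2D molecular descriptor set.
#
# A fixed, versioned panel of constitutional, topological and
# physicochemical 2D descriptors computed from SMILES/SDF input. The panel
# is declared by name in a manifest (see descriptor_manifest()) so that any
# model trained on it is reproducible. Physicochemical terms come from Open
# Babel (via ChemmineOB); graph terms are computed on the heavy-atom
# connectivity graph after canonicalization, so descriptor values do not
# depend on how the input structure was spelled.

#' Construct a DescriptorTable
#'
#' @param molecule_ids character ids, one per row of `values`.
#' @param values numeric matrix (molecules x descriptors) with column names.
#' @param label optional per-molecule class labels (`"Best"`/`"Worst"`).
#' @return object of class `"DescriptorTable"`.
#' @export
descriptor_table <- function(molecule_ids, values, label = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("descriptor matrix must have column names", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("descriptor names must be unique", call. = FALSE)
  if (length(molecule_ids) != nrow(values))
    stop("molecule_ids length must match the number of rows", call. = FALSE)
  if (any(!is.finite(values)))
    stop("descriptor matrix contains non-finite values", call. = FALSE)
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != nrow(values))
      stop("label length must match the number of rows", call. = FALSE)
  }
  structure(list(molecule_ids = as.character(molecule_ids),
                 descriptor_names = colnames(values),
                 values = values,
                 label = label),
            class = "DescriptorTable")
}

#' @export
print.DescriptorTable <- function(x, ...) {
  cat("DescriptorTable:", nrow(x$values), "molecules x",
      ncol(x$values), "descriptors",
      if (!is.null(x$label)) paste0("(labeled: ",
        paste(names(table(x$label)), table(x$label),
              sep = "=", collapse = ", "), ")"), "\n")
  invisible(x)
}

.formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  out <- c(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0, F = 0,
           CL = 0, BR = 0, I = 0, B = 0, SE = 0)
  for (t in toks) {
    el <- .normalize_element(gsub("[0-9]", "", t))
    k <- suppressWarnings(as.numeric(gsub("[^0-9]", "", t)))
    if (is.na(k)) k <- 1
    if (el %in% names(out)) out[el] <- out[el] + k
  }
  out
}

# Descriptor vector for one molecule: heavy-atom bond-order matrix `cm`
# (square, entries 0/1/2/3), element symbols, and the Open Babel property
# row (MW, logP, TPSA, MR, HBA1, HBA2, HBD, nF, formula).
.mol_descriptors <- function(cm, elements, prop) {
  n <- length(elements)
  adj <- (cm > 0) * 1L
  deg <- unname(rowSums(adj))
  m <- sum(adj) / 2
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  D <- igraph::distances(g)
  finite_off <- is.finite(D) & D > 0

  fc <- .formula_counts(prop$formula)
  ep <- element_params(elements)

  bridges <- igraph::bridges(g)
  non_bridge <- setdiff(seq_len(max(m, 0)), as.integer(bridges))
  el_mat <- igraph::as_edgelist(g, names = FALSE)
  ring_atoms <- if (m > 0 && length(non_bridge) > 0)
    unique(as.vector(el_mat[non_bridge, , drop = FALSE])) else integer(0)

  cyclomatic <- m - n + comp$no

  d_off <- D[finite_off]
  wiener <- sum(d_off) / 2
  harary <- sum(1 / d_off) / 2
  ecc <- unname(apply(D, 1L, function(r) max(r[is.finite(r)])))
  diameter <- max(ecc)
  radius <- min(ecc)

  zagreb1 <- sum(deg^2)
  edge_deg <- if (m > 0) cbind(deg[el_mat[, 1]], deg[el_mat[, 2]])
    else matrix(0, 0, 2)
  zagreb2 <- sum(edge_deg[, 1] * edge_deg[, 2])
  platt <- sum(edge_deg[, 1] + edge_deg[, 2] - 2)
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (m > 0) sum(1 / sqrt(edge_deg[, 1] * edge_deg[, 2])) else 0

  # simple connectivity chi over 2- and 3-edge paths
  chi2 <- 0; p2 <- 0
  for (j in seq_len(n)) {
    nb <- which(adj[j, ] > 0)
    if (length(nb) >= 2) {
      prs <- utils::combn(nb, 2)
      p2 <- p2 + ncol(prs)
      chi2 <- chi2 + sum(1 / sqrt(deg[prs[1, ]] * deg[j] * deg[prs[2, ]]))
    }
  }
  chi3 <- 0; p3 <- 0
  if (m > 0) for (e in seq_len(nrow(el_mat))) {
    j <- el_mat[e, 1]; k <- el_mat[e, 2]
    for (i in setdiff(which(adj[j, ] > 0), k))
      for (l in setdiff(which(adj[k, ] > 0), c(j, i))) {
        p3 <- p3 + 1
        chi3 <- chi3 + 1 / sqrt(deg[i] * deg[j] * deg[k] * deg[l])
      }
  }

  kappa1 <- if (m > 0) n * (n - 1)^2 / m^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) (n - 1) * (n - 3)^2 / p3^2 else 0

  balaban <- 0
  if (m > 0 && comp$no == 1L) {
    s <- rowSums(D)
    balaban <- m / (cyclomatic + 1) *
      sum(1 / sqrt(s[el_mat[, 1]] * s[el_mat[, 2]]))
  }
  ecc_conn <- sum(ecc * deg)

  bond_orders <- cm[upper.tri(cm)]
  bond_orders <- bond_orders[bond_orders > 0]

  out <- c(
    mw = prop$MW, logp = prop$logP, tpsa = prop$TPSA, mr = prop$MR,
    hba1 = prop$HBA1, hba2 = prop$HBA2, hbd = prop$HBD, n_fluorine = prop$nF,
    n_heavy = n, n_atoms_total = n + unname(fc["H"]), n_bonds = m,
    n_single_bonds = sum(bond_orders == 1),
    n_double_bonds = sum(bond_orders == 2),
    n_triple_bonds = sum(bond_orders >= 3),
    n_rings = cyclomatic, n_ring_atoms = length(ring_atoms),
    frac_ring_atoms = if (n > 0) length(ring_atoms) / n else 0,
    n_components = comp$no,
    count_C = unname(fc["C"]), count_H = unname(fc["H"]),
    count_N = unname(fc["N"]), count_O = unname(fc["O"]),
    count_S = unname(fc["S"]), count_P = unname(fc["P"]),
    count_F = unname(fc["F"]), count_Cl = unname(fc["CL"]),
    count_Br = unname(fc["BR"]), count_I = unname(fc["I"]),
    n_heteroatoms = n - sum(elements == "C"),
    n_halogens = unname(fc["F"] + fc["CL"] + fc["BR"] + fc["I"]),
    frac_heteroatoms = if (n > 0) (n - sum(elements == "C")) / n else 0,
    deg1_atoms = sum(deg == 1), deg2_atoms = sum(deg == 2),
    deg3_atoms = sum(deg == 3), deg4_atoms = sum(deg >= 4),
    mean_degree = if (n > 0) mean(deg) else 0, max_degree = max(deg, 0),
    mw_per_heavy = if (n > 0) prop$MW / n else 0,
    wiener = wiener, harary = harary, diameter = diameter, radius = radius,
    mean_eccentricity = mean(ecc), eccentric_connectivity = ecc_conn,
    zagreb1 = zagreb1, zagreb2 = zagreb2, platt = platt,
    balaban_j = balaban, chi0 = chi0, chi1 = chi1, chi2 = chi2, chi3 = chi3,
    kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3)

  # 2D autocorrelations over atomic mass, electronegativity, polarizability
  # and van der Waals radius at topological lags 1-8 (Moreau-Broto sum,
  # Moran and Geary coefficients).
  props <- list(mass = ep$mass, en = ep$electronegativity,
                pol = ep$polarizability, vdw = ep$vdw_radius)
  ac <- numeric(0)
  for (pn in names(props)) {
    p <- props[[pn]]
    pv <- stats::var(p) * (n - 1) / n  # population variance
    pm <- mean(p)
    for (lag in 1:8) {
      sel <- finite_off & D == lag
      nd <- sum(sel) / 2
      ats <- if (nd > 0) sum(outer(p, p)[sel]) / 2 else 0
      moran <- 0; geary <- 0
      if (nd > 0 && isTRUE(pv > 0)) {
        dev <- p - pm
        moran <- (sum(outer(dev, dev)[sel]) / (2 * nd)) / pv
        diff2 <- outer(p, p, "-")^2
        geary <- (sum(diff2[sel]) / (4 * nd)) / (pv * n / (n - 1))
      }
      ac <- c(ac, ats, moran, geary)
      names(ac)[length(ac) - 2:0] <-
        paste0(c("ats", "moran", "geary"), lag, "_", pn)
    }
  }
  res <- c(out, ac)
  res[!is.finite(res)] <- 0
  res
}

.read_molecule_input <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    if (grepl("\\.sdf$", x, ignore.case = TRUE)) {
      sdf <- ChemmineR::read.SDFset(x)
      smi <- as.character(ChemmineR::sdf2smiles(sdf))
      ids <- ChemmineR::sdfid(sdf)
      names(smi) <- make.unique(ids)
      return(smi)
    }
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[[`, character(1), 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA, "")
    ids[is.na(ids)] <- paste0("mol", which(is.na(ids)))
    names(smi) <- make.unique(ids)
    return(smi)
  }
  smi <- as.character(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(smi) <- paste0("mol", seq_along(smi))
  else names(smi) <- names(x)
  smi
}

#' Compute the open 2D descriptor panel
#'
#' Accepts SMILES (a character vector, or a path to a one-molecule-per-line
#' SMILES file with an optional id column) or an SDF file. Each molecule is
#' canonicalized first, so two spellings of the same structure yield
#' identical descriptor rows. Unparseable molecules are recorded in the
#' `"failures"` attribute and the run continues; if every molecule fails,
#' an error is raised.
#'
#' @param molecules SMILES vector or file path (`.smi`/`.txt`/`.sdf`).
#' @param min_mw if non-NULL, molecules with molecular weight at or below
#'   this value (g/mol) are excluded after computation.
#' @return a [descriptor_table()]; attributes `"failures"` (data.frame of
#'   id/error) and `"manifest"`.
#' @export
compute_descriptors <- function(molecules, min_mw = NULL) {
  smi <- .read_molecule_input(molecules)
  rows <- list(); fails <- list()
  for (id in names(smi)) {
    res <- tryCatch({
      sdf0 <- suppressWarnings(ChemmineR::smiles2sdf(smi[[id]]))
      if (length(sdf0) == 0L) stop("structure did not parse")
      prop <- suppressWarnings(ChemmineR::propOB(sdf0))
      if (nrow(prop) == 0L || !nzchar(prop$cansmi[1]))
        stop("structure did not parse")
      # rebuild from the canonical SMILES so graph and properties are
      # spelling-invariant (additive terms depend on atom order bitwise)
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(prop$cansmi[1]))
      prop <- suppressWarnings(ChemmineR::propOB(sdf))
      cm <- ChemmineR::conMA(sdf[[1]])
      ab <- ChemmineR::atomblock(sdf[[1]])
      elements <- .normalize_element(sub("_.*$", "", rownames(ab)))
      if (length(elements) == 0L) stop("no atoms parsed")
      .mol_descriptors(cm, elements, prop[1, , drop = FALSE])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[id]] <- conditionMessage(res)
    } else {
      rows[[id]] <- res
    }
  }
  if (length(rows) == 0L)
    stop("no molecule could be parsed (", length(fails), " failure(s))",
         call. = FALSE)
  values <- do.call(rbind, rows)
  if (!is.null(min_mw)) {
    keep <- values[, "mw"] > min_mw
    values <- values[keep, , drop = FALSE]
    if (nrow(values) == 0L)
      stop("all molecules excluded by the molecular-weight floor",
           call. = FALSE)
  }
  tab <- descriptor_table(rownames(values), values)
  attr(tab, "failures") <- if (length(fails) > 0)
    data.frame(molecule_id = names(fails),
               error = unlist(fails, use.names = FALSE),
               stringsAsFactors = FALSE)
    else data.frame(molecule_id = character(), error = character(),
                    stringsAsFactors = FALSE)
  attr(tab, "manifest") <- descriptor_manifest(tab)
  tab
}

#' Prune uninformative and redundant descriptors
#'
#' Drops zero-variance columns, then walks the remaining columns in manifest
#' order and drops any column with absolute Pearson correlation above 0.99
#' to an earlier kept column (so of a correlated pair, the later-named
#' column goes). Order-stable and idempotent.
#'
#' @param table a [descriptor_table()] with at least 2 molecules.
#' @param max_cor correlation threshold. Default 0.99.
#' @return the pruned `DescriptorTable`.
#' @export
prune_descriptors <- function(table, max_cor = 0.99) {
  stopifnot(inherits(table, "DescriptorTable"))
  v <- table$values
  if (nrow(v) < 2L)
    stop("pruning needs at least two molecules", call. = FALSE)
  sds <- apply(v, 2L, stats::sd)
  v <- v[, sds > 1e-12, drop = FALSE]
  keep <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    ok <- TRUE
    for (i in which(keep)) {
      r <- stats::cor(v[, i], v[, j])
      if (is.finite(r) && abs(r) > max_cor) { ok <- FALSE; break }
    }
    keep[j] <- ok
  }
  out <- descriptor_table(table$molecule_ids, v[, keep, drop = FALSE],
                          table$label)
  attr(out, "manifest") <- descriptor_manifest(out)
  out
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(x, collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Descriptor manifest
#'
#' Names, panel version and a hash of the descriptor list, recorded inside
#' trained models so a model can refuse descriptor tables it was not built
#' for.
#'
#' @param table a `DescriptorTable` (or a character vector of names).
#' @return list with `version`, `names`, `hash`.
#' @export
descriptor_manifest <- function(table) {
  nm <- if (inherits(table, "DescriptorTable")) table$descriptor_names
        else as.character(table)
  list(version = "dockscreen-2d-1.0", names = nm, hash = md5_string(nm))
}
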