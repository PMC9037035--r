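# Complex parsing, interface extraction and the frozen alanine scan.

test_that("parse_complex reads both chains, assigns parameters, rejects bad input", {
  txt <- toy_pdb_text(10)
  cx <- parse_complex(paste(txt, collapse = "\n"), "A", "B")
  expect_s3_class(cx, "Complex")
  expect_equal(nrow(cx$atoms), 20)
  expect_equal(cx$receptor_chains, "A")
  expect_equal(cx$partner_chains, "B")
  expect_true(all(cx$atoms$vdw_radius > 0))

  expect_error(parse_complex(paste(txt, collapse = "\n"), "A", "Q"),
               "configuration error.*Q")
  expect_error(parse_complex(paste(toy_pdb_text(5, "Xq"), collapse = "\n"),
                             "A", "B"),
               "Xq")
  # truncated coordinate record names its line
  bad <- txt
  bad[3] <- substr(bad[3], 1, 40)
  expect_error(parse_complex(paste(bad, collapse = "\n"), "A", "B"),
               "line 3")
})

test_that("waters are discarded and chain sets must be disjoint", {
  txt <- toy_pdb_text(5)
  wat <- sprintf(
    "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    99, "O", "HOH", "A", 99, 50, 50, 50, "O")
  cx <- parse_complex(paste(c(txt[seq_len(10)], wat, "END"),
                            collapse = "\n"), "A", "B")
  expect_false(any(cx$atoms$resname == "HOH"))
  expect_error(new_complex(cx$atoms, "A", "A"), "disjoint")
})

test_that("interface_residues applies the heavy-atom distance rule", {
  rec <- ligand_atoms(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 30)))
  lig <- ligand_atoms("C", matrix(c(3, 0, 0), 1))
  cx <- two_chain_complex(rec, lig, res_size = 1)
  got <- interface_residues(cx, 4.5)
  expect_equal(got$resno, 1L)           # 3.0 A < 4.5 A: residue 1 only
  far <- two_chain_complex(rec, ligand_atoms("C", matrix(c(10, 0, 30), 1)),
                           res_size = 1)
  expect_equal(nrow(interface_residues(far, 4.5)), 0L)
})

test_that("interface set matches exhaustive enumeration and grows with cutoff", {
  for (s in 1:20) {
    cx <- two_chain_complex(random_atoms(30, s), random_atoms(20, s + 500),
                            res_size = 3)
    for (cutoff in c(2.5, 4.5, 7)) {
      got <- interface_residues(cx, cutoff)
      expect_equal(sort(paste(got$chain, got$resno)),
                   oracle_interface(cx, cutoff))
    }
    small <- interface_residues(cx, 3)
    large <- interface_residues(cx, 6)
    expect_true(all(paste(small$chain, small$resno) %in%
                      paste(large$chain, large$resno)))
  }
})

test_that("alanine scan follows the glycine/alanine and out-of-range conventions", {
  cx <- scan_fixture(resname = "GLY")
  expect_equal(alanine_scan(cx, "A", 1)$delta_affinity, 0)
  cx <- scan_fixture(resname = "ALA")
  expect_equal(alanine_scan(cx, "A", 1)$delta_affinity, 0)
  # side chain entirely beyond the interaction cutoff: nothing eliminated
  far <- scan_fixture(sidechain_xyz = matrix(c(0, 0, 0), 1),
                      partner_xyz = matrix(c(50, 0, 0), 1))
  expect_equal(alanine_scan(far, "A", 1)$delta_affinity, 0)
  expect_error(alanine_scan(far, "A", 99), "lookup error")
  expect_error(alanine_scan(far, "B", 1), "lookup error")
})

test_that("delta affinity is exactly the eliminated pairwise sum", {
  # single side-chain atom against a single partner atom
  cx <- scan_fixture(sidechain_xyz = matrix(c(0, 0, 0), 1),
                     partner_xyz = matrix(c(3.4, 0, 0), 1))
  removed <- cx$atoms[cx$atoms$atom_name == "CG1", , drop = FALSE]
  partner <- complex_side(cx, "partner")
  expect_equal(alanine_scan(cx, "A", 1)$delta_affinity,
               oracle_pair_energy(removed, partner), tolerance = 1e-12)

  # multi-atom side chains against random partner clouds
  for (s in 1:10) {
    set.seed(s)
    sc <- matrix(rnorm(9, sd = 1.5), 3)
    pa <- matrix(rnorm(12, mean = 4, sd = 2), 4)
    cx <- scan_fixture(sidechain_xyz = sc, partner_xyz = pa,
                       partner_elements = sample(c("C", "N", "O"), 4,
                                                 replace = TRUE))
    removed <- cx$atoms[grepl("^CG", cx$atoms$atom_name), , drop = FALSE]
    partner <- complex_side(cx, "partner")
    expect_equal(alanine_scan(cx, "A", 1)$delta_affinity,
                 oracle_pair_energy(removed, partner), tolerance = 1e-9)
  }
})

test_that("delta affinity is invariant under rigid motion of the whole complex", {
  set.seed(42)
  cx <- scan_fixture(sidechain_xyz = matrix(rnorm(9, sd = 1.5), 3),
                     partner_xyz = matrix(rnorm(12, mean = 4, sd = 2), 4))
  base <- alanine_scan(cx, "A", 1)$delta_affinity
  for (s in 1:5) {
    moved <- rigid_complex(cx, s)
    expect_equal(alanine_scan(moved, "A", 1)$delta_affinity, base,
                 tolerance = 1e-9)
  }
})

test_that("hot-spot calling filters by threshold and nests across thresholds", {
  scan <- data.frame(chain = "A", resno = c(87, 44, 81),
                     resname = c("ARG", "TYR", "LEU"),
                     label = c("ARG87", "TYR44", "LEU81"),
                     delta_affinity = c(7.2, 4.0, 3.9),
                     is_hot_spot = NA)
  expect_equal(sort(call_hot_spots(scan, 4)$label), c("ARG87", "TYR44"))
  expect_equal(nrow(call_hot_spots(scan, 10)), 0L)

  set.seed(7)
  scan20 <- data.frame(chain = "A", resno = 1:20, resname = "VAL",
                       label = paste0("VAL", 1:20),
                       delta_affinity = runif(20, 0, 8), is_hot_spot = NA)
  # spreadsheet-style oracle: direct comparison column
  expect_equal(call_hot_spots(scan20, 4)$resno,
               sort(scan20$resno[scan20$delta_affinity >= 4]))
  for (t1 in c(2, 4, 6)) {
    sub <- call_hot_spots(scan20, t1 + 1)$resno
    expect_true(all(sub %in% call_hot_spots(scan20, t1)$resno))
  }
})
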