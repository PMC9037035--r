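# Hydrogen-bond detection, attractive-contact counting, SASA/BSA.

test_that("hydrogen-bond distance and angle criteria behave as declared", {
  rec <- ligand_atoms("N", matrix(c(0, 0, 0), 1))
  rec$resno <- 87L; rec$resname <- "ARG"; rec$chain <- "A"
  close_o <- ligand_atoms("O", matrix(c(2.9, 0, 0), 1))
  hb <- detect_hbonds(rec, close_o)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$label, "ARG87")
  expect_equal(hb$distance, 2.9)

  far_o <- ligand_atoms("O", matrix(c(3.8, 0, 0), 1))
  expect_equal(nrow(detect_hbonds(rec, far_o)), 0L)

  # explicit hydrogen: angle 155 degrees passes, 90 fails
  mk_pose <- function(theta) {
    h <- c(1.0 * cos(pi * (180 - theta) / 180),
           1.0 * sin(pi * (180 - theta) / 180), 0)
    lig <- ligand_atoms(c("O", "H"), rbind(c(2.9, 0, 0), c(2.9, 0, 0) - h))
    lig
  }
  expect_equal(nrow(detect_hbonds(rec, mk_pose(155))), 1L)
  expect_equal(nrow(detect_hbonds(rec, mk_pose(90))), 0L)
  # apolar ligand: nothing to detect
  expect_equal(nrow(detect_hbonds(rec, ligand_atoms("C", matrix(c(2.9, 0, 0), 1)))), 0L)
})

test_that("attractive-contact window excludes clashes and distant pairs", {
  rec <- ligand_atoms("C", matrix(c(0, 0, 0), 1))
  mid <- ligand_atoms("C", matrix(c(3.4, 0, 0), 1))   # ratio exactly 1.0
  expect_equal(count_attractive_vdw(rec, mid)$count, 1L)
  clash <- ligand_atoms("C", matrix(c(1.7, 0, 0), 1)) # ratio 0.5
  expect_equal(count_attractive_vdw(rec, clash)$count, 0L)
  far <- ligand_atoms("C", matrix(c(4.6, 0, 0), 1))   # ratio 1.35
  expect_equal(count_attractive_vdw(rec, far)$count, 0L)
})

test_that("hydrogen bonds and contact counts match exhaustive enumeration", {
  for (s in 1:20) {
    rec <- random_atoms(15, s, box = 10)
    rec$resno <- rep(1:5, 3); rec$resname <- "VAL"; rec$chain <- "A"
    lig <- random_atoms(15, s + 900, box = 10)
    hb <- detect_hbonds(rec, lig)
    expect_equal(sort(paste(hb$resno, hb$receptor_atom, hb$ligand_atom)),
                 oracle_hbonds(rec, lig))
    vdw <- count_attractive_vdw(rec, lig)
    expect_equal(vdw$count, oracle_vdw_count(rec, lig))
    expect_equal(sum(vdw$by_residue$contacts), vdw$count)
  }
})

test_that("contact and hydrogen-bond results are atom-order invariant", {
  rec <- random_atoms(20, 31, box = 9)
  rec$resno <- rep(1:4, 5); rec$resname <- "VAL"; rec$chain <- "A"
  lig <- random_atoms(12, 77, box = 9)
  base_vdw <- count_attractive_vdw(rec, lig)
  base_hb <- detect_hbonds(rec, lig)
  set.seed(5)
  perm_r <- sample.int(nrow(rec)); perm_l <- sample.int(nrow(lig))
  got_vdw <- count_attractive_vdw(rec[perm_r, ], lig[perm_l, ])
  got_hb <- detect_hbonds(rec[perm_r, ], lig[perm_l, ])
  expect_equal(got_vdw$count, base_vdw$count)
  expect_equal(got_vdw$by_residue, base_vdw$by_residue)
  expect_equal(sort(paste(got_hb$resno, got_hb$receptor_atom, got_hb$ligand_atom)),
               sort(paste(base_hb$resno, base_hb$receptor_atom, base_hb$ligand_atom)))
})

test_that("isolated-atom SASA matches the sphere area to lattice error", {
  for (r in c(1.52, 1.7, 1.98)) {
    at <- ligand_atoms("C", matrix(0, 1, 3))
    at$vdw_radius <- r
    analytic <- 4 * pi * (r + 1.4)^2
    expect_lt(abs(sum(sasa_atoms(at)) - analytic) / analytic, 0.01)
  }
})

test_that("two-sphere BSA matches the spherical-cap closed form within 2%", {
  a <- ligand_atoms("C", matrix(c(0, 0, 0), 1)); a$vdw_radius <- 1.7
  b <- ligand_atoms("C", matrix(c(3, 0, 0), 1)); b$vdw_radius <- 1.7
  R <- 1.7 + 1.4
  analytic <- 2 * (2 * pi * R * (R - 3 / 2))  # both caps
  got <- buried_surface_area(a, b)
  expect_lt(abs(got - analytic) / analytic, 0.02)
})

test_that("BSA vanishes for separated partners and shrinks with separation", {
  rec <- random_atoms(10, 3, box = 6)
  lig_far <- random_atoms(8, 4, box = 6)
  lig_far$x <- lig_far$x + 100
  expect_equal(buried_surface_area(rec, lig_far), 0)

  a <- ligand_atoms("C", matrix(c(0, 0, 0), 1))
  prev <- Inf
  for (d in c(2.5, 3.0, 3.5, 4.0, 5.0, 7.0)) {
    b <- ligand_atoms("C", matrix(c(d, 0, 0), 1))
    cur <- buried_surface_area(a, b)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("BSA is stable under rigid motion and lattice refinement", {
  tc <- make_toy_complex(toy_complex_spec(3, planted_hbond_residues = 1:2,
                                          planted_contact_counts = c("3" = 4),
                                          seed = 9))
  base <- buried_surface_area(tc$receptor, tc$ligand)
  expect_gt(base, 0)
  for (s in 1:3) {
    atoms <- apply_rigid(rbind(tc$receptor, tc$ligand), s)
    rec_m <- atoms[atoms$chain == "A", ]; lig_m <- atoms[atoms$chain == "B", ]
    expect_lt(abs(buried_surface_area(rec_m, lig_m) - base) / base, 0.005)
  }
  fine <- geometry_params(sasa_points = 1920)
  expect_lt(abs(buried_surface_area(tc$receptor, tc$ligand, fine) - base) /
              base, 0.01)
})

test_that("profile_pose composes its parts and rejects empty ligands", {
  for (s in c(2, 8)) {
    tc <- make_toy_complex(toy_complex_spec(4, planted_hbond_residues = s %% 4 + 1,
                                            planted_contact_counts =
                                              stats::setNames(3L, as.character(s %% 3 + 1)),
                                            seed = s))
    prof <- profile_pose(tc$complex, tc$ligand, docking_score = -5.5,
                         molecule_id = "t")
    expect_equal(sort(prof$hbond_residues),
                 sort(unique(detect_hbonds(tc$receptor, tc$ligand)$label)))
    expect_equal(prof$vdw_contact_count,
                 count_attractive_vdw(tc$receptor, tc$ligand)$count)
    expect_equal(prof$bsa, buried_surface_area(tc$receptor, tc$ligand))
    expect_equal(prof$docking_score, -5.5)
  }
  expect_error(profile_pose(make_toy_complex(toy_complex_spec(2))$complex,
                            data.frame()), "empty")
})
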