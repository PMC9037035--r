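# Interaction criteria, Best/Worst labeling and three-property ranking.

fake_profile <- function(hb, vdw) list(hbond_residues = hb, vdw_residues = vdw)

test_that("criteria presets require exactly the declared interactions", {
  full <- criteria_preset("full_site")
  prof <- fake_profile("ARG87",
                       c("TYR44", "GLU45", "MET83", "LEU81", "TYR147"))
  expect_true(passes_criteria(prof, full))
  missing_glu <- fake_profile("ARG87", c("TYR44", "MET83", "LEU81", "TYR147"))
  expect_false(passes_criteria(missing_glu, full))
  subB <- fake_profile("ARG87", c("TYR44", "GLU45", "TRP62"))
  expect_true(passes_criteria(subB, criteria_preset("subsite_b")))
  expect_false(passes_criteria(subB, full))
  # TRP62 required only in sub-site B; LYS163 in none
  expect_false("TRP62" %in% full$required_vdw_residues)
  expect_false("LYS163" %in% c(full$required_vdw_residues,
                               criteria_preset("subsite_a")$required_vdw_residues,
                               criteria_preset("subsite_b")$required_vdw_residues))
})

test_that("passes_criteria is monotone in the interaction sets", {
  full <- criteria_preset("full_site")
  base <- fake_profile("ARG87",
                       c("TYR44", "GLU45", "MET83", "LEU81", "TYR147"))
  expect_true(passes_criteria(base, full))
  grown <- fake_profile(c(base$hbond_residues, "LEU82"),
                        c(base$vdw_residues, "LYS163", "TRP62"))
  expect_true(passes_criteria(grown, full))
})

test_that("Best/Worst labeling follows the threshold punctuation exactly", {
  th <- label_thresholds()
  rec <- function(s, v, b) data.frame(molecule_id = "x", docking_score = s,
                                      vdw_contacts = v, bsa = b)
  expect_equal(label_best_worst(rec(-4.0, 292, 843), th), "Best")
  expect_equal(label_best_worst(rec(-2.4, 293, 986), th), "neither")
  expect_equal(label_best_worst(rec(-0.5, 100, 500), th), "Worst")
  # boundary: -3 is not strictly below -3
  expect_equal(label_best_worst(rec(-3.0, 250, 750), th), "neither")
  # inclusive boundaries on the other criteria
  expect_equal(label_best_worst(rec(-3.1, 250, 750), th), "Best")
  expect_equal(label_best_worst(rec(-1.0, 150, 600), th), "Worst")
})

test_that("no record can be both Best and Worst", {
  set.seed(11)
  recs <- data.frame(molecule_id = sprintf("m%d", 1:500),
                     docking_score = runif(500, -9, 1),
                     vdw_contacts = sample(0:500, 500, TRUE),
                     bsa = runif(500, 0, 1200))
  lab <- label_best_worst(recs)
  counts <- filter_and_count(recs)
  expect_equal(unname(sum(counts)), 500L)
  expect_true(all(lab %in% c("Best", "Worst", "neither")))
  expect_error(label_thresholds(best_score_below = -1,
                                worst_score_at_least = -3,
                                best_bsa_at_least = 500,
                                worst_bsa_at_most = 600,
                                best_vdw_at_least = 100,
                                worst_vdw_at_most = 200),
               "disjoint")
})

test_that("ranking is deterministic, permutation-invariant, and favours the printed leader", {
  recs <- docked_candidates()
  ranked <- rank_molecules(recs)
  # lowest docking score (-7) and most contacts (453) both belong to
  # Z49734016: it holds the best rank on those two properties
  expect_equal(recs$molecule_id[which.min(recs$docking_score)], "Z49734016")
  expect_equal(recs$molecule_id[which.max(recs$vdw_contacts)], "Z49734016")
  expect_true("Z49734016" %in% ranked$molecule_id[1:2])

  for (s in 1:5) {
    set.seed(s)
    perm <- rank_molecules(recs[sample.int(nrow(recs)), ])
    expect_equal(perm$molecule_id, ranked$molecule_id)
    expect_equal(perm$rank_score, ranked$rank_score)
  }
  one <- rank_molecules(recs[3, , drop = FALSE])
  expect_equal(one$rank, 1L)
  expect_error(rank_molecules(recs[0, ]), "no records")
})

test_that("label tallies recover planted structure and handle empty input", {
  expect_equal(filter_and_count(docked_candidates()),
               c(Best = 4L, Worst = 0L, neither = 6L))
  expect_equal(filter_and_count(docked_candidates()[0, ]),
               c(Best = 0L, Worst = 0L, neither = 0L))
  pt <- make_pose_table(137, 68 / 137, 69 / 137, seed = 21)
  expect_equal(filter_and_count(pt$records),
               c(Best = 68L, Worst = 69L, neither = 0L))
  expect_equal(label_best_worst(pt$records), pt$truth)
})
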