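# ISE ensemble: binning, MCC, training, index scoring, cross-validation,
# enrichment and cutoff selection.

# Hand-built model with n_pass always-true filters and n_fail never-true
# filters on a single descriptor.
manual_model <- function(n_pass, n_fail) {
  mk <- function(lower, upper)
    list(clauses = data.frame(descriptor = "d1", bin_lo = 1L, bin_hi = 1L,
                              lower = lower, upper = upper,
                              stringsAsFactors = FALSE),
         train_mcc = 0.8)
  filters <- c(replicate(n_pass, mk(-Inf, Inf), simplify = FALSE),
               replicate(n_fail, mk(1e6, 1e6 + 1), simplify = FALSE))
  structure(list(filters = filters, manifest = descriptor_manifest("d1"),
                 bins = structure(list(edges = list(d1 = numeric(0)),
                                       n_bins = c(d1 = 1L)),
                                  class = "DescriptorBins"),
                 params = ise_params(), seed = 1L, n_train = 0L),
            class = "ISEModel")
}

test_that("equal-frequency binning places edges at the expected quantiles", {
  tab <- descriptor_table(sprintf("m%d", 1:100),
                          matrix(1:100, 100, 1, dimnames = list(NULL, "d1")))
  bins <- bin_descriptors(tab, 5)
  expect_equal(bins$edges$d1,
               unname(stats::quantile(1:100, c(.2, .4, .6, .8))))
  expect_equal(unname(bins$n_bins["d1"]), 5L)
  b <- assign_bins(tab$values, bins)
  expect_equal(as.integer(table(b[, 1])), rep(20L, 5))  # populations equal

  const <- descriptor_table(sprintf("m%d", 1:10),
                            matrix(1, 10, 1, dimnames = list(NULL, "c")))
  expect_warning(bc <- bin_descriptors(const, 5), "fewer distinct values")
  expect_equal(unname(bc$n_bins["c"]), 1L)
  expect_true(all(assign_bins(const$values, bc) == 1L))
})

test_that("bin populations differ by at most one on continuous data", {
  set.seed(3)
  for (n in c(68, 137, 200)) {
    tab <- descriptor_table(sprintf("m%d", 1:n),
                            matrix(rnorm(n), n, 1,
                                   dimnames = list(NULL, "d1")))
    b <- assign_bins(tab$values, bin_descriptors(tab, 10))
    pops <- table(b[, 1])
    expect_lte(max(pops) - min(pops), 1)
  }
})

test_that("MCC matches the closed form and its degenerate conventions", {
  expect_equal(mcc(68, 0, 69, 0), 1)
  expect_equal(mcc(5, 1, 9, 5), (45 - 5) / sqrt(8400), tolerance = 1e-9)
  expect_equal(mcc(5, 1, 9, 5), 0.4364, tolerance = 1e-4)
  expect_equal(mcc(3, 3, 3, 3), 0)
  expect_equal(mcc(0, 0, 5, 5), 0)   # degenerate margin
  expect_error(mcc(0, 0, 0, 0), "zero total")
  expect_error(mcc(-1, 0, 1, 0), "non-negative")
})

test_that("MCC is antisymmetric under label swap on random confusion matrices", {
  set.seed(1)
  for (i in 1:1000) {
    cm <- sample(0:40, 4, replace = TRUE)
    if (sum(cm) == 0) cm[1] <- 1
    expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]),
                 -mcc(cm[4], cm[3], cm[2], cm[1]), tolerance = 1e-12)
  }
})

test_that("index scoring follows the pass/fail arithmetic and bounds", {
  row <- c(d1 = 0)
  expect_equal(score_index(manual_model(10, 0), row)$index, 1)
  expect_equal(score_index(manual_model(0, 10), row)$index, -1)
  s <- score_index(manual_model(600, 319), row)
  expect_equal(s$n_pass + s$n_fail, 919)
  expect_equal(s$index, (600 - 319) / 919, tolerance = 1e-12)
  expect_equal(round(s$index, 4), 0.3058)
  expect_error(score_index(manual_model(1, 0), c(other = 1)), "d1")
})

test_that("training recovers planted signal and is byte-deterministic", {
  tab <- make_learning_set(learning_set_spec(68, 69, 50, 3, 2, seed = 101))
  p <- ise_params(n_candidates = 600, max_iterations = 15)
  m <- train_ise(tab, p, seed = 5)
  expect_gt(length(m$filters), 0)
  expect_gte(m$filters[[1]]$train_mcc, 0.7)
  informative <- attr(tab, "truth")$informative
  expect_true(any(m$filters[[1]]$clauses$descriptor %in% informative))
  # filters sorted by training MCC, all above the floor
  mccs <- vapply(m$filters, `[[`, numeric(1), "train_mcc")
  expect_true(all(diff(mccs) <= 0))
  expect_true(all(mccs >= 0.7))

  m2 <- train_ise(tab, p, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_ise_model(m, f1); write_ise_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("pure-noise learning sets fail to model", {
  tab <- make_learning_set(learning_set_spec(68, 69, 50, 0, 0, seed = 55))
  expect_warning(m <- train_ise(tab, ise_params(n_candidates = 400,
                                                max_iterations = 6),
                                seed = 3),
                 "failed to model")
  expect_lte(length(m$filters), 2)
  expect_error(train_ise(descriptor_table(tab$molecule_ids, tab$values,
                                          rep("Best", 137)),
                         seed = 1),
               "degenerate")
})

test_that("model serialization round-trips through JSON", {
  tab <- make_learning_set(learning_set_spec(20, 20, 10, 2, 3, seed = 8))
  m <- train_ise(tab, ise_params(n_candidates = 200, max_iterations = 4),
                 seed = 2)
  f <- tempfile(fileext = ".json")
  write_ise_model(m, f)
  m2 <- read_ise_model(f)
  expect_equal(length(m2$filters), length(m$filters))
  expect_equal(m2$filters[[1]]$clauses, m$filters[[1]]$clauses)
  expect_equal(m2$manifest$hash, m$manifest$hash)
  sc1 <- score_table(m, tab)
  sc2 <- score_table(m2, tab)
  expect_equal(sc1$index, sc2$index)
  unlink(f)
})

test_that("stratified folds have pigeonhole sizes and full test coverage", {
  tab <- make_learning_set(learning_set_spec(68, 69, 20, 2, 3, seed = 7))
  cv <- suppressWarnings(cross_validate(tab, 5,
    ise_params(n_candidates = 200, max_iterations = 4), seed = 4))
  pos <- tab$label == "Best"
  expect_equal(sort(as.integer(table(cv$fold_assignment[pos]))),
               c(13L, 13L, 14L, 14L, 14L))
  expect_equal(sort(as.integer(table(cv$fold_assignment[!pos]))),
               c(13L, 14L, 14L, 14L, 14L))
  expect_setequal(cv$test_scores$molecule_id, tab$molecule_ids)
  expect_equal(nrow(cv$test_scores), 137)
  expect_error(cross_validate(make_learning_set(
    learning_set_spec(4, 40, 10, 1, 2, seed = 1)), 5), "fewer molecules")
})

test_that("cross-validated recovery separates planted classes", {
  tab <- make_learning_set(learning_set_spec(68, 69, 50, 3, 2, seed = 105))
  cv <- suppressWarnings(cross_validate(tab, 5,
    ise_params(n_candidates = 600, max_iterations = 15), seed = 6))
  tm <- index_threshold_mcc(cv$test_scores, cv$test_scores$label)
  expect_gte(max(tm$mcc), 0.5)
  # final model is the deduplicated union of the fold filter sets
  sigs <- vapply(cv$final_model$filters, function(f)
    paste(f$clauses$descriptor, f$clauses$bin_lo, f$clauses$bin_hi,
          collapse = "|"), character(1))
  expect_false(anyDuplicated(sigs) > 0)
  n_fold <- sum(vapply(cv$fold_models, function(m) length(m$filters),
                       integer(1)))
  expect_lte(length(cv$final_model$filters), n_fold)
})

test_that("enrichment curve matches per-threshold counting and flags fp = 0", {
  idx <- c(rep(1, 40), rep(0, 28), rep(-1, 69))
  lab <- rep(c("Best", "Worst"), c(68, 69))
  curve <- enrichment_curve(idx, lab)
  expect_equal(curve$tp[curve$threshold == -1], 68)
  expect_equal(curve$fp[curve$threshold == -1], 69)
  expect_equal(curve$ratio[curve$threshold == -1], 68 / 69)
  expect_true(is.infinite(curve$ratio[curve$threshold == 0]))
  expect_true(all(diff(curve$tp) <= 0))
  expect_true(all(diff(curve$fp) <= 0))

  set.seed(12)
  ridx <- runif(60, -1, 1)
  rlab <- sample(c("Best", "Worst"), 60, TRUE, prob = c(.5, .5))
  rc <- enrichment_curve(ridx, rlab)
  for (k in seq_len(nrow(rc))) {
    t <- rc$threshold[k]
    expect_equal(rc$tp[k], sum(rlab == "Best" & ridx >= t))
    expect_equal(rc$fp[k], sum(rlab == "Worst" & ridx >= t))
  }
  expect_error(enrichment_curve(ridx, rep("Worst", 60)), "no positive")
})

test_that("cutoff selection picks the smallest qualifying threshold", {
  curve <- data.frame(threshold = c(-1, 0, 0.75),
                      tp = c(68, 40, 33), fp = c(69, 10, 2),
                      ratio = c(1, 4, 16.5))
  class(curve) <- c("EnrichmentCurve", "data.frame")
  expect_equal(select_cutoff(curve, 10), 0.75)
  expect_equal(select_cutoff(curve, 0), -1)
  expect_error(select_cutoff(curve, 20), "maximum achievable is 16.5")
})

test_that("indices stay in [-1, 1] and increase with filters passed", {
  n <- 37
  idx <- vapply(0:n, function(k)
    score_index(manual_model(k, n - k), c(d1 = 0))$index, numeric(1))
  expect_true(all(idx >= -1 & idx <= 1))
  expect_true(all(diff(idx) > 0))
  expect_equal(idx[1], -1)
  expect_equal(idx[n + 1], 1)
})
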