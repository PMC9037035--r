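# Iterative Stochastic Elimination (ISE) filter-ensemble classifier.
#
# A "filter" is a conjunction of descriptor-range clauses; a molecule passes
# a filter when every clause interval contains its value. Training samples
# random candidate filters over equal-frequency descriptor bins, scores each
# by its training Matthews correlation coefficient (MCC) against the
# Best/Worst labels, and iteratively eliminates from the sampling pool the
# (descriptor, bin) values over-represented among the bottom-scoring
# candidates. Surviving high-MCC candidates, greedily deduplicated by clause
# overlap, form the model. Screening reports a molecular index in [-1, 1]:
# (filters passed - filters failed) / filters total.

#' ISE training hyperparameters
#'
#' @param n_bins equal-frequency bins per descriptor. Default 10.
#' @param max_clauses maximum clauses per candidate filter. Default 4.
#' @param n_candidates candidate filters drawn per iteration. Default 2000.
#' @param max_iterations elimination iterations cap. Default 50.
#' @param worst_fraction fraction of candidates counted as bottom-scoring
#'   each iteration. Default 0.25.
#' @param over_representation a (descriptor, bin) value is eliminated when
#'   its usage among bottom-scoring candidates exceeds this multiple of the
#'   expected share. Default 2.
#' @param min_cell_usage minimum total usage before a cell may be judged.
#'   Default 5.
#' @param mcc_floor only filters with training MCC at or above this enter
#'   the model. Default 0.7.
#' @param max_overlap greedy deduplication drops a filter whose clause-cell
#'   Jaccard overlap with an already kept filter reaches this value.
#'   Default 0.75.
#' @param weight_by_mcc weight filters by training MCC when computing the
#'   index (off by default; the plain pass/fail index matches the stated
#'   [-1, 1] semantics).
#' @return object of class `"ISEParams"`.
#' @export
ise_params <- function(n_bins = 10, max_clauses = 4, n_candidates = 2000,
                       max_iterations = 50, worst_fraction = 0.25,
                       over_representation = 2, min_cell_usage = 5,
                       mcc_floor = 0.7, max_overlap = 0.75,
                       weight_by_mcc = FALSE) {
  stopifnot(n_bins >= 2, max_clauses >= 1, n_candidates >= 1,
            max_iterations >= 1, worst_fraction > 0, worst_fraction < 1,
            over_representation > 1, mcc_floor >= -1, mcc_floor <= 1,
            max_overlap > 0, max_overlap <= 1)
  structure(list(n_bins = as.integer(n_bins),
                 max_clauses = as.integer(max_clauses),
                 n_candidates = as.integer(n_candidates),
                 max_iterations = as.integer(max_iterations),
                 worst_fraction = worst_fraction,
                 over_representation = over_representation,
                 min_cell_usage = as.integer(min_cell_usage),
                 mcc_floor = mcc_floor,
                 max_overlap = max_overlap,
                 weight_by_mcc = isTRUE(weight_by_mcc)),
            class = "ISEParams")
}

#' Equal-frequency descriptor binning
#'
#' Computes per-descriptor bin edges at equal-frequency quantiles of the
#' (training) values. Descriptors with fewer distinct values than requested
#' bins get fewer bins, with a warning. Every value maps to exactly one bin
#' via [assign_bins()].
#'
#' @param table a [descriptor_table()] (pruned).
#' @param n_bins requested bins per descriptor (>= 2).
#' @return object of class `"DescriptorBins"`: list with `edges` (interior
#'   edges per descriptor) and `n_bins` (realized bin counts).
#' @export
bin_descriptors <- function(table, n_bins = 10) {
  stopifnot(inherits(table, "DescriptorTable"), n_bins >= 2)
  v <- table$values
  edges <- vector("list", ncol(v))
  names(edges) <- colnames(v)
  short <- character(0)
  for (j in seq_len(ncol(v))) {
    probs <- seq(0, 1, length.out = n_bins + 1)[-c(1, n_bins + 1)]
    e <- unique(as.numeric(stats::quantile(v[, j], probs, type = 7)))
    # drop edges equal to the extremes so no bin is empty of range
    e <- e[e > min(v[, j]) & e <= max(v[, j])]
    if (length(e) < n_bins - 1) short <- c(short, colnames(v)[j])
    edges[[j]] <- e
  }
  if (length(short) > 0)
    warning("descriptor(s) with fewer distinct values than bins: ",
            paste(utils::head(short, 5), collapse = ", "),
            if (length(short) > 5) " ...", call. = FALSE)
  structure(list(edges = edges,
                 n_bins = vapply(edges, length, integer(1)) + 1L),
            class = "DescriptorBins")
}

#' Map descriptor values to bin indices
#'
#' @param values numeric matrix (molecules x descriptors) whose columns
#'   match the binning.
#' @param bins a [bin_descriptors()] object.
#' @return integer matrix of bin indices (1-based).
#' @export
assign_bins <- function(values, bins) {
  stopifnot(inherits(bins, "DescriptorBins"))
  nm <- names(bins$edges)
  missing_d <- setdiff(nm, colnames(values))
  if (length(missing_d) > 0)
    stop("values lack binned descriptor(s): ",
         paste(utils::head(missing_d, 5), collapse = ", "), call. = FALSE)
  out <- matrix(0L, nrow(values), length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm))
    out[, j] <- findInterval(values[, nm[j]], bins$edges[[nm[j]]]) + 1L
  out
}

#' Matthews correlation coefficient
#'
#' Standard MCC from a 2x2 confusion matrix; defined as 0 whenever a
#' denominator factor vanishes (a degenerate margin carries no association).
#' Vectorized over its arguments.
#'
#' @param tp,fp,tn,fn non-negative counts (total > 0).
#' @return numeric in [-1, 1].
#' @export
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  tot <- tp + fp + tn + fn
  if (any(tot == 0)) stop("confusion matrix with zero total", call. = FALSE)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  out <- ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
  unname(out)
}

.label_to_positive <- function(label) {
  if (is.logical(label)) return(label)
  lab <- as.character(label)
  ok <- lab %in% c("Best", "Worst")
  if (!all(ok)) stop("labels must be 'Best'/'Worst' (or logical)",
                     call. = FALSE)
  lab == "Best"
}

.clause_cells <- function(cand) {
  unlist(lapply(seq_along(cand$desc), function(i)
    paste0(cand$desc[i], ":", cand$lo[i]:cand$hi[i])))
}

.candidate_signature <- function(cand) {
  o <- order(cand$desc, cand$lo, cand$hi)
  paste(cand$desc[o], cand$lo[o], cand$hi[o], sep = ":", collapse = "|")
}

.eval_candidate <- function(cand, B, pos) {
  pass <- rep(TRUE, nrow(B))
  for (i in seq_along(cand$desc)) {
    b <- B[, cand$desc[i]]
    pass <- pass & b >= cand$lo[i] & b <= cand$hi[i]
  }
  tp <- sum(pass & pos); fp <- sum(pass & !pos)
  fn <- sum(!pass & pos); tn <- sum(!pass & !pos)
  list(pass = pass, mcc = mcc(tp, fp, tn, fn))
}

.draw_candidate <- function(active, max_clauses) {
  eligible <- which(vapply(active, any, logical(1)))
  if (length(eligible) == 0L) return(NULL)
  nc <- sample.int(max_clauses, 1L)
  nc <- min(nc, length(eligible))
  ds <- if (length(eligible) == 1L) eligible
        else sample(eligible, nc)
  lo <- integer(nc); hi <- integer(nc)
  for (i in seq_len(nc)) {
    ab <- which(active[[ds[i]]])
    pick <- if (length(ab) == 1L) c(ab, ab) else sample(ab, 2L, replace = TRUE)
    lo[i] <- min(pick); hi[i] <- max(pick)
  }
  list(desc = ds, lo = lo, hi = hi)
}

#' Train an ISE filter-ensemble model
#'
#' See the module header for the algorithm. Deterministic given `seed`: the
#' fitted model serializes byte-identically across runs with the same table,
#' parameters and seed. When no candidate reaches `mcc_floor` the returned
#' model has zero filters and a warning reports the failure to model (the
#' expected outcome on pure-noise data).
#'
#' @param table a labeled [descriptor_table()] (labels `"Best"`/`"Worst"`,
#'   at least 5 molecules per class).
#' @param params an [ise_params()] object.
#' @param seed integer seed for all stochastic steps.
#' @return object of class `"ISEModel"`: `filters` (each with `clauses`
#'   data.frame of descriptor/lower/upper/bin range and `train_mcc`, sorted
#'   by decreasing MCC), `manifest`, `bins`, `params`, `seed`, `n_train`.
#' @export
train_ise <- function(table, params = ise_params(), seed = 1) {
  stopifnot(inherits(table, "DescriptorTable"), inherits(params, "ISEParams"))
  if (is.null(table$label))
    stop("training requires a labeled descriptor table", call. = FALSE)
  pos <- .label_to_positive(table$label)
  if (sum(pos) < 5 || sum(!pos) < 5)
    stop("degenerate learning set: need >= 5 molecules per class",
         call. = FALSE)
  set.seed(as.integer(seed))
  bins <- bin_descriptors(table, params$n_bins)
  B <- assign_bins(table$values, bins)
  active <- lapply(bins$n_bins, function(nb) rep(TRUE, nb))
  names(active) <- names(bins$edges)
  active <- unname(active)

  archive <- list()   # signature -> list(cand, mcc)
  for (iter in seq_len(params$max_iterations)) {
    cands <- vector("list", params$n_candidates)
    mccs <- numeric(params$n_candidates)
    for (k in seq_len(params$n_candidates)) {
      cand <- .draw_candidate(active, params$max_clauses)
      if (is.null(cand)) break
      ev <- .eval_candidate(cand, B, pos)
      cands[[k]] <- cand
      mccs[k] <- ev$mcc
    }
    drawn <- !vapply(cands, is.null, logical(1))
    cands <- cands[drawn]; mccs <- mccs[drawn]
    if (length(cands) == 0L) break
    good <- which(mccs >= params$mcc_floor)
    for (k in good) {
      sig <- .candidate_signature(cands[[k]])
      if (is.null(archive[[sig]]))
        archive[[sig]] <- list(cand = cands[[k]], mcc = mccs[k])
    }
    # eliminate (descriptor, bin) cells over-represented among the worst
    n_bot <- max(1L, floor(params$worst_fraction * length(cands)))
    bot <- order(mccs)[seq_len(n_bot)]
    cell_tot <- new.env(parent = emptyenv())
    cell_bot <- new.env(parent = emptyenv())
    for (k in seq_along(cands)) {
      cells <- .clause_cells(cands[[k]])
      for (cl in cells) {
        cell_tot[[cl]] <- (if (is.null(cell_tot[[cl]])) 0 else cell_tot[[cl]]) + 1
        if (k %in% bot)
          cell_bot[[cl]] <- (if (is.null(cell_bot[[cl]])) 0 else cell_bot[[cl]]) + 1
      }
    }
    removed <- 0L
    frac_bot <- n_bot / length(cands)
    for (cl in ls(cell_bot)) {
      tot <- cell_tot[[cl]]
      if (tot < params$min_cell_usage) next
      if (cell_bot[[cl]] >= params$over_representation * frac_bot * tot) {
        parts <- as.integer(strsplit(cl, ":", fixed = TRUE)[[1]])
        if (active[[parts[1]]][parts[2]]) {
          active[[parts[1]]][parts[2]] <- FALSE
          removed <- removed + 1L
        }
      }
    }
    if (removed == 0L) break  # pool stable
    if (!any(vapply(active, any, logical(1)))) break
  }

  # greedy deduplication by clause-cell overlap, best MCC first
  sigs <- names(archive)
  if (length(sigs) > 0) {
    ord <- order(-vapply(archive, `[[`, numeric(1), "mcc"), sigs)
    kept <- list(); kept_cells <- list()
    for (i in ord) {
      cells <- .clause_cells(archive[[i]]$cand)
      dup <- FALSE
      for (kc in kept_cells) {
        jac <- length(intersect(cells, kc)) / length(union(cells, kc))
        if (jac >= params$max_overlap) { dup <- TRUE; break }
      }
      if (!dup) {
        kept[[length(kept) + 1L]] <- archive[[i]]
        kept_cells[[length(kept_cells) + 1L]] <- cells
      }
    }
  } else kept <- list()

  desc_names <- names(bins$edges)
  filters <- lapply(kept, function(k) {
    cand <- k$cand
    cl <- data.frame(
      descriptor = desc_names[cand$desc],
      bin_lo = cand$lo, bin_hi = cand$hi,
      lower = vapply(seq_along(cand$desc), function(i) {
        e <- bins$edges[[cand$desc[i]]]
        if (cand$lo[i] == 1L) -Inf else e[cand$lo[i] - 1L]
      }, numeric(1)),
      upper = vapply(seq_along(cand$desc), function(i) {
        e <- bins$edges[[cand$desc[i]]]
        if (cand$hi[i] > length(e)) Inf else e[cand$hi[i]]
      }, numeric(1)),
      stringsAsFactors = FALSE)
    list(clauses = cl, train_mcc = k$mcc)
  })
  if (length(filters) > 1) {
    ord <- order(-vapply(filters, `[[`, numeric(1), "train_mcc"),
                 vapply(filters, function(f)
                   paste(f$clauses$descriptor, collapse = "|"), character(1)))
    filters <- filters[ord]
  }
  if (length(filters) == 0L)
    warning("ISE failed to model: no candidate filter reached the MCC floor (",
            params$mcc_floor, ")", call. = FALSE)
  structure(list(filters = filters,
                 manifest = descriptor_manifest(table),
                 bins = bins,
                 params = params,
                 seed = as.integer(seed),
                 n_train = nrow(table$values)),
            class = "ISEModel")
}

#' @export
print.ISEModel <- function(x, ...) {
  cat("ISEModel:", length(x$filters), "filter(s)")
  if (length(x$filters) > 0)
    cat(" | train MCC", round(x$filters[[1]]$train_mcc, 3), "(top) to",
        round(x$filters[[length(x$filters)]]$train_mcc, 3), "(bottom)")
  cat(" | seed", x$seed, "\n")
  invisible(x)
}

.filter_passes <- function(filter, values_row) {
  cl <- filter$clauses
  v <- values_row[cl$descriptor]
  # half-open bin intervals [lower, upper); +/-Inf at the extremes
  all(v >= cl$lower & (v < cl$upper | cl$upper == Inf))
}

#' Index a molecule against an ISE model
#'
#' A molecule passes a filter when every clause interval contains its
#' descriptor value. The molecular index is
#' `(n_pass - n_fail) / (n_pass + n_fail)`, in [-1, 1].
#'
#' @param model an [train_ise()] model with at least one filter.
#' @param molecule_row named numeric vector of descriptor values covering
#'   the model manifest.
#' @return list (`IndexScore`): `index`, `n_pass`, `n_fail`.
#' @export
score_index <- function(model, molecule_row) {
  stopifnot(inherits(model, "ISEModel"))
  if (length(model$filters) == 0L)
    stop("model has no filters; nothing to score", call. = FALSE)
  missing_d <- setdiff(model$manifest$names, names(molecule_row))
  if (length(missing_d) > 0)
    stop("molecule row lacks descriptor(s): ",
         paste(utils::head(missing_d, 5), collapse = ", "), call. = FALSE)
  pass <- vapply(model$filters, .filter_passes, logical(1), molecule_row)
  n_pass <- sum(pass); n_fail <- sum(!pass)
  if (model$params$weight_by_mcc) {
    w <- vapply(model$filters, `[[`, numeric(1), "train_mcc")
    index <- sum(w * ifelse(pass, 1, -1)) / sum(w)
  } else {
    index <- (n_pass - n_fail) / (n_pass + n_fail)
  }
  structure(list(index = index, n_pass = n_pass, n_fail = n_fail),
            class = "IndexScore")
}

#' Index every molecule of a descriptor table
#'
#' @param model an `ISEModel`.
#' @param table a [descriptor_table()] covering the model manifest.
#' @return data.frame: `molecule_id`, `index`, `n_pass`, `n_fail`.
#' @export
score_table <- function(model, table) {
  stopifnot(inherits(table, "DescriptorTable"))
  rows <- lapply(seq_len(nrow(table$values)), function(i) {
    s <- score_index(model, table$values[i, ])
    data.frame(molecule_id = table$molecule_ids[i], index = s$index,
               n_pass = s$n_pass, n_fail = s$n_fail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified k-fold cross-validation with a merged final model
#'
#' Splits each class into k near-equal folds (sizes differing by at most
#' one), trains on each set of k-1 folds and scores the held-out fold, so
#' every molecule is scored exactly once as a test molecule. The final model
#' is the union of the k filter sets, deduplicated by clause signature.
#'
#' @param table labeled [descriptor_table()].
#' @param k number of folds (>= 2; each class must have >= k molecules).
#' @param params an [ise_params()] object.
#' @param seed integer seed (drives fold assignment and all training).
#' @return list: `fold_models`, `test_scores` (pooled data.frame with
#'   `molecule_id`, `fold`, `label`, `index`, `n_pass`, `n_fail`),
#'   `final_model`, `fold_assignment`.
#' @export
cross_validate <- function(table, k = 5, params = ise_params(), seed = 1) {
  stopifnot(inherits(table, "DescriptorTable"), k >= 2)
  if (is.null(table$label)) stop("labels required", call. = FALSE)
  pos <- .label_to_positive(table$label)
  if (min(sum(pos), sum(!pos)) < k)
    stop("a class has fewer molecules than folds", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- integer(length(pos))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold_models <- vector("list", k)
  score_rows <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    sub <- descriptor_table(table$molecule_ids[tr],
                            table$values[tr, , drop = FALSE],
                            table$label[tr])
    m <- train_ise(sub, params,
                   seed = (as.integer(seed) + 7919L * f) %% 2147483647L)
    fold_models[[f]] <- m
    te <- which(!tr)
    if (length(m$filters) == 0L) {
      sc <- data.frame(molecule_id = table$molecule_ids[te],
                       index = NA_real_, n_pass = NA_integer_,
                       n_fail = NA_integer_, stringsAsFactors = FALSE)
    } else {
      sc <- score_table(m, descriptor_table(table$molecule_ids[te],
                                            table$values[te, , drop = FALSE],
                                            table$label[te]))
    }
    sc$fold <- f
    sc$label <- table$label[te]
    score_rows[[f]] <- sc
  }
  test_scores <- do.call(rbind, score_rows)
  rownames(test_scores) <- NULL

  all_filters <- unlist(lapply(fold_models, `[[`, "filters"),
                        recursive = FALSE)
  sigs <- vapply(all_filters, function(fl)
    paste(fl$clauses$descriptor, fl$clauses$bin_lo, fl$clauses$bin_hi,
          sep = ":", collapse = "|"), character(1))
  keep <- !duplicated(sigs)
  merged <- all_filters[keep]
  if (length(merged) > 1) {
    ord <- order(-vapply(merged, `[[`, numeric(1), "train_mcc"), sigs[keep])
    merged <- merged[ord]
  }
  final_model <- structure(list(filters = merged,
                                manifest = descriptor_manifest(table),
                                bins = fold_models[[1]]$bins,
                                params = params,
                                seed = as.integer(seed),
                                n_train = nrow(table$values)),
                           class = "ISEModel")
  list(fold_models = fold_models, test_scores = test_scores,
       final_model = final_model, fold_assignment = fold)
}

#' Enrichment curve of true over false positives by index threshold
#'
#' At each threshold t, `tp` is the number of positives ("Best") with index
#' at or above t, `fp` the number of negatives, and `ratio = tp/fp` (an
#' explicit `Inf` sentinel when `fp` is 0 — never silently dropped).
#' Thresholds are the sorted distinct indices, always including -1.
#'
#' @param scores numeric indices, or a `score_table()` data.frame.
#' @param labels `"Best"`/`"Worst"` labels (or logical), one per score.
#' @return data.frame of class `"EnrichmentCurve"`: `threshold`, `tp`,
#'   `fp`, `ratio`.
#' @export
enrichment_curve <- function(scores, labels) {
  if (is.data.frame(scores)) scores <- scores$index
  pos <- .label_to_positive(labels)
  stopifnot(length(scores) == length(pos))
  ok <- !is.na(scores)
  if (!any(ok)) stop("all indices are NA (no fold produced filters)",
                     call. = FALSE)
  scores <- scores[ok]; pos <- pos[ok]
  if (sum(pos) == 0) stop("no positive molecules in the labels",
                          call. = FALSE)
  thresholds <- sort(unique(c(-1, scores)))
  tp <- vapply(thresholds, function(t) sum(pos & scores >= t), numeric(1))
  fp <- vapply(thresholds, function(t) sum(!pos & scores >= t), numeric(1))
  out <- data.frame(threshold = thresholds, tp = tp, fp = fp,
                    ratio = ifelse(fp == 0, Inf, tp / fp))
  class(out) <- c("EnrichmentCurve", "data.frame")
  out
}

#' Select the candidate-selection cutoff from an enrichment curve
#'
#' The smallest index threshold whose TP/FP ratio reaches `min_ratio`
#' (choosing the lowest qualifying threshold keeps the candidate pool as
#' large as possible at that enrichment). Errors, reporting the maximum
#' achievable ratio, when no threshold qualifies.
#'
#' @param curve an [enrichment_curve()].
#' @param min_ratio required TP/FP ratio.
#' @return the selected index threshold (scalar).
#' @export
select_cutoff <- function(curve, min_ratio) {
  stopifnot(inherits(curve, "EnrichmentCurve"), nrow(curve) > 0)
  ok <- which(curve$ratio >= min_ratio)
  if (length(ok) == 0)
    stop("no threshold reaches TP/FP ", min_ratio,
         "; maximum achievable is ", max(curve$ratio), call. = FALSE)
  curve$threshold[min(ok)]
}

#' MCC along the index-threshold axis
#'
#' Treats "index >= t" as the positive prediction and reports the MCC at
#' every distinct threshold; useful for picking the operating point of a
#' cross-validated model.
#'
#' @inheritParams enrichment_curve
#' @return data.frame: `threshold`, `mcc`.
#' @export
index_threshold_mcc <- function(scores, labels) {
  if (is.data.frame(scores)) scores <- scores$index
  pos <- .label_to_positive(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; pos <- pos[ok]
  thresholds <- sort(unique(scores))
  m <- vapply(thresholds, function(t) {
    pred <- scores >= t
    mcc(sum(pred & pos), sum(pred & !pos), sum(!pred & !pos),
        sum(!pred & pos))
  }, numeric(1))
  data.frame(threshold = thresholds, mcc = m)
}

#' Serialize an ISE model to versioned JSON
#'
#' @param model an `ISEModel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ise_model <- function(model, path) {
  stopifnot(inherits(model, "ISEModel"))
  payload <- list(
    format = "dockscreen-ise-model",
    format_version = "1.0",
    manifest = model$manifest,
    seed = model$seed,
    n_train = model$n_train,
    params = unclass(model$params),
    bins = list(edges = model$bins$edges,
                n_bins = as.list(model$bins$n_bins)),
    filters = lapply(model$filters, function(f)
      list(train_mcc = f$train_mcc, clauses = f$clauses)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an ISE model from JSON
#'
#' @param path file written by [write_ise_model()].
#' @return an `ISEModel`.
#' @export
read_ise_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "dockscreen-ise-model"))
    stop("not an ISE model file: ", path, call. = FALSE)
  edges <- lapply(p$bins$edges, function(e) as.numeric(unlist(e)))
  filters <- lapply(p$filters, function(f) {
    cl <- f$clauses
    desc <- vapply(cl, function(r) r$descriptor, character(1))
    lo <- vapply(cl, function(r) as.integer(r$bin_lo), integer(1))
    hi <- vapply(cl, function(r) as.integer(r$bin_hi), integer(1))
    # interval bounds are reconstructed from the stored bin edges (JSON has
    # no native representation for the +/-Inf extremes)
    clauses <- data.frame(
      descriptor = desc, bin_lo = lo, bin_hi = hi,
      lower = vapply(seq_along(desc), function(i) {
        e <- edges[[desc[i]]]
        if (lo[i] == 1L) -Inf else e[lo[i] - 1L]
      }, numeric(1)),
      upper = vapply(seq_along(desc), function(i) {
        e <- edges[[desc[i]]]
        if (hi[i] > length(e)) Inf else e[hi[i]]
      }, numeric(1)),
      stringsAsFactors = FALSE)
    list(clauses = clauses, train_mcc = as.numeric(f$train_mcc))
  })
  bins <- structure(list(edges = edges,
                         n_bins = vapply(edges, length, integer(1)) + 1L),
                    class = "DescriptorBins")
  params <- do.call(ise_params, p$params)
  manifest <- list(version = p$manifest$version,
                   names = vapply(p$manifest$names, identity, character(1)),
                   hash = p$manifest$hash)
  structure(list(filters = filters,
                 manifest = manifest,
                 bins = bins,
                 params = params,
                 seed = as.integer(p$seed),
                 n_train = as.integer(p$n_train)),
            class = "ISEModel")
}
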