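# Interaction criteria, Best/Worst labeling and three-property ranking for
# docked-pose records.

#' Named set of required interactions
#'
#' A pose passes a criteria set when it hydrogen-bonds every residue in
#' `required_hbond_residues` and makes at least one attractive van der Waals
#' contact with every residue in `required_vdw_residues`. Residues are given
#' as "ARG87"-style labels.
#'
#' @param name criteria-set name.
#' @param required_hbond_residues residue labels requiring a hydrogen bond.
#' @param required_vdw_residues residue labels requiring a VDW contact.
#' @return object of class `"CriteriaSet"`.
#' @export
criteria_set <- function(name, required_hbond_residues = character(),
                         required_vdw_residues = character()) {
  required_hbond_residues <- toupper(required_hbond_residues)
  required_vdw_residues <- toupper(required_vdw_residues)
  if (length(required_hbond_residues) + length(required_vdw_residues) == 0L)
    stop("a criteria set must require at least one interaction",
         call. = FALSE)
  structure(list(name = name,
                 required_hbond_residues = required_hbond_residues,
                 required_vdw_residues = required_vdw_residues),
            class = "CriteriaSet")
}

#' Shipped interaction-criteria presets
#'
#' `"full_site"` requires ligands to span the whole hot-spot site of the
#' egg-surface receptor JUNO: a hydrogen bond to ARG87 plus attractive VDW
#' contacts with TYR44, GLU45, MET83, LEU81 and TYR147 (LYS163 is too
#' distant from the rest of the site to require, and requiring TRP62 rejects
#' most poses). `"subsite_a"` and `"subsite_b"` split the site in two, each
#' keeping the ARG87 hydrogen bond; TRP62 is reachable within sub-site B and
#' is required there.
#'
#' @param name one of `"full_site"`, `"subsite_a"`, `"subsite_b"`.
#' @return a [criteria_set()].
#' @export
criteria_preset <- function(name = c("full_site", "subsite_a", "subsite_b")) {
  name <- match.arg(name)
  switch(name,
    full_site = criteria_set("full_site", "ARG87",
                             c("TYR44", "GLU45", "MET83", "LEU81", "TYR147")),
    subsite_a = criteria_set("subsite_a", "ARG87",
                             c("MET83", "LEU81", "TYR147")),
    subsite_b = criteria_set("subsite_b", "ARG87",
                             c("TYR44", "GLU45", "TRP62")))
}

#' Does a pose profile meet a criteria set?
#'
#' True iff every required hydrogen-bond residue appears among the profile's
#' hydrogen-bonded residues and every required VDW residue among its
#' contacted residues. Monotone: adding interactions never turns a pass
#' into a fail.
#'
#' @param profile a `PoseProfile`, or any list with `hbond_residues` and
#'   `vdw_residues` character fields.
#' @param criteria a [criteria_set()].
#' @return logical scalar.
#' @export
passes_criteria <- function(profile, criteria) {
  stopifnot(inherits(criteria, "CriteriaSet"))
  all(criteria$required_hbond_residues %in% toupper(profile$hbond_residues)) &&
    all(criteria$required_vdw_residues %in% toupper(profile$vdw_residues))
}

#' Best/Worst labeling thresholds
#'
#' The two regions of (docking score, BSA, VDW contacts) space defining the
#' learning classes. Defaults are the screening conditions used throughout
#' this package: Best requires docking score strictly below -3 kcal/mol, BSA of
#' at least 750 A^2 and at least 250 attractive VDW contacts; Worst requires
#' score of at least -1, BSA at most 600 and at most 150 contacts. Strict
#' vs. inclusive comparisons follow that punctuation exactly, and the
#' regions are disjoint by construction.
#'
#' @param best_score_below,best_bsa_at_least,best_vdw_at_least Best-region
#'   bounds.
#' @param worst_score_at_least,worst_bsa_at_most,worst_vdw_at_most
#'   Worst-region bounds.
#' @return object of class `"LabelThresholds"`.
#' @export
label_thresholds <- function(best_score_below = -3,
                             best_bsa_at_least = 750,
                             best_vdw_at_least = 250,
                             worst_score_at_least = -1,
                             worst_bsa_at_most = 600,
                             worst_vdw_at_most = 150) {
  if (!(best_score_below <= worst_score_at_least ||
        worst_bsa_at_most < best_bsa_at_least ||
        worst_vdw_at_most < best_vdw_at_least))
    stop("Best and Worst regions must be disjoint", call. = FALSE)
  structure(list(best = list(score_below = best_score_below,
                             bsa_at_least = best_bsa_at_least,
                             vdw_at_least = best_vdw_at_least),
                 worst = list(score_at_least = worst_score_at_least,
                              bsa_at_most = worst_bsa_at_most,
                              vdw_at_most = worst_vdw_at_most)),
            class = "LabelThresholds")
}

.check_records <- function(records) {
  required <- c("molecule_id", "docking_score", "vdw_contacts", "bsa")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("pose records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records
}

#' Label pose records as Best, Worst or neither
#'
#' A record is Best when all three Best conditions hold, Worst when all
#' three Worst conditions hold, otherwise neither. The two regions are
#' disjoint, so no record can receive both labels.
#'
#' @param records data.frame with columns `molecule_id`, `docking_score`,
#'   `vdw_contacts`, `bsa` (one or more rows).
#' @param thresholds a [label_thresholds()] object.
#' @return character vector (`"Best"`, `"Worst"`, `"neither"`), one per row.
#' @export
label_best_worst <- function(records, thresholds = label_thresholds()) {
  stopifnot(inherits(thresholds, "LabelThresholds"))
  records <- .check_records(records)
  b <- thresholds$best; w <- thresholds$worst
  is_best <- records$docking_score < b$score_below &
    records$bsa >= b$bsa_at_least & records$vdw_contacts >= b$vdw_at_least
  is_worst <- records$docking_score >= w$score_at_least &
    records$bsa <= w$bsa_at_most & records$vdw_contacts <= w$vdw_at_most
  ifelse(is_best, "Best", ifelse(is_worst, "Worst", "neither"))
}

#' Tally Best/Worst labels over a record table
#'
#' @inheritParams label_best_worst
#' @return named integer vector `c(Best=, Worst=, neither=)`.
#' @export
filter_and_count <- function(records, thresholds = label_thresholds()) {
  if (is.null(records) || nrow(records) == 0L)
    return(c(Best = 0L, Worst = 0L, neither = 0L))
  lab <- label_best_worst(records, thresholds)
  c(Best = sum(lab == "Best"), Worst = sum(lab == "Worst"),
    neither = sum(lab == "neither"))
}

#' Rank pose records by three properties
#'
#' Each record receives `rank_score = rank(docking score, ascending) +
#' rank(VDW contacts, descending) + rank(BSA, descending)` (ties share the
#' minimum rank); output is sorted by `rank_score`, ties broken by docking
#' score then molecule id. A reproducible surrogate for expert inspection
#' across the three properties: deterministic and invariant to input order.
#'
#' @inheritParams label_best_worst
#' @return the records, sorted, with added `rank_score` and `rank` columns.
#' @export
rank_molecules <- function(records) {
  records <- .check_records(records)
  if (nrow(records) == 0L) stop("no records to rank", call. = FALSE)
  rs <- rank(records$docking_score, ties.method = "min") +
    rank(-records$vdw_contacts, ties.method = "min") +
    rank(-records$bsa, ties.method = "min")
  out <- records
  out$rank_score <- rs
  out <- out[order(out$rank_score, out$docking_score, out$molecule_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' The ten docked JUNO-site candidates sent for in vitro testing
#'
#' Built-in pose-record table for the ten top-ranked docked molecules
#' (docking score in kcal/mol, attractive VDW contact count, buried surface
#' area in A^2) that accompany this pipeline as a worked example. The
#' docking scores are ingested external values.
#'
#' @return data.frame with columns `molecule_id`, `docking_score`,
#'   `vdw_contacts`, `bsa`.
#' @export
docked_candidates <- function() {
  data.frame(
    molecule_id = c("Z49720304", "Z18823321", "Z1290281203", "Z1033235866",
                    "Z131775002", "Z56788505", "Z786028994", "Z1172207733",
                    "Z49734016", "Z66693270"),
    docking_score = c(-4, -3.8, -3.4, -3.4, -4.4, -5.4, -4.3, -2.4, -7, -3.3),
    vdw_contacts = c(292L, 233L, 272L, 220L, 211L, 316L, 241L, 293L, 453L,
                     210L),
    bsa = c(843, 883, 848, 751, 748, 1039, 832, 986, 779, 818),
    stringsAsFactors = FALSE)
}
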