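# Multi-stage pipeline driver: one YAML/list config, stage toggles, CSV
# outputs with provenance headers, and a JSON run manifest. Stage outputs
# are pure functions of (inputs, parameters, seed): re-running an identical
# config reproduces identical files.

# Fixed stage order; each stage has a fixed index so that enabling or
# disabling unrelated stages does not perturb another stage's randomness.
.pipeline_stages <- c("simulate", "hotspots", "profile", "label", "rank",
                      "train", "screen")

#' Per-stage seed fan-out
#'
#' Derives a stage's seed as the global seed plus a fixed large prime times
#' the stage's fixed index (reduced mod 2^31 - 1), so enabling or disabling
#' unrelated stages never perturbs another stage's randomness.
#'
#' @param global_seed the pipeline's global seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  idx <- match(stage, .pipeline_stages)
  if (is.na(idx)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(global_seed) + 104729 * idx) %% 2147483647)
}

.write_stage_csv <- function(df, path, stage, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dockscreen ", as.character(utils::packageVersion("dockscreen"))),
    paste0("# stage: ", stage),
    paste0("# seed: ", seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Read a pipeline stage CSV
#'
#' Reads CSV files written by [run_pipeline()] (provenance comment lines
#' starting with `#` are skipped).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$output_dir))
    stop("config validation error: output_dir is required", call. = FALSE)
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config validation error: no stages configured", call. = FALSE)
  unknown <- setdiff(names(config$stages), .pipeline_stages)
  if (length(unknown) > 0L)
    stop("config validation error: unknown stage(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  enabled <- names(config$stages)[vapply(config$stages, function(s)
    isTRUE(s$enabled), logical(1))]
  stochastic <- intersect(enabled, c("simulate", "train"))
  if (length(stochastic) > 0L && is.null(config$seed))
    stop("config validation error: seed required when stochastic stage(s) ",
         paste(stochastic, collapse = ", "), " are enabled", call. = FALSE)
  # every referenced input path must exist before any stage runs
  for (st in enabled) {
    s <- config$stages[[st]]
    for (key in intersect(names(s), c("pdb", "records", "table", "poses"))) {
      if (is.character(s[[key]]) && !file.exists(s[[key]]))
        stop("config validation error: stage '", st, "' input path not ",
             "found: ", s[[key]], call. = FALSE)
    }
  }
  config$enabled_stages <- intersect(.pipeline_stages, enabled)
  config
}

#' Run the screening pipeline from one config
#'
#' Executes the enabled stages in dependency order — simulate a learning
#' set, hot-spot scan a complex, label and rank pose records, train the ISE
#' classifier by stratified cross-validation, screen and select an
#' enrichment cutoff — writing per-stage CSV/JSON outputs and a manifest
#' (parameters, seed, input and output hashes, package version) into
#' `output_dir`. The config is a YAML file path or an equivalent list:
#'
#' ```
#' seed: 17
#' output_dir: out/
#' stages:
#'   simulate: {enabled: yes, n_best: 68, n_worst: 69, n_descriptors: 50,
#'              n_informative: 3, effect_size: 2}
#'   train:    {enabled: yes, folds: 5, n_candidates: 400, max_iterations: 8}
#'   screen:   {enabled: yes, min_ratio: 3}
#' ```
#'
#' A stage failure aborts the run naming the stage; outputs of completed
#' stages are retained and listed as partial in the manifest.
#'
#' @param config YAML path or list.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- .validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(
    tool = "dockscreen",
    version = as.character(utils::packageVersion("dockscreen")),
    seed = seed,
    stages = list(),
    inputs = list(),
    outputs = list(),
    status = "running")
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(config$stages[[stage]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- paste0("failed at stage '", stage, "': ",
                                 conditionMessage(res))
      manifest_path <- file.path(out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[stage]] <<- res
  }

  note_input <- function(path) {
    manifest$inputs[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  note_output <- function(path) {
    manifest$outputs[[basename(path)]] <<- unname(tools::md5sum(path))
  }

  for (stage in config$enabled_stages) {
    message("[dockscreen] stage: ", stage)
    switch(stage,
      simulate = run_stage("simulate", function(s) {
        spec <- learning_set_spec(
          n_best = s$n_best %||% 68, n_worst = s$n_worst %||% 69,
          n_descriptors = s$n_descriptors %||% 206,
          n_informative = s$n_informative %||% 3,
          effect_size = s$effect_size %||% 2,
          seed = stage_seed(seed, "simulate"))
        tab <- make_learning_set(spec)
        state$table <- tab
        df <- data.frame(molecule_id = tab$molecule_ids, label = tab$label,
                         tab$values, stringsAsFactors = FALSE)
        p <- .write_stage_csv(df, file.path(out_dir, "learning_set.csv"),
                              "simulate", spec$seed)
        note_output(p)
        tp <- file.path(out_dir, "learning_set_truth.json")
        jsonlite::write_json(attr(tab, "truth"), tp, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        note_output(tp)
        list(seed = spec$seed, n_molecules = nrow(tab$values),
             n_descriptors = ncol(tab$values))
      }),
      hotspots = run_stage("hotspots", function(s) {
        note_input(s$pdb)
        cx <- parse_complex(s$pdb, s$receptor_chains, s$partner_chains)
        params <- energy_params(
          hot_spot_threshold = s$threshold %||% 4)
        scan <- scan_interface(cx, params,
                               interface_cutoff = s$interface_cutoff %||% 4.5)
        state$scan <- scan
        p <- .write_stage_csv(scan, file.path(out_dir, "hotspots.csv"),
                              "hotspots", NA)
        note_output(p)
        list(n_interface = nrow(scan), n_hot_spots = sum(scan$is_hot_spot))
      }),
      profile = run_stage("profile", function(s) {
        note_input(s$pdb)
        cx <- parse_complex(s$pdb, s$receptor_chains, s$partner_chains)
        prof <- profile_pose(cx, complex_side(cx, "partner"),
                             molecule_id = s$molecule_id %||% "partner",
                             docking_score = s$docking_score %||% NA_real_)
        state$profile <- prof
        df <- data.frame(
          molecule_id = prof$molecule_id,
          docking_score = prof$docking_score,
          hbond_residues = paste(prof$hbond_residues, collapse = ";"),
          vdw_contacts = prof$vdw_contact_count,
          bsa = prof$bsa, stringsAsFactors = FALSE)
        p <- .write_stage_csv(df, file.path(out_dir, "profile.csv"),
                              "profile", NA)
        note_output(p)
        list(vdw_contacts = prof$vdw_contact_count, bsa = prof$bsa,
             n_hbond_residues = length(prof$hbond_residues))
      }),
      label = run_stage("label", function(s) {
        recs <- if (!is.null(s$records)) {
          note_input(s$records)
          read_stage_csv(s$records)
        } else docked_candidates()
        th <- label_thresholds()
        recs$label <- label_best_worst(recs, th)
        state$records <- recs
        p <- .write_stage_csv(recs, file.path(out_dir, "labels.csv"),
                              "label", NA)
        note_output(p)
        as.list(filter_and_count(recs, th))
      }),
      rank = run_stage("rank", function(s) {
        recs <- state$records
        if (is.null(recs)) {
          if (!is.null(s$records)) { note_input(s$records)
            recs <- read_stage_csv(s$records) }
          else recs <- docked_candidates()
        }
        ranked <- rank_molecules(recs)
        p <- .write_stage_csv(ranked, file.path(out_dir, "ranking.csv"),
                              "rank", NA)
        note_output(p)
        list(n_ranked = nrow(ranked), top = ranked$molecule_id[1])
      }),
      train = run_stage("train", function(s) {
        tab <- state$table
        if (is.null(tab)) {
          if (is.null(s$table))
            stop("no learning table: enable simulate or give a table path")
          note_input(s$table)
          df <- read_stage_csv(s$table)
          tab <- descriptor_table(df$molecule_id,
                                  as.matrix(df[, !(names(df) %in%
                                    c("molecule_id", "label"))]),
                                  df$label)
        }
        params <- ise_params(
          n_candidates = s$n_candidates %||% 2000,
          max_iterations = s$max_iterations %||% 50,
          n_bins = s$n_bins %||% 10,
          max_clauses = s$max_clauses %||% 4,
          mcc_floor = s$mcc_floor %||% 0.7)
        cv <- cross_validate(tab, k = s$folds %||% 5, params = params,
                             seed = stage_seed(seed, "train"))
        state$cv <- cv
        p <- .write_stage_csv(cv$test_scores,
                              file.path(out_dir, "test_scores.csv"),
                              "train", stage_seed(seed, "train"))
        note_output(p)
        mp <- file.path(out_dir, "model.json")
        write_ise_model(cv$final_model, mp)
        note_output(mp)
        list(seed = stage_seed(seed, "train"),
             n_filters = length(cv$final_model$filters),
             folds = s$folds %||% 5)
      }),
      screen = run_stage("screen", function(s) {
        cv <- state$cv
        if (is.null(cv)) stop("screen requires the train stage")
        curve <- enrichment_curve(cv$test_scores$index,
                                  cv$test_scores$label)
        p <- .write_stage_csv(as.data.frame(curve),
                              file.path(out_dir, "enrichment.csv"),
                              "screen", NA)
        note_output(p)
        cutoff <- if (!is.null(s$cutoff)) s$cutoff
                  else select_cutoff(curve, s$min_ratio %||% 3)
        sel <- cv$test_scores[!is.na(cv$test_scores$index) &
                                cv$test_scores$index >= cutoff, ,
                              drop = FALSE]
        sp <- .write_stage_csv(sel, file.path(out_dir, "screened.csv"),
                               "screen", NA)
        note_output(sp)
        ratio <- curve$ratio[max(which(curve$threshold <= cutoff))]
        list(cutoff = cutoff, n_selected = nrow(sel),
             tp_fp_at_cutoff = if (is.infinite(ratio)) "Inf" else ratio)
      }))
  }
  manifest$status <- "ok"
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
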