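#' @title Reproducible experiment runs
#' @description Configuration validation and a one-call driver that chains
#'   simulate/read -> extract -> featurize -> train -> evaluate into a
#'   self-describing run directory: the config snapshot and seeds it
#'   contains suffice to reproduce every artifact.
#' @name run_experiment
NULL

config_defaults <- function() {
  list(
    paths = list(corpus = NULL, lexicon = NULL, curated = NULL,
                 rundir = "rundir"),
    seeds = list(pipeline = 1L, simulation = 1L),
    parameters = list(fraction = 0.8, k = 5L, top_k = 50L, min_patients = 4L,
                      n_trees = 300L, sens_floor = 0.70,
                      cutoff_override = NULL,
                      n_patients = 73L, prevalence = 0.37,
                      notes_meanlog = log(70), notes_sdlog = 1.16,
                      notes_min = 1L, notes_max = 876L),
    flags = list(simulate = FALSE, stratified = FALSE, stemming = FALSE,
                 final_features = "reselect", write_corpus = FALSE)
  )
}

merge_defaults <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      user[[nm]] <- merge_defaults(user[[nm]], defaults[[nm]])
    } else if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
    }
  }
  user
}

#' Validate a run configuration
#'
#' Reads a YAML or JSON configuration file (or takes a list), fills every
#' omitted constant with the pipeline defaults (training fraction 0.8,
#' 5 folds, top 50 codes, minimum 4 patients per code, 300 trees,
#' sensitivity floor 0.70), and checks domains.
#'
#' @param config path to a YAML/JSON file, or a (possibly partial) config
#'   list.
#' @return A validated `run_config` list with components `paths`, `seeds`,
#'   `parameters`, `flags`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  cfg <- merge_defaults(config, config_defaults())
  p <- cfg$parameters
  check <- function(ok, key, msg) {
    if (!ok) stop("config parameter \"", key, "\" out of domain: ", msg)
  }
  check(p$fraction > 0 && p$fraction < 1, "fraction", "must be in (0, 1)")
  check(p$k >= 2, "k", "need at least 2 folds")
  check(p$top_k >= 1, "top_k", "must be >= 1")
  check(p$min_patients >= 1, "min_patients", "must be >= 1")
  check(p$n_trees >= 1, "n_trees", "must be >= 1")
  check(p$sens_floor >= 0 && p$sens_floor <= 1, "sens_floor",
        "must be in [0, 1]")
  if (!is.null(p$cutoff_override)) {
    check(p$cutoff_override >= 0 && p$cutoff_override <= 1, "cutoff_override",
          "must be in [0, 1]")
  }
  check(p$prevalence >= 0 && p$prevalence <= 1, "prevalence",
        "must be in [0, 1]")
  check(p$n_patients >= 2, "n_patients", "must be >= 2")
  check(p$notes_min >= 1 && p$notes_max >= p$notes_min, "notes_min",
        "need 1 <= notes_min <= notes_max")
  if (!cfg$flags$final_features %in% c("reselect", "union")) {
    stop("config parameter \"final_features\" out of domain: ",
         "must be \"reselect\" or \"union\"")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run a full experiment into a run directory
#'
#' Loads or simulates the corpus, runs [run_pipeline()], and writes the
#' artifacts: `config.json` (snapshot), `split.tsv`, `folds.tsv`,
#' `fold_features.tsv` (per-fold selected codes with rank),
#' `cv_performance.csv`, `holdout_performance.csv`, `roc.csv`, `roc.png`,
#' `summary.json` (selected cutoff, headline metrics, AUC, cohort summary,
#' model fingerprint), and `log.txt` with stage timings.
#'
#' @param config a `run_config`, config list, or path (see
#'   [validate_config()]).
#' @return The `pipeline_result`, invisibly, with `rundir` attached.
#' @export
run_experiment <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  rundir <- cfg$paths$rundir
  dir.create(rundir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(rundir, "log.txt")
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(c(log_lines,
                   sprintf("[%s] stage %s FAILED: %s",
                           format(Sys.time()), name, conditionMessage(e))),
                 log_path)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    log_lines <<- c(log_lines, sprintf("[%s] stage %s done in %.1fs",
                                       format(Sys.time()), name, dt))
    res
  }

  lexicon <- stage("lexicon", {
    if (is.null(cfg$paths$lexicon)) build_default_lexicon()
    else read_lexicon(cfg$paths$lexicon)
  })
  curated <- stage("curated", {
    if (is.null(cfg$paths$curated)) default_curated_terms()
    else read_curated_terms(cfg$paths$curated)
  })
  corpus <- stage("corpus", {
    if (isTRUE(cfg$flags$simulate) || is.null(cfg$paths$corpus)) {
      gc_cfg <- generator_config(n_patients = cfg$parameters$n_patients,
                                 prevalence = cfg$parameters$prevalence,
                                 notes_meanlog = cfg$parameters$notes_meanlog,
                                 notes_sdlog = cfg$parameters$notes_sdlog,
                                 notes_min = cfg$parameters$notes_min,
                                 notes_max = cfg$parameters$notes_max,
                                 lexicon = lexicon,
                                 seed = cfg$seeds$simulation)
      generate_cohort(gc_cfg)
    } else {
      read_corpus(cfg$paths$corpus)
    }
  })
  if (isTRUE(cfg$flags$write_corpus)) {
    write_corpus(corpus, file.path(rundir, "corpus.jsonl"))
  }
  opts <- extraction_options(stemming = cfg$flags$stemming)
  res <- stage("pipeline", {
    run_pipeline(corpus, lexicon, curated,
                 seed = cfg$seeds$pipeline,
                 fraction = cfg$parameters$fraction,
                 k = cfg$parameters$k, top_k = cfg$parameters$top_k,
                 min_patients = cfg$parameters$min_patients,
                 n_trees = cfg$parameters$n_trees,
                 sens_floor = cfg$parameters$sens_floor,
                 cutoff_override = cfg$parameters$cutoff_override,
                 stratified = cfg$flags$stratified,
                 final_features = cfg$flags$final_features,
                 options = opts)
  })
  stage("report", {
    snap <- cfg
    class(snap) <- NULL
    jsonlite::write_json(snap, file.path(rundir, "config.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
    utils::write.table(
      data.frame(patient_id = c(res$split$training_patients,
                                res$split$holdout_patients),
                 set = c(rep("training", length(res$split$training_patients)),
                         rep("holdout", length(res$split$holdout_patients)))),
      file.path(rundir, "split.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(patient_id = names(res$folds), fold = as.integer(res$folds)),
      file.path(rundir, "folds.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ff <- do.call(rbind, lapply(seq_along(res$cv$fold_features), function(f) {
      codes <- res$cv$fold_features[[f]]
      data.frame(fold = f, rank = seq_along(codes), code = codes)
    }))
    utils::write.table(ff, file.path(rundir, "fold_features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report_tables(res$cv$summary, res$final$holdout_table, res$final$roc,
                  rundir)
    hl <- res$final$headline
    jsonlite::write_json(
      list(selected_cutoff = res$selected_cutoff,
           headline = as.list(hl),
           auc = res$final$roc$auc,
           cohort = res$summary,
           matrix_dims = as.list(res$matrix_dims),
           model_fingerprint = res$final$model$training_fingerprint),
      file.path(rundir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    invisible(NULL)
  })
  writeLines(log_lines, log_path)
  attr(res, "rundir") <- rundir
  invisible(res)
}
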