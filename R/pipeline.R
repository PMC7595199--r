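#' Default pipeline run configuration
#'
#' A run config bundles everything needed to reproduce a run: synthesis
#' parameters (or input paths), spectral and index options, the
#' classification task, classifier options, the master seed and the output
#' directory.  It is a plain serializable list; the same config + seed
#' reproduce identical artifacts.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master seed.
#' @param task Classification task (see [build_design_matrix()]).
#' @param n_per_group Cohort composition for simulation.
#' @param duration Recording length in seconds.
#' @param n_trees,min_leaf,mtry Classifier options ([fit_bagged_trees()]).
#' @param sessions_dir,manifest Input paths for pre-existing recordings
#'   (when `NULL`, the simulate stage generates them).
#' @param f_min,f_max,f_step,wavenumber Spectral grid options.
#' @param split pdBSI low/high boundary (Hz).
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "qeeg_run", seed = 1L,
                       task = "moderate_large_vs_rest",
                       n_per_group = c(control = 9, small = 4,
                                       moderate = 9, large = 3),
                       duration = 180, n_trees = 200, min_leaf = 1,
                       mtry = NULL, sessions_dir = NULL, manifest = NULL,
                       f_min = 0.5, f_max = 31, f_step = 0.1,
                       wavenumber = 15, split = 10, quiet = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), task = task,
                 n_per_group = n_per_group, duration = duration,
                 n_trees = n_trees, min_leaf = min_leaf, mtry = mtry,
                 sessions_dir = sessions_dir, manifest = manifest,
                 f_min = f_min, f_max = f_max, f_step = f_step,
                 wavenumber = wavenumber, split = split, quiet = quiet),
            class = "run_config")
}

stage_log <- function(config, stage, t0, detail = "") {
  if (isTRUE(config$quiet)) return(invisible())
  message(sprintf("[%s] %s (%.2f s) %s", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0, detail))
}

feature_config <- function(config) {
  list(spectral = spectral_config(config$f_min, config$f_max,
                                  config$f_step, config$wavenumber),
       split = config$split)
}

#' Simulate stage: synthetic cohort written as session files
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` and `sessions_dir` paths.
#' @export
stage_simulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  params <- synthesis_params(seed = config$seed,
                             n_per_group = config$n_per_group,
                             duration = config$duration)
  sim <- synth_cohort(params)
  sdir <- file.path(config$out_dir, "sessions")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  for (id in sim$cohort$id)
    write_session(sim$recordings[[id]], file.path(sdir, id))
  mpath <- file.path(config$out_dir, "manifest.csv")
  write_cohort(sim$cohort, mpath)
  stage_log(config, "simulate", t0,
            sprintf("-> %d sessions in %s", nrow(sim$cohort), sdir))
  invisible(list(manifest = mpath, sessions_dir = sdir))
}

#' Feature stage: session files to a per-participant feature table
#'
#' @param config A [run_config()]; `sessions_dir`/`manifest` default to the
#'   simulate stage's outputs under `out_dir`.
#' @return Invisibly, the path of the written `features.csv`.
#' @export
stage_features <- function(config) {
  t0 <- as.numeric(Sys.time())
  mpath <- config$manifest %||% file.path(config$out_dir, "manifest.csv")
  sdir <- config$sessions_dir %||% file.path(config$out_dir, "sessions")
  cohort <- read_cohort(mpath)
  fc <- feature_config(config)
  feats <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    rec <- read_session(file.path(sdir, cohort$id[i]))
    assemble_features(rec, cohort[i, ], fc)
  }))
  fpath <- file.path(config$out_dir, "features.csv")
  utils::write.csv(feats, fpath, row.names = FALSE)
  stage_log(config, "features", t0, sprintf("-> %s", fpath))
  invisible(fpath)
}

#' Classify stage: bagged trees with out-of-bag scoring
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the model, confusion matrices, metrics
#'   and the written report paths.
#' @export
stage_classify <- function(config) {
  t0 <- as.numeric(Sys.time())
  cohort <- read_cohort(config$manifest %||%
                          file.path(config$out_dir, "manifest.csv"))
  feats <- utils::read.csv(file.path(config$out_dir, "features.csv"),
                           stringsAsFactors = FALSE)
  dm <- build_design_matrix(cohort, task = config$task, features = feats)
  model <- fit_bagged_trees(dm, n_trees = config$n_trees,
                            seed = derive_seed(config$seed, 1000),
                            min_leaf = config$min_leaf, mtry = config$mtry)
  cms <- oob_confusion(model)
  if (inherits(cms, "confusion_matrix")) cms <- list(cms)
  rows <- lapply(cms, function(cm) {
    m <- confusion_metrics(cm)
    data.frame(task = config$task, positive_class = attr(cm, "positive"),
               tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity,
               chance_accuracy = chance_accuracy(dm$label),
               oob_accuracy = oob_accuracy(model))
  })
  report <- do.call(rbind, rows)
  rpath <- file.path(config$out_dir, "model_report.csv")
  utils::write.csv(report, rpath, row.names = FALSE)
  ipath <- file.path(config$out_dir, "importance.csv")
  imp <- sort(model$feature_importance, decreasing = TRUE)
  utils::write.csv(data.frame(feature = names(imp), importance = imp),
                   ipath, row.names = FALSE)
  stage_log(config, "classify", t0,
            sprintf("task=%s oob_acc=%.3f -> %s", config$task,
                    oob_accuracy(model), rpath))
  invisible(list(model = model, confusion = cms, report = report,
                 paths = c(report = rpath, importance = ipath)))
}

#' Score raw confusion counts
#'
#' Computes accuracy/sensitivity/specificity and the majority-class chance
#' accuracy for a table of confusion counts -- so externally reported
#' counts can be scored without any recordings.  For a multiclass model
#' given as one-vs-rest rows sharing a `model` value, the overall accuracy
#' `sum(TP) / total` is also reported.
#'
#' @param counts Data frame (or path to a delimited file) with columns
#'   `model`, `class`, `tn`, `fn`, `tp`, `fp`.
#' @return Data frame with one row per counts row: the three metrics,
#'   chance accuracy and (for multiclass models) `multiclass_accuracy`.
#' @export
metrics_from_counts <- function(counts) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  req <- c("model", "class", "tn", "fn", "tp", "fp")
  if (!all(req %in% names(counts)))
    abort_format(sprintf("counts table needs columns: %s",
                         paste(req, collapse = ", ")))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    m <- confusion_metrics(confusion_matrix(r$tp, r$fp, r$fn, r$tn,
                                            positive = r$class))
    data.frame(model = r$model, class = r$class,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity)
  })
  out <- do.call(rbind, out)
  # chance + multiclass accuracy per model block
  out$chance_accuracy <- NA_real_
  out$multiclass_accuracy <- NA_real_
  for (mod in unique(counts$model)) {
    sel <- counts$model == mod
    pos <- counts$tp[sel] + counts$fn[sel]
    total <- counts$tp[sel][1] + counts$fn[sel][1] +
      counts$tn[sel][1] + counts$fp[sel][1]
    if (sum(sel) == 1) pos <- c(pos, total - pos)
    out$chance_accuracy[out$model == mod] <- max(pos) / total
    if (sum(sel) > 1)
      out$multiclass_accuracy[out$model == mod] <- sum(counts$tp[sel]) / total
  }
  out
}

#' Run the full pipeline
#'
#' simulate -> features -> classify -> report, each stage leaving its
#' artifacts under `config$out_dir`; a `manifest.json` records the config,
#' its hash, the seed and the package version.  Stage failures propagate
#' with the failing stage named; artifacts written by earlier stages are
#' left intact.
#'
#' @param config A [run_config()].
#' @return Invisibly, the classify stage's result list.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wrap <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      qeeg_error(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 class = c("qeeg_stage_error", class(e)))
    })
  }
  if (is.null(config$sessions_dir)) wrap("simulate", function() stage_simulate(config))
  wrap("features", function() stage_features(config))
  res <- wrap("classify", function() stage_classify(config))

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         package = "qeegstroke",
         version = as.character(utils::packageVersion("qeegstroke")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  cat("qeegstroke pipeline run\n=======================\n")
  cat(sprintf("task: %s   seed: %d   trees: %d\n\n",
              config$task, config$seed, config$n_trees))
  print(res$report)
  sink()
  close(con)
  invisible(res)
}

# ---- command line ----------------------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort_param(sprintf("unexpected argument: %s", a))
    key <- gsub("-", "_", substring(a, 3))
    if (key %in% c("quiet", "verbose")) {
      flags[[key]] <- TRUE; i <- i + 1
    } else {
      if (i == length(args)) abort_param(sprintf("flag %s needs a value", a))
      flags[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  flags
}

cli_config <- function(flags) {
  base <- if (!is.null(flags$config))
    jsonlite::read_json(flags$config, simplifyVector = TRUE) else list()
  for (nm in setdiff(names(flags), c("config", "counts")))
    base[[nm]] <- flags[[nm]]
  cfg <- run_config()
  for (nm in intersect(names(base), names(cfg))) {
    v <- base[[nm]]
    if (nm %in% c("seed", "n_trees", "min_leaf", "mtry"))
      v <- as.integer(v)
    if (nm %in% c("duration", "f_min", "f_max", "f_step", "wavenumber",
                  "split"))
      v <- as.numeric(v)
    if (nm == "n_per_group" && is.character(v)) {
      v <- as.numeric(strsplit(v, ",")[[1]])
      names(v) <- severity_levels()
    }
    cfg[[nm]] <- v
  }
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `features`, `classify`, `run` (all stages),
#' `metrics` (score a confusion-counts file: `--counts path`), `report`
#' (print a run's summary).  Flags mirror [run_config()] fields
#' (`--out-dir`, `--seed`, `--task`, `--n-trees`, `--duration`,
#' `--n-per-group 9,4,9,3`, ...); `--config file.json` supplies a config
#' file that individual flags override.
#'
#' Exit codes: 0 success, 2 validation error, 3 stage failure.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return The exit code, invisibly.
#' @export
qeeg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: qeegstroke <simulate|features|classify|run|metrics|report> [--flags]")
    return(invisible(2L))
  }
  cmd <- args[1]
  code <- tryCatch({
    flags <- cli_parse_flags(args[-1])
    cfg <- cli_config(flags)
    switch(cmd,
      simulate = stage_simulate(cfg),
      features = stage_features(cfg),
      classify = stage_classify(cfg),
      run = run_pipeline(cfg),
      metrics = {
        if (is.null(flags$counts))
          abort_param("metrics requires --counts <file>")
        m <- metrics_from_counts(flags$counts)
        print(m, digits = 3, row.names = FALSE)
      },
      report = {
        p <- file.path(cfg$out_dir, "summary.txt")
        if (!file.exists(p)) abort_io(sprintf("no summary at %s", p))
        cat(readLines(p), sep = "\n")
      },
      abort_param(sprintf("unknown subcommand: %s", cmd)))
    0L
  },
  qeeg_stage_error = function(e) { message("error: ", conditionMessage(e)); 3L },
  qeeg_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 3L })
  invisible(code)
}
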