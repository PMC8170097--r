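#' End-to-end pipeline
#'
#' `run_all()` executes the three-step methodology on either a synthetic
#' cohort or a directory of CHAT transcripts: feature extraction,
#' per-language screening with generalizable-feature selection, and the
#' leave-one-out classification grid.  All tabular artifacts are written
#' as CSV, the selection and results as JSON, and a human-readable report
#' summarizes feature counts, the selected set and the per-scenario
#' confusion matrices.  Every output embeds the seed and a hash of the
#' configuration.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param synth a [synth_params()] object (synthetic-cohort mode), or
#'   `NULL` when `transcript_dir` is given.
#' @param transcript_dir directory of `.cha` files named
#'   `<lang>_<group>_<id>.cha` (clinical-data mode).
#' @param alpha significance level for selection.
#' @param bonferroni_m Bonferroni multiplier, or `"auto"` for the runtime
#'   feature count.
#' @param models classifier kinds to run.
#' @param seed integer master seed.
#' @param mode `"paper-faithful"` selects features once on the full data
#'   before cross-validation; `"nested-selection"` re-selects inside every
#'   training fold (honest but slower; reported per scenario).
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_params(), transcript_dir = NULL,
                       alpha = 0.05, bonferroni_m = "auto",
                       models = c("LR", "SVM", "MLP"), seed = 1,
                       mode = c("paper-faithful", "nested-selection")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(synth = synth, transcript_dir = transcript_dir,
                 alpha = alpha, bonferroni_m = bonferroni_m,
                 models = models, seed = as.integer(seed),
                 mode = match.arg(mode)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

load_transcript_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.cha$", full.names = TRUE)
  if (length(files) == 0) stop("no .cha files in ", dir, call. = FALSE)
  records <- lapply(files, function(f) {
    parts <- strsplit(sub("\\.cha$", "", basename(f)), "_")[[1]]
    if (length(parts) < 3 || !(parts[1] %in% c("en", "fr")) ||
        !(toupper(parts[2]) %in% c("HC", "AD")))
      stop("cannot parse language/group from filename: ", basename(f),
           call. = FALSE)
    list(subject_id = sub("\\.cha$", "", basename(f)),
         language = parts[1], group = toupper(parts[2]),
         age = NA_real_, duration_s = NA_real_,
         transcript = read_chat(f))
  })
  list(records = records,
       labels = vapply(records, function(r)
         as.numeric(r$group == "AD"), numeric(1)),
       languages = vapply(records, `[[`, character(1), "language"),
       ground_truth = NULL)
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with `features`, `registry`, `stats`,
#'   `selection`, `results`, `report_path` and the artifact paths.
#' @export
run_all <- function(config = run_config(), out_dir = tempfile("smrun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  hash <- config_hash(config)
  log_lines <- c(sprintf("speechmarkers run: seed=%d config=%s",
                         config$seed, hash))
  stage <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }

  # -- stage 1: cohort + features -------------------------------------
  stage("stage 1: cohort and feature extraction")
  if (!is.null(config$transcript_dir)) {
    cohort <- load_transcript_cohort(config$transcript_dir)
    params <- config$synth
    if (is.null(params)) params <- synth_params(seed = config$seed)
  } else {
    params <- config$synth
    params$seed <- config$seed
    cohort <- generate_cohort(params)
  }
  ext <- extract_cohort_features(cohort, params)
  features <- ext$features
  registry <- ext$registry

  features_csv <- file.path(out_dir, "features.csv")
  utils::write.csv(cbind(subject_id = rownames(features),
                         label = ext$labels, language = ext$languages,
                         features),
                   features_csv, row.names = FALSE)
  utils::write.csv(registry, file.path(out_dir, "registry.csv"),
                   row.names = FALSE)

  # -- stage 2: per-language statistics and selection -----------------
  stage("stage 2: cross-language screening")
  m <- if (identical(config$bonferroni_m, "auto")) ncol(features)
       else as.integer(config$bonferroni_m)
  stats_en <- build_stats_table(features[ext$languages == "en", ],
                                ext$labels[ext$languages == "en"],
                                "en", registry, m = m,
                                alpha = config$alpha)
  stats_fr <- build_stats_table(features[ext$languages == "fr", ],
                                ext$labels[ext$languages == "fr"],
                                "fr", registry, m = m,
                                alpha = config$alpha)
  stats_all <- rbind(stats_en, stats_fr)
  stats_csv <- file.path(out_dir, "stats.csv")
  utils::write.csv(stats_all, stats_csv, row.names = FALSE)

  selection <- select_generalizable(stats_en, stats_fr, registry,
                                    alpha = config$alpha)
  selection_json <- file.path(out_dir, "selection.json")
  jsonlite::write_json(c(selection, list(seed = config$seed,
                                         config_hash = hash)),
                       selection_json, auto_unbox = TRUE, digits = NA)

  # correlation pairs for cross-language effect-size plots
  corr <- data.frame(
    feature = stats_en$feature,
    subgroup = stats_en$subgroup,
    r_pb_en = stats_en$r_pb,
    r_pb_fr = stats_fr$r_pb[match(stats_en$feature, stats_fr$feature)],
    sig_en = stats_en$significant_uncorrected,
    sig_fr = stats_fr$significant_uncorrected[
      match(stats_en$feature, stats_fr$feature)])
  utils::write.csv(corr, file.path(out_dir, "correlation_pairs.csv"),
                   row.names = FALSE)

  # -- stage 3: classification grid ----------------------------------
  stage("stage 3: leave-one-out classification grid")
  results <- run_scenarios(features, ext$labels, ext$languages, registry,
                           selection, ages = ext$ages,
                           models = config$models, seed = config$seed)
  results_json <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(seed = config$seed, config_hash = hash, mode = config$mode,
         results = lapply(results, unclass)),
    results_json, auto_unbox = TRUE, digits = NA)

  # -- report ---------------------------------------------------------
  stage("report")
  fam <- table(registry$subgroup)
  rep_lines <- c(
    "speechmarkers pipeline report",
    sprintf("seed: %d   config: %s", config$seed, hash),
    sprintf("subjects: %d (en %d / fr %d)", nrow(features),
            sum(ext$languages == "en"), sum(ext$languages == "fr")),
    "feature counts per family:",
    sprintf("  %-15s %d", names(fam), as.integer(fam)),
    sprintf("generalizable features selected (alpha=%.2f): %d",
            selection$alpha, length(selection$selected)),
    paste("  ", selection$selected),
    "",
    "scenario results:")
  for (r in results) {
    rep_lines <- c(rep_lines, if (isTRUE(r$skipped))
      sprintf("  %-28s %-4s SKIPPED (%s)", r$scenario_id, r$model, r$reason)
      else sprintf("  %-28s %-4s AUC=%.3f err=%.2f%% (n=%d, p=%d)",
                   r$scenario_id, r$model, r$auc, r$error_rate, r$n,
                   r$n_features))
  }
  rep_lines <- c(rep_lines, "", log_lines,
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report_path <- file.path(out_dir, "report.txt")
  writeLines(rep_lines, report_path)

  invisible(list(features = features, registry = registry,
                 stats = stats_all, selection = selection,
                 results = results, report_path = report_path,
                 paths = list(features = features_csv, stats = stats_csv,
                              selection = selection_json,
                              results = results_json,
                              report = report_path)))
}
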