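# End-to-end driver: simulate (or ingest) -> featurize -> collapse -> split
# -> train -> predict -> evaluate, with structured report output.

#' Experiment configuration
#'
#' Bundles and validates every knob of one end-to-end run. The three study
#' analyses are expressed through \code{analysis}: \code{"all"} uses every
#' observation under the chosen class scheme; \code{"adults_only"} and
#' \code{"children_only"} restrict rows to that subject class and the
#' vocabulary to the three behaviours children perform (sleep, enter, exit,
#' kept as three separate classes).
#'
#' @param sim A \code{\link{sim_config}} (ignored when \code{recording_path}
#'   is given).
#' @param feature_scheme "paper10" or "full14".
#' @param class_scheme "five", "four" or "three".
#' @param forest A \code{\link{forest_params}}.
#' @param train_fraction Training proportion for the 80/20 split.
#' @param stratified Stratify the split by label?
#' @param analysis "all", "adults_only" or "children_only".
#' @param n_subjects,child_fraction,reps Study design passed to
#'   \code{\link{simulate_study}}.
#' @param recording_path,tags_path Optional paths to ingest an existing
#'   recording + tag file instead of simulating.
#' @param seed Master seed; propagated to simulator, split and forest.
#' @return List of class \code{experiment_config}.
#' @export
experiment_config <- function(sim = sim_config(), feature_scheme = "paper10",
                              class_scheme = "three",
                              forest = forest_params(),
                              train_fraction = 0.8, stratified = FALSE,
                              analysis = c("all", "adults_only", "children_only"),
                              n_subjects = 27, child_fraction = 1 / 3, reps = 14,
                              recording_path = NULL, tags_path = NULL,
                              seed = 1L) {
  analysis <- match.arg(analysis)
  feature_names(feature_scheme)       # validate enums up front
  scheme_classes(class_scheme)
  stopifnot(inherits(sim, "sim_config"), inherits(forest, "forest_params"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("experiment_config: train_fraction must be in (0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  sim$seed <- seed
  forest$seed <- seed
  structure(list(sim = sim, feature_scheme = feature_scheme,
                 class_scheme = class_scheme, forest = forest,
                 train_fraction = train_fraction, stratified = stratified,
                 analysis = analysis, n_subjects = n_subjects,
                 child_fraction = child_fraction, reps = reps,
                 recording_path = recording_path, tags_path = tags_path,
                 seed = seed),
            class = "experiment_config")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[netmotion] ", fmt), ...))
}

#' Run one experiment end to end
#'
#' Executes the full pipeline for one configuration and, optionally, writes
#' the report to \code{out_dir}: \code{report.json} (machine-readable,
#' including a provenance block), \code{report.txt}, \code{confusion.csv},
#' \code{metrics.csv}, \code{importance.csv} and one \code{roc_<class>.csv}
#' point table per class. A run is a pure function of (config, seed).
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param out_dir Output directory (created if needed), or NULL to skip
#'   writing.
#' @param verbose Log each stage with row counts and the seed?
#' @return List of class \code{experiment_result}: \code{report}
#'   (\code{eval_report}), \code{importance}, \code{fit}, \code{split},
#'   \code{dataset}, \code{config}.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_stage(verbose, "seed %d, analysis '%s', scheme '%s'/'%s'",
            cfg$seed, cfg$analysis, cfg$feature_scheme, cfg$class_scheme)
  if (!is.null(cfg$recording_path)) {
    rec <- read_recording(cfg$recording_path)
    tags <- read_tags(cfg$tags_path, recording = rec)
    log_stage(verbose, "ingest: %d samples, %d tags", nrow(rec), nrow(tags))
  } else {
    sess <- simulate_study(n_subjects = cfg$n_subjects,
                           child_fraction = cfg$child_fraction,
                           reps = cfg$reps, cfg = cfg$sim)
    rec <- sess$recording
    tags <- sess$tags
    log_stage(verbose, "simulate: %d samples, %d tags", nrow(rec), nrow(tags))
  }
  ds <- build_dataset(rec, tags, scheme = cfg$feature_scheme)
  log_stage(verbose, "featurize: %d observations x %d features",
            nrow(ds), length(dataset_features(ds)))

  if (cfg$analysis == "all") {
    ds$label <- collapse_labels(ds$label, cfg$class_scheme)
    classes <- scheme_classes(cfg$class_scheme)
  } else {
    keep <- if (cfg$analysis == "adults_only") "adult" else "child"
    ds <- ds[ds$subject_class == keep & as.character(ds$label) %in% child_labels(), ]
    ds$label <- factor(as.character(ds$label),
                       levels = intersect(motion_labels(), child_labels()))
    classes <- levels(ds$label)
    log_stage(verbose, "restrict to %s: %d observations, %d classes",
              keep, nrow(ds), length(classes))
  }

  sp <- split_dataset(ds, train_fraction = cfg$train_fraction,
                      seed = cfg$seed, stratified = cfg$stratified)
  log_stage(verbose, "split: %d train / %d validation",
            nrow(sp$train), nrow(sp$validation))
  fit <- train_forest(sp$train, params = cfg$forest, classes = classes)
  pr <- predict(fit, sp$validation)
  report <- evaluate_model(sp$validation$label, pr$predicted, pr$scores,
                           classes = fit$classes)
  imp <- importance_ranking(fit)
  log_stage(verbose, "evaluate: accuracy %d/%d (%.1f%%)",
            report$correct, report$total, 100 * report$accuracy)

  res <- structure(list(report = report, importance = imp, fit = fit,
                        split = sp, dataset = ds, config = cfg),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

report_as_list <- function(res) {
  rep <- res$report
  list(
    class_scheme = res$config$class_scheme,
    feature_scheme = res$config$feature_scheme,
    analysis = res$config$analysis,
    accuracy = rep$accuracy,
    correct = rep$correct,
    total = rep$total,
    classes = rep$confusion$classes,
    confusion = as.data.frame(as.table(rep$confusion$counts)),
    metrics = rep$metrics,
    importance = res$importance,
    provenance = list(seed = res$config$seed,
                      n_trees = res$config$forest$n_trees,
                      mtry = res$config$forest$mtry,
                      train_fraction = res$config$train_fraction,
                      package_version = as.character(packageVersion("netmotion")),
                      r_version = R.version.string)
  )
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- res$report
  jsonlite::write_json(report_as_list(res), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(as.data.frame.matrix(rep$confusion$counts),
            file.path(out_dir, "confusion.csv"))
  write.csv(rep$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(res$importance, file.path(out_dir, "importance.csv"), row.names = FALSE)
  for (cl in names(rep$rocs))
    write.csv(rep$rocs[[cl]]$curve,
              file.path(out_dir, paste0("roc_", cl, ".csv")), row.names = FALSE)
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  sink(con)
  cat(sprintf("netmotion evaluation report (seed %d)\n", res$config$seed))
  cat(sprintf("analysis: %s | features: %s | classes: %s\n\n",
              res$config$analysis, res$config$feature_scheme,
              res$config$class_scheme))
  print(rep)
  cat("\nFeature importance ranking:\n")
  print(res$importance, row.names = FALSE)
  sink()
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("netmotion experiment (seed %d, analysis '%s', classes '%s')\n\n",
              x$config$seed, x$config$analysis, x$config$class_scheme))
  print(x$report)
  invisible(x)
}
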