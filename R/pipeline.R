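#' Run the full simulation-to-evaluation pipeline
#'
#' Executes the standard workflow end to end: simulate a censored training
#' set from the prior, train the estimation network, estimate parameters on
#' a fresh test set, compute the recovery report, generate a goal-labeled
#' set, train a goal classifier and evaluate it. Stage outputs are cached as
#' RDS files in `outdir` (keyed by a hash of the configuration) and a
#' manifest records the configuration, seed and package version.
#'
#' @param run_config A [default_run_config()] (or list from
#'   [read_run_config()]).
#' @param outdir Artifact directory (created if missing).
#' @param stages Character vector of stages to run, in order; any prefix of
#'   `c("simulate", "train", "recover", "labeled", "classify")`.
#' @param classifier_kind Input kind for the classifier stage.
#' @return A list with the artifacts produced (`trials`, `estimator`,
#'   `recovery`, `labeled`, `classifier`, `classifier_eval`) and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(run_config = default_run_config(),
                         outdir = tempfile("glop_run_"),
                         stages = c("simulate", "train", "recover",
                                    "labeled", "classify"),
                         classifier_kind = "summary") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rc <- as_run_config(run_config)
  obj <- run_config_objects(rc)
  cfg_hash <- rlang::hash(unclass_deep(rc))
  art <- list()
  cache <- function(name, expr) {
    f <- file.path(outdir, paste0(name, "-", cfg_hash, ".rds"))
    if (file.exists(f)) return(readRDS(f))
    val <- expr
    saveRDS(val, f)
    val
  }
  set.seed(rc$seed)
  if ("simulate" %in% stages) {
    art$trials <- cache("trials", generate_training_set(
      rc$n_trials, obj$prior, obj$geom, obj$config))
  }
  if ("train" %in% stages) {
    if (is.null(art$trials)) stop("stage 'train' needs stage 'simulate'")
    art$estimator <- cache("estimator", train_estimator(
      art$trials, epochs = rc$epochs, target_length = rc$target_length,
      lr = rc$lr, batch = rc$batch))
  }
  if ("recover" %in% stages) {
    if (is.null(art$estimator)) stop("stage 'recover' needs stage 'train'")
    test <- cache("test_trials", generate_training_set(
      rc$n_test, obj$prior, obj$geom, obj$config))
    est <- cache("test_estimates", estimate_params(test, art$estimator))
    art$test_trials <- test
    art$test_estimates <- est
    art$recovery <- recovery_analysis(test, est, test$censored_length,
                                      fps = obj$config$fps)
  }
  if ("labeled" %in% stages) {
    art$labeled <- cache("labeled", split_participants(
      generate_goal_labeled_set(
        max(4, rc$n_trials %/% 500), reps_per_cell = 1,
        geom = obj$geom, config = obj$config),
      n_test = 1, n_val = 1))
  }
  if ("classify" %in% stages) {
    if (is.null(art$labeled)) stop("stage 'classify' needs stage 'labeled'")
    art$classifier <- cache("classifier", train_classifier(
      art$labeled, classifier_kind, iterations = min(rc$epochs * 10, 500),
      estimator = art$estimator))
    test_set <- art$labeled[art$labeled$split == "test", , drop = FALSE]
    art$classifier_eval <- evaluate_classifier(test_set, art$classifier,
                                               art$estimator)
  }
  manifest <- list(
    config_hash = cfg_hash, seed = rc$seed,
    package_version = as.character(utils::packageVersion("glopr")),
    r_version = R.version.string,
    stages = stages, created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  art$manifest <- manifest
  art$outdir <- outdir
  invisible(art)
}
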