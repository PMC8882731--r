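# End-to-end workflow commands: simulate, train, predict, evaluate, sweep.
# Each command writes its outputs plus a provenance record (config, versions,
# seeds, stage counts) beside them, so any run is reproducible from the
# record alone. A thin shell wrapper over these functions is installed at
# inst/scripts/i6ma-vote.R.

#' Default run configuration
#'
#' The JSON-serializable configuration shared by the pipeline commands:
#' encoder choice, train fraction for the internal validation split, CV
#' folds, per-algorithm hyperparameter grids (`NULL` disables grid search),
#' vote threshold and master seed. Shipped as
#' `inst/extdata/default_config.json`.
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(encoder = "ONEHOT2", trainFraction = 0.8, folds = 5L,
       voteThreshold = 3L, seed = 1L, gridSearch = FALSE, grids = NULL)
}

#' Read a run configuration from JSON
#'
#' Missing fields fall back to [defaultRunConfig()]; unknown fields are an
#' error so typos do not pass silently.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return Named configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

.writeProvenance <- function(dir, command, config, extra = list()) {
  rec <- c(list(command = command,
                package = "i6maVote",
                version = as.character(utils::packageVersion("i6maVote")),
                rVersion = as.character(getRversion()),
                date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config),
           extra)
  jsonlite::write_json(rec, file.path(dir, paste0(command, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate and write a synthetic dataset
#'
#' @param outDir Output directory; receives `positives.fasta`,
#'   `negatives.fasta` and `simulation.json`.
#' @param nPos,nNeg Sample sizes.
#' @param strength Common enrichment strength for
#'   [defaultEnrichmentProfile()].
#' @param seed RNG seed.
#' @param profile Optional [EnrichmentProfile-class] overriding
#'   `strength`.
#' @return Invisibly, the generated [WindowSet-class].
#' @export
runSimulation <- function(outDir, nPos = 1000L, nNeg = 1000L, strength = 0.5,
                          seed = 1L, profile = NULL) {
  profile <- profile %||% defaultEnrichmentProfile(strength = strength)
  ws <- simulateWindows(nPos, nNeg, profile, seed = seed)
  writeSimulation(ws, outDir, profile, seed)
  invisible(ws)
}

.readCleanPair <- function(positiveFasta, negativeFasta, maxLen = 41L) {
  pos <- readFastaWindows(positiveFasta, label = 1)
  neg <- readFastaWindows(negativeFasta, label = 0)
  cleanWindows(pos, neg, maxLen = maxLen)
}

#' Train an ensemble from positive/negative FASTA files
#'
#' Pipeline: read both FASTA files, clean (length filter, per-label
#' deduplication, cross-label overlap removal), split off an internal
#' validation part, train the five-learner voting ensemble on the training
#' part (grid search when `config$gridSearch`), evaluate on the validation
#' part and save the model archive plus reports.
#'
#' @param positiveFasta,negativeFasta FASTA paths (6mA / non-6mA windows).
#' @param outDir Output directory: `model.rds`, `cleaning_report.json`,
#'   `validation_metrics.json` and `train_provenance.json`.
#' @param config Configuration list as from [readRunConfig()].
#' @return List: `model` ([I6maVoteModel-class]), `metrics` (named
#'   validation metrics), `modelPath`.
#' @export
runTraining <- function(positiveFasta, negativeFasta, outDir,
                        config = defaultRunConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  message("[clean] reading and cleaning input FASTA files")
  cleaned <- .readCleanPair(positiveFasta, negativeFasta)
  writeCleaningReport(cleaned$report, file.path(outDir, "cleaning_report.json"))
  message(sprintf("[clean] kept %d positive / %d negative windows",
                  length(cleaned$positives), length(cleaned$negatives)))

  all <- bindWindowSets(cleaned$positives, cleaned$negatives)
  split <- splitWindows(all, trainFraction = config$trainFraction,
                        seed = config$seed)
  message(sprintf("[split] %d train / %d validation windows",
                  length(split$train), length(split$test)))

  grids <- if (isTRUE(config$gridSearch)) config$grids %||% defaultGrids()
           else NULL
  message(sprintf("[train] fitting 5 base learners on %s features%s",
                  paste(config$encoder, collapse = "+"),
                  if (is.null(grids)) "" else " with grid search"))
  model <- trainEnsemble(split$train, encoder = config$encoder,
                         grids = grids, folds = config$folds,
                         voteThreshold = config$voteThreshold,
                         seed = config$seed)

  pred <- predict(model, split$test)
  metrics <- computeMetrics(confusionCounts(windowLabels(split$test),
                                            pred$ensemble_label))
  jsonlite::write_json(as.list(metrics),
                       file.path(outDir, "validation_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("[validate] ACC %.3f  MCC %.3f  SN %.3f  SP %.3f",
                  metrics[["ACC"]], metrics[["MCC"]], metrics[["SN"]],
                  metrics[["SP"]]))

  modelPath <- file.path(outDir, "model.rds")
  saveEnsemble(model, modelPath)
  .writeProvenance(outDir, "train", config,
                   list(positiveFasta = positiveFasta,
                        negativeFasta = negativeFasta,
                        cleaning = cleaned$report,
                        validationMetrics = as.list(metrics)))
  list(model = model, metrics = metrics, modelPath = modelPath)
}

#' Predict 6mA labels for a query FASTA
#'
#' @param modelPath Archive written by [saveEnsemble()] / [runTraining()].
#' @param queryFasta FASTA of candidate windows.
#' @param outPath Output TSV (`id`, `ensemble_label`, five `vote_*`
#'   columns).
#' @param skipInvalid Drop windows that are not valid adenine-centered
#'   model-length windows (with a warning listing how many) instead of
#'   aborting.
#' @return The predictions data.frame, invisibly.
#' @export
runPrediction <- function(modelPath, queryFasta, outPath,
                          skipInvalid = FALSE) {
  model <- loadEnsemble(modelPath)
  query <- readFastaWindows(queryFasta, label = 0, datasetName = "query")
  if (skipInvalid) {
    L <- model@windowLength
    center <- (L + 1L) %/% 2L
    seqs <- as.character(windowSequences(query))
    ok <- nchar(seqs) == L & substring(seqs, center, center) == "A"
    if (!all(ok)) {
      warning(sprintf("skipping %d invalid window(s): %s", sum(!ok),
                      paste(utils::head(windowIds(query)[!ok], 10L),
                            collapse = ", ")))
      query <- query[ok]
    }
    if (!length(query)) stop("no valid query windows remain")
  }
  pred <- predict(model, query)
  writePredictions(pred, outPath)
  invisible(pred)
}

#' Evaluate a saved model on labeled FASTA files
#'
#' Predicts both files with the stored ensemble and reports ACC, MCC, SN and
#' SP. The per-window predictions and the metric report (TSV and JSON) are
#' written under `outDir`.
#'
#' @inheritParams runPrediction
#' @param positiveFasta,negativeFasta Labeled FASTA paths.
#' @param outDir Output directory.
#' @return Named numeric vector of metrics, invisibly.
#' @export
runEvaluation <- function(modelPath, positiveFasta, negativeFasta, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- loadEnsemble(modelPath)
  pos <- readFastaWindows(positiveFasta, label = 1)
  neg <- readFastaWindows(negativeFasta, label = 0)
  all <- bindWindowSets(pos, neg)
  pred <- predict(model, all)
  pred$true_label <- windowLabels(all)
  writePredictions(pred, file.path(outDir, "predictions.tsv"))
  metrics <- computeMetrics(confusionCounts(pred$true_label,
                                            pred$ensemble_label))
  tsv <- data.frame(metric = names(metrics),
                    value = sprintf("%.3f", metrics))
  utils::write.table(tsv, file.path(outDir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(metrics), file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeProvenance(outDir, "evaluate", list(modelPath = modelPath),
                   list(positiveFasta = positiveFasta,
                        negativeFasta = negativeFasta,
                        metrics = as.list(metrics)))
  invisible(metrics)
}

#' Cross-validated encoder-by-classifier sweep from FASTA inputs
#'
#' Cleans the inputs and runs [sweepEncoders()] over the requested encoders
#' and all five classifiers, writing the long results and the formatted
#' classifier-by-encoder table as TSV.
#'
#' @inheritParams runEvaluation
#' @param encoders Character vector of encoder names (default all six).
#' @param config Configuration list (folds and seed are used).
#' @return The long sweep data.frame, invisibly.
#' @export
runSweep <- function(positiveFasta, negativeFasta, outDir,
                     encoders = c("AMNF", "ADNF", "DPCP", "TPCP",
                                  "ONEHOT1", "ONEHOT2"),
                     config = defaultRunConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cleaned <- .readCleanPair(positiveFasta, negativeFasta)
  all <- bindWindowSets(cleaned$positives, cleaned$negatives)
  res <- sweepEncoders(all, encoders, folds = config$folds,
                       seed = config$seed)
  utils::write.table(res, file.path(outDir, "sweep_long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(formatSweepTable(res),
                     file.path(outDir, "sweep_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeProvenance(outDir, "sweep", config,
                   list(encoders = encoders, n = length(all)))
  invisible(res)
}
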