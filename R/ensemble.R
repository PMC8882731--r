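# Five-learner voting ensemble: base-learner contract, grid search, training,
# prediction and persistence.
#
# Base learners are delegated to established implementations (ranger for the
# random forest, MASS::lda, nnet for the single-hidden-layer MLP, xgboost)
# behind one fit/predict contract; the SGD learner — an L2-regularized
# logistic regression fit by per-sample stochastic gradient descent — is
# implemented here. Votes are hard 0/1 labels, never probabilities.

.ALGORITHMS <- c("RF", "LDA", "MLP", "SGD", "XGB")

#' Base classifier specification
#'
#' @param algorithm One of `"RF"`, `"LDA"`, `"MLP"`, `"SGD"`, `"XGB"`.
#' @param hyperparameters Named list overriding [defaultHyperparameters()].
#' @param seed Integer seed for stochastic algorithms (recorded always).
#' @return A list of class `"baseSpec"`.
#' @examples
#' baseSpec("RF", list(num.trees = 100), seed = 7)
#' @export
baseSpec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithm <- toupper(algorithm)
  if (!algorithm %in% .ALGORITHMS)
    stop("algorithm must be one of: ", paste(.ALGORITHMS, collapse = ", "))
  hp <- utils::modifyList(defaultHyperparameters(algorithm), hyperparameters)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "baseSpec")
}

#' Default hyperparameters per base algorithm
#'
#' Conservative defaults sized for 41-nt window features; all are overridable
#' through [baseSpec()] or tunable through [gridSearch()].
#'
#' @param algorithm One of the five algorithm names.
#' @return Named list of hyperparameters.
#' @export
defaultHyperparameters <- function(algorithm) {
  switch(toupper(algorithm),
    RF  = list(num.trees = 300L, mtry = NULL),
    LDA = list(),
    MLP = list(size = 4L, decay = 1e-2, maxit = 100L),
    SGD = list(learningRate = 0.05, lambda = 1e-4, epochs = 20L),
    XGB = list(nrounds = 150L, eta = 0.3, max_depth = 6L),
    stop("unknown algorithm: ", algorithm)
  )
}

#' Default grid-search grids per algorithm
#'
#' The published method optimizes each base learner by exhaustive grid
#' search but does not fix the grids; these are the package defaults, also
#' shipped as `inst/extdata/default_config.json` so users can see and edit
#' them. LDA has no tunable hyperparameters here and gets an empty grid.
#'
#' @return Named list (one element per algorithm) of name -> value-vector
#'   grids.
#' @export
defaultGrids <- function() {
  list(
    RF  = list(num.trees = c(200L, 500L)),
    LDA = list(),
    MLP = list(size = c(4L, 8L), decay = c(1e-3, 1e-2)),
    SGD = list(learningRate = c(0.01, 0.05, 0.1), lambda = c(1e-4, 1e-3)),
    XGB = list(eta = c(0.1, 0.3), max_depth = c(3L, 6L))
  )
}

.ensureColnames <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)) - 1L)
  X
}

#' Fit one base classifier
#'
#' Uniform fit contract over the five algorithms. `y` must contain both
#' classes; stochastic algorithms reproduce exactly given `spec$seed`.
#'
#' @param spec A [baseSpec()].
#' @param X Numeric feature matrix (rows = samples).
#' @param y Labels, coercible to integer 0/1, one per row of `X`.
#' @return A fitted classifier of class `"i6maBaseFit"`; predict with
#'   [predictBase()].
#' @export
trainBase <- function(spec, X, y) {
  stopifnot(inherits(spec, "baseSpec"))
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both classes are required")
  X <- .ensureColnames(X)
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    RF = {
      args <- list(x = X, y = factor(y, levels = 0:1),
                   num.trees = hp$num.trees, seed = spec$seed,
                   num.threads = 1L, verbose = FALSE)
      if (!is.null(hp$mtry)) args$mtry <- hp$mtry
      do.call(ranger::ranger, args)
    },
    LDA = {
      # MASS::lda refuses variables with zero pooled within-group variance.
      # Truly constant columns (equal class means too) carry no information
      # and are dropped; columns that are constant within classes but differ
      # between them are maximally discriminative and are kept with a tiny
      # seeded jitter so the within-group scatter is invertible.
      n0 <- sum(y == 0L); n1 <- sum(y == 1L)
      m0 <- colMeans(X[y == 0L, , drop = FALSE])
      m1 <- colMeans(X[y == 1L, , drop = FALSE])
      v0 <- apply(X[y == 0L, , drop = FALSE], 2, stats::var)
      v1 <- apply(X[y == 1L, , drop = FALSE], 2, stats::var)
      pw <- ((n0 - 1) * v0 + (n1 - 1) * v1) / max(n0 + n1 - 2L, 1L)
      keep <- which(pw > 0 | abs(m0 - m1) > 0)
      if (!length(keep)) stop("all features are constant within classes")
      Xk <- X[, keep, drop = FALSE]
      deg <- which(pw[keep] == 0)
      if (length(deg)) {
        set.seed(spec$seed)
        Xk[, deg] <- Xk[, deg] +
          stats::rnorm(nrow(Xk) * length(deg), sd = 1e-3)
      }
      f <- suppressWarnings(
        MASS::lda(Xk, grouping = factor(y, levels = 0:1)))
      list(fit = f, keep = keep)
    },
    MLP = {
      set.seed(spec$seed)
      nnet::nnet(x = X, y = matrix(y, ncol = 1L), size = hp$size,
                 decay = hp$decay, maxit = hp$maxit, entropy = TRUE,
                 MaxNWts = 1e6, trace = FALSE)
    },
    SGD = .sgdFit(X, y, learningRate = hp$learningRate, lambda = hp$lambda,
                  epochs = hp$epochs, seed = spec$seed),
    XGB = {
      set.seed(spec$seed)
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1L,
                      seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    }
  )
  structure(list(algorithm = spec$algorithm, hyperparameters = hp,
                 seed = spec$seed, fit = fit,
                 featureNames = colnames(X)),
            class = "i6maBaseFit")
}

# L2-regularized logistic regression trained by per-sample stochastic
# gradient descent with an inverse-scaling learning-rate schedule.
.sgdFit <- function(X, y, learningRate, lambda, epochs, seed) {
  set.seed(seed)
  n <- nrow(X)
  w <- numeric(ncol(X))
  b <- 0
  t <- 0L
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      eta <- learningRate / (1 + learningRate * lambda * t)
      xi <- X[i, ]
      z <- sum(w * xi) + b
      g <- 1 / (1 + exp(-z)) - y[i]
      w <- w * (1 - eta * lambda) - eta * g * xi
      b <- b - eta * g
    }
  }
  list(w = w, b = b)
}

#' Predict hard 0/1 votes from a fitted base classifier
#'
#' @param fit An `"i6maBaseFit"` from [trainBase()].
#' @param X Feature matrix with the same columns as at training time.
#' @return Integer vector of 0/1 votes, one per row.
#' @export
predictBase <- function(fit, X) {
  stopifnot(inherits(fit, "i6maBaseFit"))
  X <- .ensureColnames(X)
  if (!is.null(fit$featureNames) && ncol(X) != length(fit$featureNames))
    stop("feature dimension mismatch: model expects ",
         length(fit$featureNames), " features, got ", ncol(X))
  switch(fit$algorithm,
    RF = as.integer(as.character(
      stats::predict(fit$fit, data = as.data.frame(X),
                     num.threads = 1L)$predictions)),
    LDA = as.integer(as.character(
      stats::predict(fit$fit$fit, X[, fit$fit$keep, drop = FALSE])$class)),
    MLP = as.integer(stats::predict(fit$fit, X) >= 0.5),
    SGD = as.integer(as.vector(X %*% fit$fit$w) + fit$fit$b >= 0),
    XGB = as.integer(stats::predict(fit$fit, xgboost::xgb.DMatrix(X)) >= 0.5)
  )
}

#' Majority vote over base-classifier labels
#'
#' Returns 1 iff at least `threshold` of the votes are 1. With five voters
#' and the default threshold of 3 this is the strict-majority rule (no tie is
#' possible). For an even number of voters under the default threshold, an
#' exact split maps to 0 (non-6mA) with a warning.
#'
#' @param votes Vector of 0/1 votes, or a matrix with one column per voter
#'   (rows are decided independently).
#' @param threshold Integer number of positive votes required; default
#'   `floor(nVoters/2) + 1`.
#' @return Integer 0/1 decision(s).
#' @examples
#' majorityVote(c(1, 1, 1, 0, 0))   # 1
#' majorityVote(c(1, 1, 0, 0, 0))   # 0
#' @export
majorityVote <- function(votes, threshold = NULL) {
  if (is.matrix(votes)) {
    nv <- ncol(votes)
    if (!nv) stop("empty vote matrix")
    threshold <- threshold %||% (nv %/% 2L + 1L)
    .checkThreshold(threshold, nv)
    s <- rowSums(votes)
    if (nv %% 2L == 0L && threshold == nv %/% 2L + 1L && any(s == nv / 2L))
      warning("tied votes in an even ensemble map to 0 (non-6mA)")
    return(as.integer(s >= threshold))
  }
  if (!length(votes)) stop("empty vote list")
  stopifnot(all(votes %in% c(0L, 1L)))
  nv <- length(votes)
  threshold <- threshold %||% (nv %/% 2L + 1L)
  .checkThreshold(threshold, nv)
  s <- sum(votes)
  if (nv %% 2L == 0L && threshold == nv %/% 2L + 1L && s == nv / 2L)
    warning("tied votes in an even ensemble map to 0 (non-6mA)")
  as.integer(s >= threshold)
}

.checkThreshold <- function(threshold, nv) {
  if (threshold < 1L || threshold > nv)
    stop("threshold must lie in [1, ", nv, "]")
}

#' Exhaustive grid search by stratified cross-validated accuracy
#'
#' Evaluates every combination in the Cartesian product of `grid` by
#' stratified k-fold cross-validation accuracy and returns the best, with
#' deterministic tie-breaking (first combination in enumeration order wins).
#' Combinations that fail to train are recorded and skipped; if all fail, an
#' error is raised.
#'
#' @param spec A [baseSpec()]; grid values override its hyperparameters.
#' @param grid Named list mapping hyperparameter names to value vectors.
#' @param X,y As in [trainBase()].
#' @param folds Number of CV folds (>= 2, default 5).
#' @param seed Seed for the fold assignment.
#' @return List of class `"gridSearchResult"`: `algorithm`, `results` (one
#'   row per combination with its CV accuracy), `best` (row index) and
#'   `bestHyperparameters`.
#' @export
gridSearch <- function(spec, grid, X, y, folds = 5L, seed = 1L) {
  stopifnot(inherits(spec, "baseSpec"), folds >= 2L)
  if (!length(grid)) stop("grid must be non-empty")
  y <- as.integer(y)
  X <- .ensureColnames(X)
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  foldId <- .stratifiedFolds(y, folds, seed)
  acc <- rep(NA_real_, nrow(combos))
  failures <- character(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    hp <- as.list(combos[ci, , drop = FALSE])
    names(hp) <- names(combos)
    sp <- baseSpec(spec$algorithm,
                   utils::modifyList(spec$hyperparameters, hp),
                   seed = spec$seed)
    res <- tryCatch({
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- foldId != f
        fit <- trainBase(sp, X[tr, , drop = FALSE], y[tr])
        pred <- predictBase(fit, X[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      correct / length(y)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[ci] <- conditionMessage(res)
    else acc[ci] <- res
  }
  if (all(is.na(acc)))
    stop("every grid combination failed to train; first error: ",
         failures[which(nzchar(failures))[1L]])
  best <- which.max(acc)  # first maximum in enumeration order
  bestHp <- as.list(combos[best, , drop = FALSE])
  names(bestHp) <- names(combos)
  structure(list(algorithm = spec$algorithm,
                 results = cbind(combos, cvAccuracy = acc,
                                 error = failures),
                 best = best,
                 bestHyperparameters = bestHp),
            class = "gridSearchResult")
}

# fold assignment: within each class, shuffled round-robin -> fold sizes
# differ by at most one and both classes appear in every fold
.stratifiedFolds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  foldId <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    foldId[ix] <- rep_len(seq_len(k), length(ix))
  }
  foldId
}

#' Train the five-learner majority-voting ensemble
#'
#' Encodes the training windows once, optionally grid-searches each
#' algorithm's hyperparameters (stratified CV within the training data),
#' fits all five base classifiers on the full training matrix and returns
#' the assembled [I6maVoteModel-class].
#'
#' @param train A cleaned [WindowSet-class] containing both classes.
#' @param encoder Encoder specification as in [encodeWindows()] (default
#'   `"ONEHOT2"`, the method's standard choice).
#' @param specs Optional list of five [baseSpec()]s (one per algorithm, any
#'   order); defaults to the five algorithms with default hyperparameters
#'   and seeds derived from `seed`.
#' @param grids Optional named list of per-algorithm grids as in
#'   [defaultGrids()]; when supplied, each named algorithm is tuned by
#'   [gridSearch()] before the final fit.
#' @param folds CV folds for grid search.
#' @param voteThreshold Positive votes required to call a window 6mA
#'   (default 3 of 5).
#' @param seed Integer master seed.
#' @inheritParams encodeFused
#' @return An [I6maVoteModel-class].
#' @examples
#' \donttest{
#' ws <- simulateWindows(150, 150, defaultEnrichmentProfile(strength = 1),
#'                       seed = 1)
#' model <- trainEnsemble(ws, seed = 1)
#' }
#' @export
trainEnsemble <- function(train, encoder = "ONEHOT2", specs = NULL,
                          grids = NULL, folds = 5L, voteThreshold = 3L,
                          seed = 1L,
                          dinucleotideTable = NULL, trinucleotideTable = NULL) {
  stopifnot(is(train, "WindowSet"))
  encoder <- toupper(encoder)
  y <- windowLabels(train)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  X <- encodeWindows(train, encoder, dinucleotideTable, trinucleotideTable)
  if (is.null(specs))
    specs <- lapply(seq_along(.ALGORITHMS), function(i)
      baseSpec(.ALGORITHMS[i], seed = as.integer(seed) + i))
  algs <- vapply(specs, function(s) s$algorithm, character(1))
  if (!setequal(algs, .ALGORITHMS) || length(algs) != 5L)
    stop("specs must cover exactly the five algorithms: ",
         paste(.ALGORITHMS, collapse = ", "))
  specs <- specs[match(.ALGORITHMS, algs)]

  gridResults <- list()
  if (!is.null(grids)) {
    for (i in seq_along(specs)) {
      g <- grids[[specs[[i]]$algorithm]]
      if (is.null(g) || !length(g)) next
      gs <- gridSearch(specs[[i]], g, X, y, folds = folds, seed = seed)
      gridResults[[specs[[i]]$algorithm]] <- gs
      specs[[i]] <- baseSpec(
        specs[[i]]$algorithm,
        utils::modifyList(specs[[i]]$hyperparameters, gs$bestHyperparameters),
        seed = specs[[i]]$seed)
    }
  }

  fits <- lapply(specs, function(s) trainBase(s, X, y))
  names(fits) <- .ALGORITHMS
  pt <- if ("DPCP" %in% encoder) dinucleotideTable %||% defaultPropertyTable(2L)
        else if ("TPCP" %in% encoder) trinucleotideTable %||% defaultPropertyTable(3L)
        else NULL
  new("I6maVoteModel",
      baseModels = fits,
      algorithms = .ALGORITHMS,
      encoder = encoder,
      propertyTable = pt,
      voteThreshold = as.integer(voteThreshold),
      windowLength = as.integer(unique(width(windowSequences(train)))),
      metadata = list(trainedOn = datasetName(train),
                      seed = as.integer(seed),
                      nTrain = length(train),
                      classCounts = as.list(table(y)),
                      gridResults = gridResults,
                      package = "i6maVote",
                      version = as.character(utils::packageVersion("i6maVote")),
                      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

.coerceQuery <- function(newdata) {
  if (is(newdata, "WindowSet")) return(newdata)
  if (is(newdata, "XStringSet") || is.character(newdata)) {
    nm <- names(newdata)
    s <- as.character(newdata)  # drops names
    names(s) <- if (is.null(nm)) paste0("q", seq_along(s)) else nm
    return(WindowSet(s, labels = 0L, datasetName = "query"))
  }
  stop("newdata must be a WindowSet, DNAStringSet or character vector")
}

#' Predict 6mA labels for query windows
#'
#' Re-encodes the query windows with the model's recorded encoder, collects
#' the five hard base-classifier votes and combines them by majority voting.
#' Every query must have the model's window length and an "A" at the central
#' position; offending window ids are listed in the error.
#'
#' @param object An [I6maVoteModel-class].
#' @param newdata A [WindowSet-class], [Biostrings::DNAStringSet] or
#'   character vector of windows.
#' @param ... Ignored.
#' @return A `data.frame` with columns `id`, `ensemble_label` and one
#'   `vote_<algorithm>` column per base classifier; `ensemble_label` always
#'   equals [majorityVote()] of the vote columns at the model's threshold.
#' @export
setMethod("predict", "I6maVoteModel", function(object, newdata, ...) {
  ws <- .coerceQuery(newdata)
  if (!length(ws)) stop("no query windows")
  w <- width(windowSequences(ws))
  badLen <- w != object@windowLength
  center <- (object@windowLength + 1L) %/% 2L
  seqs <- as.character(windowSequences(ws))
  badCenter <- !badLen & substring(seqs, center, center) != "A"
  if (any(badLen) || any(badCenter)) {
    offenders <- unique(c(windowIds(ws)[badLen], windowIds(ws)[badCenter]))
    stop(sprintf(
      "%d window(s) are not valid %d-nt adenine-centered windows: %s",
      length(offenders), object@windowLength,
      paste(utils::head(offenders, 10L), collapse = ", ")))
  }
  di <- tri <- NULL
  if (!is.null(object@propertyTable)) {
    if (kmerSize(object@propertyTable) == 2L) di <- object@propertyTable
    else tri <- object@propertyTable
  }
  X <- encodeWindows(ws, object@encoder, di, tri)
  votes <- vapply(object@baseModels, function(f) predictBase(f, X),
                  integer(length(ws)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L,
                                           dimnames = list(NULL, object@algorithms))
  lab <- majorityVote(votes, object@voteThreshold)
  out <- data.frame(id = windowIds(ws), ensemble_label = lab,
                    stringsAsFactors = FALSE)
  for (a in object@algorithms) out[[paste0("vote_", a)]] <- votes[, a]
  out
})

#' Write ensemble predictions as TSV
#'
#' @param predictions The data.frame returned by
#'   [predict,I6maVoteModel-method].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted ensemble
#'
#' The on-disk container is a single RDS archive bundling the five fitted
#' base learners (the xgboost booster is converted to its raw byte
#' serialization so the archive survives package/version changes), the
#' encoder specification, any property table, the vote threshold and the
#' training provenance plus a version stamp. `loadEnsemble()` restores a
#' model whose predictions are identical to the pre-save model's.
#'
#' @param model An [I6maVoteModel-class].
#' @param path Archive path (conventionally `.rds`).
#' @return `saveEnsemble()`: invisibly, the path. `loadEnsemble()`: the
#'   restored [I6maVoteModel-class].
#' @export
saveEnsemble <- function(model, path) {
  stopifnot(is(model, "I6maVoteModel"))
  bm <- model@baseModels
  xgb <- bm$XGB
  xgb$fit <- xgboost::xgb.save.raw(xgb$fit)
  xgb$serialized <- TRUE
  bm$XGB <- xgb
  payload <- list(format = "i6maVote-model", formatVersion = 1L,
                  baseModels = bm, algorithms = model@algorithms,
                  encoder = model@encoder,
                  propertyTable = model@propertyTable,
                  voteThreshold = model@voteThreshold,
                  windowLength = model@windowLength,
                  metadata = model@metadata)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "i6maVote-model"))
    stop(path, " is not an i6maVote model archive")
  bm <- payload$baseModels
  if (isTRUE(bm$XGB$serialized)) {
    bm$XGB$fit <- xgboost::xgb.load.raw(bm$XGB$fit)
    bm$XGB$serialized <- NULL
  }
  new("I6maVoteModel",
      baseModels = bm, algorithms = payload$algorithms,
      encoder = payload$encoder, propertyTable = payload$propertyTable,
      voteThreshold = payload$voteThreshold,
      windowLength = payload$windowLength, metadata = payload$metadata)
}
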