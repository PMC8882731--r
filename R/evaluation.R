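# Performance metrics (ACC, MCC, SN, SP) and cross-validation machinery.

#' Confusion counts from true and predicted labels
#'
#' TP/TN are correctly predicted 6mA / non-6mA windows; FP/FN are
#' incorrectly predicted non-6mA / 6mA windows.
#'
#' @param yTrue,yPred Equal-length vectors of 0/1 labels.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred) || !length(yTrue))
    stop("yTrue and yPred must be non-empty and of equal length")
  stopifnot(all(yTrue %in% 0:1), all(yPred %in% 0:1))
  c(TP = sum(yTrue == 1L & yPred == 1L),
    TN = sum(yTrue == 0L & yPred == 0L),
    FP = sum(yTrue == 0L & yPred == 1L),
    FN = sum(yTrue == 1L & yPred == 0L))
}

#' Accuracy, Matthews correlation, sensitivity, specificity
#'
#' Computes the four standard binary-classification metrics from confusion
#' counts:
#' \deqn{ACC = (TP + TN) / (TP + FN + TN + FP)}
#' \deqn{MCC = (TP \cdot TN - FN \cdot FP) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' \deqn{SN = TP / (TP + FN), \quad SP = TN / (TN + FP)}
#' When the MCC denominator is 0 the uninformative value 0 is returned; when
#' a class is absent, the corresponding rate (SN or SP) is `NA`.
#'
#' @param cm Named vector with elements TP, TN, FP, FN (as returned by
#'   [confusionCounts()]).
#' @return Named numeric vector `c(ACC, MCC, SN, SP)`.
#' @examples
#' computeMetrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
#' @export
computeMetrics <- function(cm) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(cm)))
  tp <- as.numeric(cm[["TP"]]); tn <- as.numeric(cm[["TN"]])
  fp <- as.numeric(cm[["FP"]]); fn <- as.numeric(cm[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / den
  sn <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  c(ACC = acc, MCC = mcc, SN = sn, SP = sp)
}

#' Stratified k-fold cross-validation of one encoder/classifier pair
#'
#' Splits the windows into stratified folds (deterministic under `seed`; each
#' window is tested exactly once and fold sizes differ by at most one per
#' class), trains the base classifier on each training part and evaluates on
#' the held-out fold.
#'
#' @param data A [WindowSet-class] with both classes (each with at least
#'   `folds` members).
#' @param encoder Encoder specification as in [encodeWindows()].
#' @param spec A [baseSpec()].
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @inheritParams encodeFused
#' @return List of class `"cvResult"`: `perFold` (data.frame of fold-wise
#'   ACC/MCC/SN/SP), `mean` (named vector of fold means), and `metadata`.
#' @export
kfoldCv <- function(data, encoder, spec, folds = 5L, seed = 1L,
                    dinucleotideTable = NULL, trinucleotideTable = NULL) {
  stopifnot(is(data, "WindowSet"), folds >= 2L)
  y <- windowLabels(data)
  if (any(table(factor(y, levels = 0:1)) < folds))
    stop("each class needs at least `folds` samples")
  X <- encodeWindows(data, encoder, dinucleotideTable, trinucleotideTable)
  foldId <- .stratifiedFolds(y, folds, seed)
  perFold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    tr <- foldId != f
    fit <- trainBase(spec, X[tr, , drop = FALSE], y[tr])
    pred <- predictBase(fit, X[!tr, , drop = FALSE])
    m <- computeMetrics(confusionCounts(y[!tr], pred))
    data.frame(fold = f, t(m))
  }))
  structure(list(perFold = perFold,
                 mean = colMeans(perFold[, c("ACC", "MCC", "SN", "SP")]),
                 metadata = list(encoder = paste(toupper(encoder),
                                                 collapse = "+"),
                                 algorithm = spec$algorithm,
                                 folds = folds, seed = as.integer(seed),
                                 n = length(data))),
            class = "cvResult")
}

#' Cross-validated sweep over encoder and classifier combinations
#'
#' Runs [kfoldCv()] for every (encoder, classifier) cell with the same folds
#' and seed, producing the data behind an encoder-comparison table: one row
#' per cell with the mean CV metrics.
#'
#' @param data A [WindowSet-class].
#' @param encoders Character vector of encoder names.
#' @param specs List of [baseSpec()]s (one per classifier to evaluate);
#'   defaults to the five algorithms with default hyperparameters.
#' @param folds,seed As in [kfoldCv()].
#' @inheritParams encodeFused
#' @return data.frame with columns `encoder`, `algorithm`, `ACC`, `MCC`,
#'   `SN`, `SP`.
#' @export
sweepEncoders <- function(data, encoders, specs = NULL, folds = 5L, seed = 1L,
                          dinucleotideTable = NULL, trinucleotideTable = NULL) {
  stopifnot(length(encoders) >= 1L)
  if (is.null(specs))
    specs <- lapply(seq_along(.ALGORITHMS), function(i)
      baseSpec(.ALGORITHMS[i], seed = as.integer(seed) + i))
  if (!length(specs)) stop("specs must be non-empty")
  rows <- list()
  for (enc in encoders) {
    for (sp in specs) {
      cv <- kfoldCv(data, enc, sp, folds = folds, seed = seed,
                    dinucleotideTable = dinucleotideTable,
                    trinucleotideTable = trinucleotideTable)
      rows[[length(rows) + 1L]] <-
        data.frame(encoder = paste(toupper(enc), collapse = "+"),
                   algorithm = sp$algorithm, t(cv$mean))
    }
  }
  do.call(rbind, rows)
}

#' Format a sweep as a classifier-by-encoder table
#'
#' Reshapes the long [sweepEncoders()] output into the conventional report
#' layout: rows are classifier-metric pairs, columns are encoders, values to
#' three decimals.
#'
#' @param sweepResult The data.frame from [sweepEncoders()].
#' @return A character-matrix-backed data.frame ready for printing or TSV
#'   export.
#' @export
formatSweepTable <- function(sweepResult) {
  metrics <- c("ACC", "MCC", "SN", "SP")
  encoders <- unique(sweepResult$encoder)
  algs <- unique(sweepResult$algorithm)
  rows <- list()
  for (a in algs) for (m in metrics) {
    vals <- vapply(encoders, function(e) {
      v <- sweepResult[sweepResult$encoder == e & sweepResult$algorithm == a, m]
      sprintf("%.3f", v)
    }, character(1))
    rows[[paste(a, m)]] <- c(classifier = a, metric = m, vals)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
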