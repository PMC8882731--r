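#' @import methods
#' @importFrom Biostrings DNAStringSet BStringSet readBStringSet writeXStringSet width
#' @importFrom stats predict rnorm runif var setNames
#' @importFrom MASS lda
#' @importFrom nnet nnet
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train xgb.DMatrix xgb.save.raw xgb.load.raw
#' @importFrom utils read.delim write.table head
NULL

#' WindowSet: labeled fixed-length DNA windows
#'
#' A `WindowSet` holds a collection of DNA windows (as a
#' [Biostrings::DNAStringSet] over the alphabet A/C/G/T/N) together with a
#' parallel vector of binary labels (1 = the central adenine carries an
#' N6-methyl mark, 0 = it does not) and a free-text dataset name. Model-ready
#' windows are 41 nt long with an "A" at the central position; that stronger
#' invariant is enforced at prediction time, not at construction, so that
#' uncleaned user data can be represented and then passed through
#' [cleanWindows()].
#'
#' @slot sequences A [Biostrings::DNAStringSet]; names are window identifiers.
#' @slot labels Integer vector of 0/1, parallel to `sequences`.
#' @slot datasetName Length-one character, free-text provenance.
#'
#' @seealso [readFastaWindows()], [cleanWindows()], [splitWindows()],
#'   [simulateWindows()]
#' @export
setClass("WindowSet",
  representation(
    sequences = "DNAStringSet",
    labels = "integer",
    datasetName = "character"
  )
)

setValidity("WindowSet", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "number of sequences and labels must match")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(object@datasetName) != 1L)
    msg <- c(msg, "datasetName must be a single string")
  bad <- grepl("[^ACGTN]", as.character(object@sequences))
  if (any(bad))
    msg <- c(msg, sprintf("%d sequence(s) contain characters outside {A,C,G,T,N}",
                          sum(bad)))
  if (length(msg)) msg else TRUE
})

#' Construct a WindowSet
#'
#' @param sequences A [Biostrings::DNAStringSet], or a named character vector
#'   of sequences over A/C/G/T/N.
#' @param labels Vector coercible to integer 0/1, one per sequence; a single
#'   value is recycled.
#' @param datasetName Free-text name recorded as provenance.
#' @return A [WindowSet-class] object.
#' @examples
#' ws <- WindowSet(c(w1 = "ACGTA", w2 = "AANTA"), labels = c(1, 0))
#' windowLabels(ws)
#' @export
WindowSet <- function(sequences, labels, datasetName = "unnamed") {
  if (!is(sequences, "DNAStringSet")) {
    nm <- names(sequences)  # as.character/toupper may strip names
    seqs <- toupper(as.character(sequences))
    names(seqs) <- if (is.null(nm)) paste0("w", seq_along(seqs)) else nm
    sequences <- DNAStringSet(seqs)
  }
  if (length(labels) == 1L) labels <- rep(labels, length(sequences))
  new("WindowSet",
      sequences = sequences,
      labels = as.integer(labels),
      datasetName = as.character(datasetName))
}

#' @describeIn WindowSet-class number of windows
#' @param x,object A `WindowSet`.
#' @export
setMethod("length", "WindowSet", function(x) length(x@sequences))

#' Accessors for WindowSet
#'
#' `windowSequences()` returns the underlying [Biostrings::DNAStringSet],
#' `windowLabels()` the integer 0/1 label vector, `windowIds()` the window
#' identifiers and `datasetName()` the provenance string.
#'
#' @param x A [WindowSet-class].
#' @return See the individual descriptions.
#' @export
windowSequences <- function(x) {
  stopifnot(is(x, "WindowSet"))
  x@sequences
}

#' @rdname windowSequences
#' @export
windowLabels <- function(x) {
  stopifnot(is(x, "WindowSet"))
  x@labels
}

#' @rdname windowSequences
#' @export
windowIds <- function(x) {
  stopifnot(is(x, "WindowSet"))
  names(x@sequences)
}

#' @rdname windowSequences
#' @export
datasetName <- function(x) {
  stopifnot(is(x, "WindowSet"))
  x@datasetName
}

#' @describeIn WindowSet-class subset windows by index or logical mask
#' @param i Index vector.
#' @param j,...,drop Ignored; present for generic compatibility.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = TRUE) {
  new("WindowSet",
      sequences = x@sequences[i],
      labels = x@labels[i],
      datasetName = x@datasetName)
})

#' @describeIn WindowSet-class brief summary of contents
#' @export
setMethod("show", "WindowSet", function(object) {
  n <- length(object)
  wid <- if (n) paste(range(width(object@sequences)), collapse = "-") else "NA"
  cat(sprintf("WindowSet \"%s\": %d windows (%d positive, %d negative), width %s nt\n",
              object@datasetName, n, sum(object@labels == 1L),
              sum(object@labels == 0L), wid))
})

#' Combine two WindowSets
#'
#' Concatenates windows and labels; the dataset name of the first argument is
#' kept.
#' @param x,y [WindowSet-class] objects.
#' @return A combined [WindowSet-class].
#' @export
bindWindowSets <- function(x, y) {
  new("WindowSet",
      sequences = c(windowSequences(x), windowSequences(y)),
      labels = c(windowLabels(x), windowLabels(y)),
      datasetName = datasetName(x))
}

#' PropertyTable: k-mer physicochemical property values
#'
#' A complete k-mer-by-property numeric matrix feeding the physicochemical
#' encoders ([encodePCP()]): for dinucleotides (`kmerSize = 2`) all 25 tokens
#' over A/C/G/T/N, for trinucleotides (`kmerSize = 3`) all 125 tokens. Row
#' order follows the package codebook (lexicographic with symbol order
#' A < C < G < T < N, see [kmerCodebook()]).
#'
#' @slot kmerSize Integer, 2 or 3.
#' @slot values Numeric matrix; rownames are the k-mer tokens in codebook
#'   order, colnames the property names. No missing cells.
#'
#' @seealso [readPropertyTable()], [defaultPropertyTable()], [encodePCP()]
#' @export
setClass("PropertyTable",
  representation(kmerSize = "integer", values = "matrix")
)

setValidity("PropertyTable", function(object) {
  msg <- character()
  k <- object@kmerSize
  if (length(k) != 1L || !k %in% c(2L, 3L))
    msg <- c(msg, "kmerSize must be 2 or 3")
  expected <- kmerCodebook(k)
  if (!identical(rownames(object@values), expected))
    msg <- c(msg, sprintf("rownames must be the %d k-mers in codebook order",
                          length(expected)))
  if (anyNA(object@values))
    msg <- c(msg, "property values must not contain missing cells")
  if (!is.numeric(object@values) || ncol(object@values) < 1L)
    msg <- c(msg, "values must be a numeric matrix with >= 1 property column")
  if (length(msg)) msg else TRUE
})

#' @describeIn PropertyTable-class brief summary
#' @param object A `PropertyTable`.
#' @export
setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable: %d-mers, %d tokens x %d properties\n",
              object@kmerSize, nrow(object@values), ncol(object@values)))
})

#' Accessors for PropertyTable
#' @param x A [PropertyTable-class].
#' @return `propertyValues()` the numeric matrix; `kmerSize()` the k-mer size.
#' @export
propertyValues <- function(x) {
  stopifnot(is(x, "PropertyTable"))
  x@values
}

#' @rdname propertyValues
#' @export
kmerSize <- function(x) {
  stopifnot(is(x, "PropertyTable"))
  x@kmerSize
}

#' I6maVoteModel: fitted five-learner voting ensemble
#'
#' The trained classifier: five fitted base learners (random forest, linear
#' discriminant analysis, multi-layer perceptron, SGD logistic regression,
#' extreme gradient boosting), the encoder specification used to turn windows
#' into features (so prediction re-encodes identically), the vote threshold
#' (default 3 of 5: a window is called 6mA-positive when at least three base
#' classifiers vote positive), and training provenance.
#'
#' @slot baseModels Named list of fitted base classifiers (class
#'   `i6maBaseFit`), in training order.
#' @slot algorithms Character vector of the base algorithm names.
#' @slot encoder Character encoder specification (see [encodeWindows()]).
#' @slot propertyTable A [PropertyTable-class] or `NULL`, recorded when the
#'   encoder needs one.
#' @slot voteThreshold Integer number of positive votes required.
#' @slot windowLength Integer expected window width in nt.
#' @slot metadata List: dataset name, seed, grid-search results, timestamps.
#'
#' @seealso [trainEnsemble()], [predict,I6maVoteModel-method],
#'   [saveEnsemble()], [loadEnsemble()]
#' @export
setClass("I6maVoteModel",
  representation(
    baseModels = "list",
    algorithms = "character",
    encoder = "character",
    propertyTable = "ANY",
    voteThreshold = "integer",
    windowLength = "integer",
    metadata = "list"
  )
)

setValidity("I6maVoteModel", function(object) {
  msg <- character()
  if (length(object@baseModels) != length(object@algorithms))
    msg <- c(msg, "one fitted model per algorithm is required")
  if (object@voteThreshold < 1L ||
      object@voteThreshold > length(object@baseModels))
    msg <- c(msg, "voteThreshold must lie in [1, number of base models]")
  if (object@windowLength < 2L)
    msg <- c(msg, "windowLength must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn I6maVoteModel-class summary of the ensemble
#' @param object An `I6maVoteModel`.
#' @export
setMethod("show", "I6maVoteModel", function(object) {
  cat(sprintf("I6maVoteModel: %d base learners [%s]\n",
              length(object@baseModels), paste(object@algorithms, collapse = ", ")))
  cat(sprintf("  encoder: %s | window length: %d nt | vote threshold: %d/%d\n",
              paste(object@encoder, collapse = "+"), object@windowLength,
              object@voteThreshold, length(object@baseModels)))
  if (!is.null(object@metadata$trainedOn))
    cat(sprintf("  trained on: %s (seed %s)\n", object@metadata$trainedOn,
                as.character(object@metadata$seed)))
})

#' Accessors for I6maVoteModel
#' @param x An [I6maVoteModel-class].
#' @return `baseModels()` the list of fitted base learners; `modelEncoder()`
#'   the encoder specification; `voteThreshold()` the integer vote cutoff;
#'   `modelMetadata()` the provenance list.
#' @export
baseModels <- function(x) {
  stopifnot(is(x, "I6maVoteModel"))
  x@baseModels
}

#' @rdname baseModels
#' @export
modelEncoder <- function(x) {
  stopifnot(is(x, "I6maVoteModel"))
  x@encoder
}

#' @rdname baseModels
#' @export
voteThreshold <- function(x) {
  stopifnot(is(x, "I6maVoteModel"))
  x@voteThreshold
}

#' @rdname baseModels
#' @export
modelMetadata <- function(x) {
  stopifnot(is(x, "I6maVoteModel"))
  x@metadata
}
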