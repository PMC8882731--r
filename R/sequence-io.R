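# FASTA input/output, normalization, dataset cleaning and splitting.

#' Normalize a DNA sequence to the A/C/G/T/N alphabet
#'
#' Uppercases and maps every character outside {A,C,G,T} — lowercase
#' ambiguity codes, U, gaps, anything else — to "N", the unidentified
#' nucleotide. The map is a pure character substitution: applying it twice
#' equals applying it once.
#'
#' @param x Character vector of sequences.
#' @return Character vector with attribute `"nReplaced"`, the total number of
#'   characters mapped to N.
#' @examples
#' normalizeSequence("acgru")   # "ACGNN"
#' @export
normalizeSequence <- function(x) {
  up <- toupper(x)
  out <- gsub("[^ACGT]", "N", up)
  nRep <- sum(nchar(gsub("[ACGTN]", "", up)))
  attr(out, "nReplaced") <- nRep
  out
}

#' Read labeled DNA windows from FASTA
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file, normalizes every
#' sequence with [normalizeSequence()] — warning with the count of characters
#' mapped to N — and applies one label to all records.
#'
#' @param path FASTA file path.
#' @param label 0 (non-6mA) or 1 (6mA) applied to every record.
#' @param datasetName Provenance name; defaults to the file name.
#' @return A [WindowSet-class].
#' @export
readFastaWindows <- function(path, label, datasetName = basename(path)) {
  stopifnot(label %in% c(0, 1))
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("no records in FASTA file: ", path)
  seqs <- normalizeSequence(as.character(raw))
  nRep <- attr(seqs, "nReplaced")
  if (nRep > 0)
    warning(sprintf("%d character(s) outside {A,C,G,T} mapped to N in %s",
                    nRep, path))
  ids <- sub("\\s.*$", "", names(raw))
  WindowSet(stats::setNames(as.character(seqs), ids), label, datasetName)
}

#' Write a WindowSet to FASTA
#'
#' One record per window, identifier preserved, in input order; reading the
#' file back with [readFastaWindows()] round-trips sequences and ids exactly.
#'
#' @param data A non-empty [WindowSet-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFastaWindows <- function(data, path) {
  stopifnot(is(data, "WindowSet"))
  if (!length(data)) stop("refusing to write an empty WindowSet")
  Biostrings::writeXStringSet(windowSequences(data), path)
  invisible(path)
}

.dedupKeepFirst <- function(ws) {
  keep <- !duplicated(as.character(windowSequences(ws)))
  list(set = ws[keep], removed = sum(!keep))
}

#' Clean positive/negative window sets
#'
#' Applies, in order: (1) drop windows whose length differs from `maxLen`
#' (windows longer than the model window are outside the model; shorter ones
#' are dropped too because every downstream encoder assumes one fixed
#' length); (2) within each label, deduplicate exact sequence strings,
#' keeping the first occurrence in file order; (3) remove any sequence
#' present in both cleaned sets from BOTH sets. Windows whose central
#' character is not "A" trigger a warning here (and a hard error at
#' prediction time). Cleaning is idempotent.
#'
#' @param positives,negatives Non-empty [WindowSet-class] objects.
#' @param maxLen Required window length in nt (default 41).
#' @return A list with elements `positives`, `negatives` (cleaned
#'   [WindowSet-class]s) and `report`, a per-label list of counts
#'   `input, removed_length, removed_duplicate, removed_overlap, output`
#'   (serializable with [writeCleaningReport()]).
#' @export
cleanWindows <- function(positives, negatives, maxLen = 41L) {
  stopifnot(is(positives, "WindowSet"), is(negatives, "WindowSet"))
  if (!length(positives) || !length(negatives))
    stop("both input sets must be non-empty")
  maxLen <- as.integer(maxLen)

  cleanOne <- function(ws) {
    input <- length(ws)
    okLen <- width(windowSequences(ws)) == maxLen
    ws <- ws[okLen]
    dd <- .dedupKeepFirst(ws)
    list(set = dd$set, input = input,
         removed_length = sum(!okLen), removed_duplicate = dd$removed)
  }
  p <- cleanOne(positives)
  n <- cleanOne(negatives)

  pSeq <- as.character(windowSequences(p$set))
  nSeq <- as.character(windowSequences(n$set))
  overlap <- intersect(pSeq, nSeq)
  pKeep <- !(pSeq %in% overlap)
  nKeep <- !(nSeq %in% overlap)
  pOut <- p$set[pKeep]
  nOut <- n$set[nKeep]
  if (!length(pOut) || !length(nOut))
    stop("cleaning left an empty ",
         if (!length(pOut)) "positive" else "negative", " set")

  center <- (maxLen + 1L) %/% 2L
  notA <- sum(substring(c(as.character(windowSequences(pOut)),
                          as.character(windowSequences(nOut))),
                        center, center) != "A")
  if (notA > 0)
    warning(sprintf("%d cleaned window(s) lack an 'A' at the central position; %s",
                    notA, "prediction will reject them"))

  report <- list(
    positive = list(input = p$input, removed_length = p$removed_length,
                    removed_duplicate = p$removed_duplicate,
                    removed_overlap = sum(!pKeep), output = length(pOut)),
    negative = list(input = n$input, removed_length = n$removed_length,
                    removed_duplicate = n$removed_duplicate,
                    removed_overlap = sum(!nKeep), output = length(nOut))
  )
  list(positives = pOut, negatives = nOut, report = report)
}

#' Serialize a cleaning report as JSON
#'
#' @param report The `report` element of a [cleanWindows()] result.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
writeCleaningReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Stratified random train/test split
#'
#' Splits a labeled dataset into disjoint train and test parts whose union is
#' the input. With `stratified = TRUE` (default) each label contributes
#' `round(n_label * trainFraction)` windows to the training part, so each
#' label's train share is within one sample of `trainFraction`. Deterministic
#' given `seed`.
#'
#' @param data A [WindowSet-class].
#' @param trainFraction Fraction in (0, 1) assigned to training (default 0.8).
#' @param seed Integer RNG seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @return List with [WindowSet-class] elements `train` and `test`.
#' @export
splitWindows <- function(data, trainFraction = 0.8, seed = 1L,
                         stratified = TRUE) {
  stopifnot(is(data, "WindowSet"),
            trainFraction > 0, trainFraction < 1)
  n <- length(data)
  labs <- windowLabels(data)
  if (stratified && any(table(factor(labs, levels = 0:1)) < 2L))
    stop("stratified split needs >= 2 samples of each label")
  set.seed(as.integer(seed))
  idxTrain <- if (stratified) {
    unlist(lapply(split(seq_len(n), labs), function(ix) {
      k <- round(length(ix) * trainFraction)
      k <- min(max(k, 1L), length(ix) - 1L)
      sample(ix, k)
    }), use.names = FALSE)
  } else {
    k <- round(n * trainFraction)
    if (k < 1L || k >= n) stop("trainFraction yields an empty partition")
    sample(seq_len(n), k)
  }
  idxTrain <- sort(idxTrain)
  if (!length(idxTrain) || length(idxTrain) == n)
    stop("trainFraction yields an empty partition")
  list(train = data[idxTrain], test = data[-idxTrain])
}
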