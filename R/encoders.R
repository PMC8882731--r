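# Feature encoders turning A/C/G/T/N windows into numeric vectors.
# Symbol order A < C < G < T < N fixes every codebook ordering below.

.ALPHABET <- c("A", "C", "G", "T", "N")

.ENCODERS <- c("AMNF", "ADNF", "DPCP", "TPCP", "ONEHOT1", "ONEHOT2")

#' k-mer codebook over the 5-letter DNA alphabet
#'
#' Enumerates all k-mers over {A,C,G,T,N} in lexicographic order with symbol
#' order A < C < G < T < N (AA, AC, AG, AT, AN, CA, ..., NT, NN for k = 2).
#' This ordering defines the one-hot index of each k-mer and the row order of
#' [PropertyTable-class] matrices.
#'
#' @param k k-mer size (>= 1).
#' @return Character vector of the `5^k` tokens in codebook order.
#' @examples
#' kmerCodebook(1)
#' head(kmerCodebook(2))
#' @export
kmerCodebook <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  grids <- rev(do.call(expand.grid,
                       c(rep(list(.ALPHABET), k),
                         list(stringsAsFactors = FALSE,
                              KEEP.OUT.ATTRS = FALSE))))
  # expand.grid varies the first factor fastest; reversing column order gives
  # the last sequence position fastest, i.e. true lexicographic order.
  do.call(paste0, grids)
}

.checkAlphabet <- function(s) {
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,N}; ",
         "normalize with readFastaWindows() or normalizeSequence() first")
  invisible(s)
}

.asSequence <- function(seq) {
  if (is(seq, "WindowSet")) {
    stopifnot(length(seq) == 1L)
    return(as.character(windowSequences(seq))[[1L]])
  }
  if (is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    return(as.character(seq)[[1L]])
  }
  as.character(seq)
}

#' Split a window into overlapping k-mers
#'
#' Returns the `L - k + 1` overlapping k-mers of a window in 5'-to-3' order
#' with step 1, e.g. `tokenize("ACGTNA", 2)` gives AC, CG, GT, TN, NA.
#'
#' @param seq A character sequence, single-element DNAStringSet, or
#'   single-window [WindowSet-class].
#' @param k k-mer size.
#' @return Character vector of k-mer tokens.
#' @examples
#' tokenize("ACGTNA", 2)
#' @export
tokenize <- function(seq, k) {
  s <- .asSequence(seq)
  k <- as.integer(k)
  L <- nchar(s)
  if (k < 1L) stop("k must be >= 1")
  if (L < k) stop(sprintf("window of length %d is shorter than k = %d", L, k))
  substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

.kmerIndex <- function(tokens, k) {
  # 1-based codebook index of each token; NA for malformed tokens
  m <- matrix(match(unlist(strsplit(tokens, "", fixed = TRUE)), .ALPHABET) - 1L,
              nrow = k)
  as.integer(colSums(m * 5L^((k - 1L):0)) + 1L)
}

#' Mononucleotide one-hot encoding (One-hot1)
#'
#' Each nucleotide becomes a 5-bit indicator over (A, C, G, T, N), and the
#' indicators are concatenated in sequence order: an L-nt window yields a
#' 5L-dimensional 0/1 vector with exactly L ones.
#'
#' @inheritParams tokenize
#' @return Numeric 0/1 vector of length `5 * L`.
#' @examples
#' encodeOneHot1("ACGTNA")
#' @export
encodeOneHot1 <- function(seq) {
  s <- .asSequence(seq)
  .checkAlphabet(s)
  idx <- .kmerIndex(tokenize(s, 1L), 1L)
  out <- numeric(5L * length(idx))
  out[(seq_along(idx) - 1L) * 5L + idx] <- 1
  out
}

#' Dinucleotide one-hot encoding (One-hot2)
#'
#' Each of the L-1 overlapping dinucleotides becomes a 25-bit indicator over
#' the dinucleotide codebook ([kmerCodebook]`(2)`: AA -> bit 1, AC -> bit 2,
#' ..., NN -> bit 25) and the indicators are concatenated in sequence order.
#' A 6-nt window yields 125 bits; a 41-nt window yields the model's standard
#' 1000-dimensional feature vector with exactly 40 ones.
#'
#' @inheritParams tokenize
#' @return Numeric 0/1 vector of length `25 * (L - 1)`.
#' @examples
#' length(encodeOneHot2("ACGTNA"))
#' @export
encodeOneHot2 <- function(seq) {
  s <- .asSequence(seq)
  .checkAlphabet(s)
  idx <- .kmerIndex(tokenize(s, 2L), 2L)
  out <- numeric(25L * length(idx))
  out[(seq_along(idx) - 1L) * 25L + idx] <- 1
  out
}

#' Accumulated mononucleotide frequency (AMNF)
#'
#' Element t is the frequency of the nucleotide at position t within the
#' prefix of length t: `AMNF("ACGTNA") = (1, 1/2, 1/3, 1/4, 1/5, 2/6)`.
#' "N" counts like any other symbol. The first element is always 1 and all
#' values lie in (0, 1].
#'
#' @inheritParams tokenize
#' @return Numeric vector of length L.
#' @examples
#' round(encodeAMNF("ACGTNA"), 2)
#' @export
encodeAMNF <- function(seq) {
  s <- .asSequence(seq)
  .checkAlphabet(s)
  if (!nchar(s)) stop("empty sequence")
  .accumulatedFrequency(tokenize(s, 1L))
}

#' Accumulated dinucleotide frequency (ADNF)
#'
#' Element t is the frequency of the t-th overlapping dinucleotide among the
#' first t dinucleotides: `ADNF("ACGTNA") = (1, 1/2, 1/3, 1/4, 1/5)`.
#'
#' @inheritParams tokenize
#' @return Numeric vector of length L - 1.
#' @examples
#' round(encodeADNF("ACGTNA"), 2)
#' @export
encodeADNF <- function(seq) {
  s <- .asSequence(seq)
  .checkAlphabet(s)
  if (nchar(s) < 2L) stop("ADNF needs a window of length >= 2")
  .accumulatedFrequency(tokenize(s, 2L))
}

.accumulatedFrequency <- function(tokens) {
  f <- factor(tokens, levels = unique(tokens))
  # running count of each token up to position t, divided by t
  running <- stats::ave(rep(1, length(tokens)), f, FUN = cumsum)
  running / seq_along(tokens)
}

#' Physicochemical property encoding (DPCP / TPCP)
#'
#' For every k-mer token i of the codebook and every property j of the table,
#' the output cell is `N_i * PC_ij`, where `N_i` is the count of token i among
#' the window's overlapping k-mers and `PC_ij` the tabulated property value.
#' Cells are flattened token-major (all properties of token 1, then token 2,
#' ...). With `kmerSize = 2` this is the dinucleotide descriptor DPCP
#' (dimension `25 * P`); with `kmerSize = 3` the trinucleotide descriptor
#' TPCP (dimension `125 * P`).
#'
#' @inheritParams tokenize
#' @param table A [PropertyTable-class].
#' @param normalizeCounts If `TRUE`, use relative k-mer frequencies
#'   `N_i / (L - k + 1)` instead of raw counts. Off by default: the
#'   descriptor is defined on raw counts.
#' @return Numeric vector of length `nrow(table) * ncol(table)`.
#' @examples
#' tab <- defaultPropertyTable(2)
#' length(encodePCP("ACGTNA", tab))
#' @export
encodePCP <- function(seq, table, normalizeCounts = FALSE) {
  stopifnot(is(table, "PropertyTable"))
  s <- .asSequence(seq)
  .checkAlphabet(s)
  k <- kmerSize(table)
  tokens <- tokenize(s, k)
  V <- propertyValues(table)
  missing <- setdiff(unique(tokens), rownames(V))
  if (length(missing))
    stop("token(s) missing from property table: ",
         paste(missing, collapse = ", "))
  counts <- table(factor(tokens, levels = rownames(V)))
  counts <- as.numeric(counts)
  if (normalizeCounts) counts <- counts / length(tokens)
  out <- as.vector(t(V * counts))  # token-major, property-minor
  names(out) <- as.vector(t(outer(rownames(V), colnames(V), paste, sep = ".")))
  out
}

#' Fused encoding by concatenation
#'
#' Concatenates the encodings of two or more encoders in the listed order,
#' with no rescaling. Fusing ONEHOT1 with ONEHOT2 on a 41-nt window gives a
#' 205 + 1000 = 1205-dimensional vector.
#'
#' @inheritParams tokenize
#' @param encoders Character vector of two or more encoder names from
#'   `r paste(c("AMNF","ADNF","DPCP","TPCP","ONEHOT1","ONEHOT2"), collapse=", ")`.
#' @param dinucleotideTable,trinucleotideTable [PropertyTable-class] objects
#'   used when DPCP / TPCP are among `encoders`; bundled defaults are used if
#'   omitted.
#' @return Numeric vector, the concatenation of the component encodings.
#' @examples
#' length(encodeFused("ACGTNA", c("AMNF", "ADNF")))
#' @export
encodeFused <- function(seq, encoders,
                        dinucleotideTable = NULL, trinucleotideTable = NULL) {
  if (length(encoders) < 2L) stop("fusion needs at least two encoders")
  unlist(lapply(encoders, function(e)
    .encodeOne(seq, e, dinucleotideTable, trinucleotideTable)),
    use.names = FALSE)
}

.encodeOne <- function(seq, encoder, dinucleotideTable = NULL,
                       trinucleotideTable = NULL) {
  encoder <- toupper(encoder)
  if (!encoder %in% .ENCODERS)
    stop("unknown encoder: ", encoder, " (expected one of ",
         paste(.ENCODERS, collapse = ", "), ")")
  switch(encoder,
    AMNF = encodeAMNF(seq),
    ADNF = encodeADNF(seq),
    ONEHOT1 = encodeOneHot1(seq),
    ONEHOT2 = encodeOneHot2(seq),
    DPCP = encodePCP(seq, dinucleotideTable %||% defaultPropertyTable(2L)),
    TPCP = encodePCP(seq, trinucleotideTable %||% defaultPropertyTable(3L))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode all windows of a WindowSet into a feature matrix
#'
#' Applies an encoder (or an ordered fusion of encoders) to every window,
#' preserving row order. All windows must share one length so the feature
#' space is well defined.
#'
#' @param data A [WindowSet-class].
#' @param encoder Character: a single encoder name, or a vector of >= 2 names
#'   which are fused by concatenation. See [encodeFused()].
#' @inheritParams encodeFused
#' @return Numeric matrix, one row per window (rownames = window ids), with
#'   attribute `"encoder"` recording the specification.
#' @examples
#' ws <- WindowSet(c(a = "ACGTA", b = "TTGAA"), labels = c(1, 0))
#' dim(encodeWindows(ws, "ONEHOT2"))
#' @export
encodeWindows <- function(data, encoder = "ONEHOT2",
                          dinucleotideTable = NULL, trinucleotideTable = NULL) {
  stopifnot(is(data, "WindowSet"))
  if (!length(data)) stop("empty WindowSet")
  w <- width(windowSequences(data))
  if (length(unique(w)) != 1L)
    stop("windows have heterogeneous lengths (", paste(unique(w), collapse = ", "),
         "); clean the dataset first")
  encoder <- toupper(encoder)
  seqs <- as.character(windowSequences(data))
  enc <- if (length(encoder) > 1L) {
    function(s) encodeFused(s, encoder, dinucleotideTable, trinucleotideTable)
  } else {
    function(s) .encodeOne(s, encoder, dinucleotideTable, trinucleotideTable)
  }
  X <- t(vapply(seqs, enc, enc(seqs[[1L]]), USE.NAMES = FALSE))
  rownames(X) <- windowIds(data)
  attr(X, "encoder") <- encoder
  X
}

#' Export a feature matrix with ids and labels as CSV
#'
#' Writes `id,label,f0,f1,...` for interoperability and debugging.
#'
#' @param data A [WindowSet-class].
#' @param X The matrix returned by [encodeWindows()] for `data`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeFeatureMatrix <- function(data, X, path) {
  stopifnot(is(data, "WindowSet"), nrow(X) == length(data))
  df <- data.frame(id = windowIds(data), label = windowLabels(data),
                   X, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("f", seq_len(ncol(X)) - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
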