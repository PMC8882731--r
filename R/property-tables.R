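# Physicochemical property tables for the DPCP/TPCP encoders.
#
# The tables are pluggable TSV inputs: header "token<TAB>prop1<TAB>...",
# one row per k-mer token over {A,C,G,T,N}. The bundled defaults
# (*_synthetic.tsv) carry SYNTHETIC standardized values — reproducible
# placeholder numbers, zero for every N-containing token — matching the
# published descriptor's shape (15 dinucleotide and 11 trinucleotide
# properties) so the machinery is fully exercised; swap in a literature
# table via readPropertyTable() for real-data work.

#' Construct a PropertyTable from a value matrix
#'
#' @param values Numeric matrix; rownames must be all `5^kmerSize` k-mer
#'   tokens (any order; rows are reordered to codebook order), colnames the
#'   property names.
#' @param kmerSize 2 (dinucleotides) or 3 (trinucleotides).
#' @return A [PropertyTable-class].
#' @examples
#' v <- matrix(0, 25, 1, dimnames = list(kmerCodebook(2), "P01"))
#' PropertyTable(v, 2)
#' @export
PropertyTable <- function(values, kmerSize) {
  kmerSize <- as.integer(kmerSize)
  tokens <- kmerCodebook(kmerSize)
  if (is.null(rownames(values)) || !setequal(rownames(values), tokens))
    stop("rownames(values) must be exactly the ", length(tokens),
         " k-mers over {A,C,G,T,N}")
  values <- values[tokens, , drop = FALSE]
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%02d", seq_len(ncol(values)))
  new("PropertyTable", kmerSize = kmerSize, values = values)
}

#' Read a property table from TSV
#'
#' Expected format: UTF-8 TSV with header `token<TAB>prop1<TAB>...` and one
#' row per k-mer token; the token set must exactly match the `5^k` k-mers
#' over {A,C,G,T,N} and no cell may be missing.
#'
#' @param path TSV file path.
#' @param kmerSize 2 or 3.
#' @return A [PropertyTable-class].
#' @export
readPropertyTable <- function(path, kmerSize) {
  # na.strings = "": the dinucleotide "NA" is a real token, not a missing cell
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  if (ncol(df) < 2L) stop("property TSV needs a token column plus >= 1 property")
  tokens <- toupper(as.character(df[[1L]]))
  if (anyDuplicated(tokens)) stop("duplicate tokens in ", path)
  v <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(v)) stop("non-numeric property values in ", path)
  rownames(v) <- tokens
  PropertyTable(v, kmerSize)
}

#' Bundled default property tables (synthetic values)
#'
#' Loads the package's bundled property table for dinucleotides (15
#' properties) or trinucleotides (11 properties). The values are synthetic
#' standardized placeholders (see the package vignette); N-containing tokens
#' are 0 throughout.
#'
#' @param kmerSize 2 or 3.
#' @return A [PropertyTable-class].
#' @export
defaultPropertyTable <- function(kmerSize) {
  kmerSize <- as.integer(kmerSize)
  stopifnot(kmerSize %in% c(2L, 3L))
  fn <- if (kmerSize == 2L) "dinucleotide_properties_synthetic.tsv"
        else "trinucleotide_properties_synthetic.tsv"
  path <- system.file("extdata", fn, package = "i6maVote", mustWork = TRUE)
  readPropertyTable(path, kmerSize)
}

#' Scale a property table by a constant
#'
#' Convenience for linearity checks and unit changes: multiplies every cell.
#'
#' @param table A [PropertyTable-class].
#' @param factor Scalar multiplier.
#' @return A new [PropertyTable-class].
#' @export
scalePropertyTable <- function(table, factor) {
  stopifnot(is(table, "PropertyTable"), is.numeric(factor), length(factor) == 1L)
  PropertyTable(propertyValues(table) * factor, kmerSize(table))
}
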