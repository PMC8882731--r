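# Synthetic 41-nt window generator with position-specific nucleotide
# enrichment, emulating the two-sample-logo structure observed around plant
# 6mA sites so the full pipeline is testable without external downloads.

#' EnrichmentProfile: positional nucleotide biases for simulation
#'
#' Describes how positive (6mA) windows differ from background: a window
#' length (odd; the center is always "A" in both classes), a list of
#' enriched (position, nucleotide, strength) triples at center-relative
#' positions, a background nucleotide distribution over A/C/G/T, and an
#' optional probability of masking flank positions to N.
#'
#' At each enriched position p with nucleotide x and strength s, a positive
#' window carries x with probability `s + (1 - s) * background[x]` (the
#' enriched base is forced with probability s, otherwise the position is
#' drawn from background); negatives are background throughout.
#'
#' @slot windowLength Odd integer window width (default 41).
#' @slot enriched data.frame with columns `position` (center-relative,
#'   nonzero), `nucleotide` (A/C/G/T) and `strength` (in `[0, 1]`).
#' @slot background Named numeric over A/C/G/T summing to 1.
#' @slot nRate Probability of masking a flank position to N.
#'
#' @seealso [defaultEnrichmentProfile()], [simulateWindows()]
#' @export
setClass("EnrichmentProfile",
  representation(windowLength = "integer", enriched = "data.frame",
                 background = "numeric", nRate = "numeric")
)

setValidity("EnrichmentProfile", function(object) {
  msg <- character()
  L <- object@windowLength
  if (length(L) != 1L || L < 3L || L %% 2L == 0L)
    msg <- c(msg, "windowLength must be a single odd integer >= 3")
  e <- object@enriched
  if (!all(c("position", "nucleotide", "strength") %in% names(e)))
    msg <- c(msg, "enriched needs columns position, nucleotide, strength")
  else {
    half <- (L - 1L) %/% 2L
    if (any(e$position == 0L) || any(abs(e$position) > half))
      msg <- c(msg, "enriched positions must be nonzero and within the flanks")
    if (!all(e$nucleotide %in% c("A", "C", "G", "T")))
      msg <- c(msg, "enriched nucleotides must be A/C/G/T")
    if (any(e$strength < 0) || any(e$strength > 1))
      msg <- c(msg, "strengths must lie in [0, 1]")
    if (anyDuplicated(e[, c("position", "nucleotide")]))
      msg <- c(msg, "duplicate (position, nucleotide) pairs")
  }
  if (!identical(sort(names(object@background)), c("A", "C", "G", "T")) ||
      abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be a distribution over A, C, G, T")
  if (object@nRate < 0 || object@nRate > 1)
    msg <- c(msg, "nRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentProfile-class summary of the profile
#' @param object An `EnrichmentProfile`.
#' @export
setMethod("show", "EnrichmentProfile", function(object) {
  cat(sprintf("EnrichmentProfile: %d-nt windows, %d enriched (position, base) pairs, nRate %.2f\n",
              object@windowLength, nrow(object@enriched), object@nRate))
})

#' The default enrichment profile around plant 6mA sites
#'
#' Positions (relative to the central methylated adenine at 0) where
#' two-sample logos of plant 6mA windows show nucleotide enrichment:
#' "A" at -6, -4, -3, 4, 7, 8, 10, 11, 12; "C" at -7, -2, 2, 6, 9;
#' "G" at -8, -1, 2, 3, 5, 8; and "T" at 3 — 21 (position, base) pairs in
#' total. The logos convey position and base only, not a numeric magnitude,
#' so one configurable strength is applied to every pair (default 0.5).
#'
#' @param strength Common enrichment strength in `[0, 1]` (default 0.5).
#' @param windowLength Odd window width (default 41).
#' @param background Named A/C/G/T distribution (default uniform).
#' @param nRate Probability of masking a flank position to N (default 0).
#' @return An [EnrichmentProfile-class].
#' @examples
#' defaultEnrichmentProfile()
#' @export
defaultEnrichmentProfile <- function(strength = 0.5, windowLength = 41L,
                                     background = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                                     nRate = 0) {
  pairs <- rbind(
    data.frame(position = c(-6L, -4L, -3L, 4L, 7L, 8L, 10L, 11L, 12L),
               nucleotide = "A"),
    data.frame(position = c(-7L, -2L, 2L, 6L, 9L), nucleotide = "C"),
    data.frame(position = c(-8L, -1L, 2L, 3L, 5L, 8L), nucleotide = "G"),
    data.frame(position = 3L, nucleotide = "T")
  )
  pairs$strength <- strength
  new("EnrichmentProfile", windowLength = as.integer(windowLength),
      enriched = pairs, background = background[c("A", "C", "G", "T")],
      nRate = as.numeric(nRate))
}

#' Simulate labeled 6mA / non-6mA windows
#'
#' Generates `nPos` positive and `nNeg` negative windows of the profile's
#' length, every one with "A" at the central position. Negative windows draw
#' every flank position i.i.d. from the background distribution; positive
#' windows additionally carry each enriched nucleotide at its enriched
#' position with the profile's strength (see
#' [EnrichmentProfile-class]). Deterministic given `seed`. The output passes
#' [cleanWindows()] untouched except for chance duplicates.
#'
#' @param nPos,nNeg Numbers of positive / negative windows (>= 1).
#' @param profile An [EnrichmentProfile-class]; default
#'   [defaultEnrichmentProfile()].
#' @param seed Integer RNG seed.
#' @param datasetName Provenance name.
#' @return A [WindowSet-class] of `nPos + nNeg` windows (positives first).
#' @examples
#' ws <- simulateWindows(5, 5, seed = 42)
#' table(windowLabels(ws))
#' @export
simulateWindows <- function(nPos, nNeg, profile = defaultEnrichmentProfile(),
                            seed = 1L, datasetName = "synthetic") {
  stopifnot(is(profile, "EnrichmentProfile"), nPos >= 1L, nNeg >= 1L)
  validObject(profile)
  set.seed(as.integer(seed))
  L <- profile@windowLength
  center <- (L + 1L) %/% 2L
  bg <- profile@background

  drawBackground <- function(n) {
    m <- matrix(sample(names(bg), n * L, replace = TRUE, prob = bg),
                nrow = n, ncol = L)
    m[, center] <- "A"
    m
  }

  pos <- drawBackground(nPos)
  for (r in seq_len(nrow(profile@enriched))) {
    e <- profile@enriched[r, ]
    col <- center + e$position
    force <- stats::runif(nPos) < e$strength
    pos[force, col] <- e$nucleotide
  }
  neg <- drawBackground(nNeg)

  if (profile@nRate > 0) {
    flanks <- setdiff(seq_len(L), center)
    maskN <- function(m) {
      sel <- matrix(stats::runif(nrow(m) * length(flanks)) < profile@nRate,
                    nrow = nrow(m))
      m[, flanks][sel] <- "N"
      m
    }
    pos <- maskN(pos)
    neg <- maskN(neg)
  }

  seqs <- c(apply(pos, 1L, paste, collapse = ""),
            apply(neg, 1L, paste, collapse = ""))
  names(seqs) <- c(sprintf("pos_%05d", seq_len(nPos)),
                   sprintf("neg_%05d", seq_len(nNeg)))
  WindowSet(seqs, labels = rep(c(1L, 0L), c(nPos, nNeg)),
            datasetName = datasetName)
}

#' Write a simulated dataset as FASTA plus a JSON sidecar
#'
#' Writes `positives.fasta` and `negatives.fasta` under `dir` together with
#' `simulation.json` recording the full generating specification (window
#' length, enriched triples, background, nRate, sample sizes, seed) so the
#' dataset can be regenerated exactly.
#'
#' @param data The [WindowSet-class] from [simulateWindows()].
#' @param dir Output directory (created if missing).
#' @param profile The generating [EnrichmentProfile-class].
#' @param seed The generation seed.
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(data, dir, profile, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- windowLabels(data)
  writeFastaWindows(data[labs == 1L], file.path(dir, "positives.fasta"))
  writeFastaWindows(data[labs == 0L], file.path(dir, "negatives.fasta"))
  sidecar <- list(windowLength = profile@windowLength,
                  enriched = profile@enriched,
                  background = as.list(profile@background),
                  nRate = profile@nRate,
                  nPos = sum(labs == 1L), nNeg = sum(labs == 0L),
                  seed = as.integer(seed),
                  package = "i6maVote",
                  version = as.character(utils::packageVersion("i6maVote")))
  jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
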