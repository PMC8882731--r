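# Shared fixtures: all inputs are built in code at test time.

# random adenine-centered windows over A/C/G/T/N
randomWindows <- function(n, L = 41L, seed = 1L, centerA = TRUE,
                          alphabet = c("A", "C", "G", "T", "N")) {
  set.seed(seed)
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (centerA) m[, (L + 1L) %/% 2L] <- "A"
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("r%04d", seq_len(n))
  seqs
}

windowSet <- function(seqs, labels, name = "fixture") {
  if (is.null(names(seqs))) names(seqs) <- paste0("w", seq_along(seqs))
  WindowSet(seqs, labels, name)
}

# write sequences to a throwaway FASTA (optionally line-wrapped)
tmpFasta <- function(seqs, ids = names(seqs), wrap = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(mapply(function(id, s) {
    body <- if (is.null(wrap)) s else {
      starts <- seq(1L, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1L, nchar(s)))
    }
    c(paste0(">", id), body)
  }, ids, seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# one-property toy tables for hand-checked physicochemical encodings
toyPropertyTable <- function(k, values) {
  tokens <- kmerCodebook(k)
  v <- matrix(0, length(tokens), 1L, dimnames = list(tokens, "P01"))
  v[names(values), 1L] <- unlist(values)
  PropertyTable(v, k)
}

# accuracy of predictions against a WindowSet's labels
heldOutAccuracy <- function(model, ws) {
  mean(predict(model, ws)$ensemble_label == windowLabels(ws))
}
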