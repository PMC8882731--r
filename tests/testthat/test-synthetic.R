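# The enrichment profile and the seeded window generator.

test_that("the default profile lists the 21 known enriched (position, base) pairs", {
  prof <- defaultEnrichmentProfile()
  e <- prof@enriched
  expect_equal(nrow(e), 21L)
  aPos <- sort(e$position[e$nucleotide == "A"])
  expect_equal(aPos, c(-6, -4, -3, 4, 7, 8, 10, 11, 12))
  expect_equal(sort(e$position[e$nucleotide == "C"]), c(-7, -2, 2, 6, 9))
  expect_equal(sort(e$position[e$nucleotide == "G"]), c(-8, -1, 2, 3, 5, 8))
  expect_equal(e$position[e$nucleotide == "T"], 3)
  expect_false(any(e$position == 0))  # the center is always the methylated A
  expect_true(all(e$strength == 0.5))
  expect_equal(nrow(defaultEnrichmentProfile(strength = 0.9)@enriched), 21L)
})

test_that("profile validity rejects malformed specifications", {
  expect_error(defaultEnrichmentProfile(strength = 1.5), "strengths")
  expect_error(defaultEnrichmentProfile(windowLength = 40), "odd")
  expect_error(defaultEnrichmentProfile(windowLength = 13), "within the flanks")
})

test_that("generated windows have the right shape, labels and determinism", {
  ws <- simulateWindows(20, 30, seed = 5)
  expect_length(ws, 50L)
  expect_equal(sum(windowLabels(ws) == 1L), 20L)
  seqs <- as.character(windowSequences(ws))
  expect_true(all(nchar(seqs) == 41L))
  expect_true(all(substring(seqs, 21, 21) == "A"))
  ws2 <- simulateWindows(20, 30, seed = 5)
  expect_identical(as.character(windowSequences(ws2)), seqs)
  expect_false(identical(as.character(windowSequences(simulateWindows(20, 30, seed = 6))),
                         seqs))
})

test_that("strength 1 forces the enriched base; negatives stay at background", {
  ws <- simulateWindows(300, 300, defaultEnrichmentProfile(strength = 1),
                        seed = 7)
  seqs <- as.character(windowSequences(ws))
  posSeqs <- seqs[windowLabels(ws) == 1L]
  negSeqs <- seqs[windowLabels(ws) == 0L]
  col <- 21 - 6  # center-relative position -6
  expect_true(all(substring(posSeqs, col, col) == "A"))
  negA <- mean(substring(negSeqs, col, col) == "A")
  expect_gt(negA, 0.25 - 3 * sqrt(0.25 * 0.75 / 300))
  expect_lt(negA, 0.25 + 3 * sqrt(0.25 * 0.75 / 300))
})

test_that("partial enrichment follows the binomial expectation s + (1-s)/4", {
  prof <- defaultEnrichmentProfile(strength = 0.5)
  ws <- simulateWindows(10000, 1, prof, seed = 8)
  seqs <- as.character(windowSequences(ws))[windowLabels(ws) == 1L]
  col <- 21 - 6
  freq <- mean(substring(seqs, col, col) == "A")
  expect_equal(freq, 0.5 + 0.5 * 0.25, tolerance = 0.02 / 0.625)
})

test_that("a null profile generates statistically indistinguishable classes", {
  ws <- simulateWindows(5000, 5000, defaultEnrichmentProfile(strength = 0),
                        seed = 9)
  seqs <- as.character(windowSequences(ws))
  labs <- windowLabels(ws)
  # chi-square at a handful of enriched positions; alpha = 0.01
  for (off in c(-6, 2, 3, 12)) {
    col <- 21 + off
    tab <- table(labs, substring(seqs, col, col))
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
  }
})

test_that("generated data pass cleaning untouched and N masking works", {
  ws <- simulateWindows(200, 200, seed = 10)
  cl <- cleanWindows(ws[windowLabels(ws) == 1L], ws[windowLabels(ws) == 0L])
  expect_equal(cl$report$positive$output, 200L)
  expect_equal(cl$report$negative$output, 200L)
  expect_equal(cl$report$positive$removed_length, 0L)

  prof <- defaultEnrichmentProfile(strength = 0, nRate = 0.1)
  wsN <- simulateWindows(500, 1, prof, seed = 11)
  seqs <- as.character(windowSequences(wsN))
  expect_true(all(substring(seqs, 21, 21) == "A"))  # center never masked
  nFrac <- mean(strsplit(paste(seqs, collapse = ""), "")[[1]] == "N")
  expect_equal(nFrac, 0.1 * 40 / 41, tolerance = 0.15)
})

test_that("simulation files round-trip through the FASTA/JSON sidecar", {
  dir <- tempfile()
  prof <- defaultEnrichmentProfile(strength = 0.7)
  ws <- runSimulation(dir, nPos = 15, nNeg = 12, strength = 0.7, seed = 12)
  expect_true(file.exists(file.path(dir, "positives.fasta")))
  expect_true(file.exists(file.path(dir, "negatives.fasta")))
  sidecar <- jsonlite::read_json(file.path(dir, "simulation.json"),
                                 simplifyVector = TRUE)
  expect_equal(sidecar$nPos, 15L)
  expect_equal(sidecar$seed, 12L)
  expect_equal(nrow(sidecar$enriched), 21L)
  pos <- readFastaWindows(file.path(dir, "positives.fasta"), 1)
  expect_length(pos, 15L)
  expect_identical(as.character(windowSequences(pos)),
                   as.character(windowSequences(ws[windowLabels(ws) == 1L])))
})

test_that("held-out accuracy does not decrease with enrichment strength", {
  # separability monotonicity across strengths, median over seeds
  strengths <- c(0, 0.5, 1)
  med <- sapply(strengths, function(s) {
    accs <- sapply(1:3, function(seed) {
      ws <- simulateWindows(120, 120, defaultEnrichmentProfile(strength = s),
                            seed = 100 + seed)
      sp <- splitWindows(ws, 0.8, seed = seed)
      X <- encodeWindows(sp$train, "ONEHOT2")
      fit <- trainBase(baseSpec("RF", seed = seed), X,
                       windowLabels(sp$train))
      mean(predictBase(fit, encodeWindows(sp$test, "ONEHOT2")) ==
             windowLabels(sp$test))
    })
    median(accs)
  })
  expect_true(all(diff(med) >= -0.05))
  expect_gt(med[3], med[1])
})
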