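# Base-learner contract, majority voting, grid search, ensemble training,
# prediction and persistence.

makeSeparable <- function(n = 40, p = 12) {
  X <- rbind(matrix(1, n / 2, p), matrix(0, n / 2, p))
  colnames(X) <- paste0("f", seq_len(p) - 1L)
  list(X = X, y = rep(c(1L, 0L), each = n / 2))
}

test_that("every base algorithm fits separable data perfectly and reproduces", {
  d <- makeSeparable()
  for (alg in c("RF", "LDA", "MLP", "SGD", "XGB")) {
    sp <- baseSpec(alg, seed = 5)
    fit <- trainBase(sp, d$X, d$y)
    expect_identical(predictBase(fit, d$X), d$y)
    fit2 <- trainBase(sp, d$X, d$y)
    probe <- matrix(runif(10 * 12), 10, 12,
                    dimnames = list(NULL, colnames(d$X)))
    expect_identical(predictBase(fit, probe), predictBase(fit2, probe))
  }
})

test_that("single-class labels and dimension mismatches are rejected", {
  d <- makeSeparable()
  expect_error(trainBase(baseSpec("RF"), d$X, rep(1L, nrow(d$X))),
               "single class")
  expect_error(trainBase(baseSpec("RF"), d$X, d$y[-1]), "nrow")
  expect_error(baseSpec("SVM"), "must be one of")
})

test_that("majority vote matches exhaustive counting on all 32 five-vote patterns", {
  patterns <- expand.grid(rep(list(0:1), 5))
  for (r in seq_len(nrow(patterns))) {
    votes <- as.integer(patterns[r, ])
    expected <- as.integer(sum(votes) >= 3L)  # brute-force count comparison
    expect_identical(majorityVote(votes, 3L), expected)
    # symmetry: any permutation of voters gives the same decision
    expect_identical(majorityVote(sample(votes), 3L), expected)
  }
  expect_identical(majorityVote(c(1, 1, 1, 0, 0), 3L), 1L)
  expect_identical(majorityVote(rep(0L, 5), 3L), 0L)
})

test_that("voting is monotone and unanimous, ties in even ensembles warn to 0", {
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  for (r in seq_len(nrow(patterns))) {
    votes <- patterns[r, ]
    out <- majorityVote(votes, 3L)
    for (i in which(votes == 0L)) {
      up <- votes; up[i] <- 1L
      expect_gte(majorityVote(up, 3L), out)  # 0->1 flip never lowers the call
    }
  }
  expect_identical(majorityVote(rep(1L, 5)), 1L)
  expect_identical(majorityVote(rep(0L, 5)), 0L)
  expect_warning(tie <- majorityVote(c(1L, 1L, 0L, 0L)), "tie")
  expect_identical(tie, 0L)
})

test_that("grid search is exhaustive, deterministic, and prefers working values", {
  d <- makeSeparable(n = 40)
  one <- gridSearch(baseSpec("SGD"), list(epochs = 10L), d$X, d$y,
                    folds = 4L, seed = 2)
  expect_equal(nrow(one$results), 1L)
  expect_identical(one$bestHyperparameters$epochs, 10L)

  # epochs = 0 leaves the SGD learner at its zero initialization -> constant
  # prediction, CV accuracy ~ 0.5 on balanced data; a trained value must win
  two <- gridSearch(baseSpec("SGD"), list(epochs = c(0L, 15L)), d$X, d$y,
                    folds = 4L, seed = 2)
  expect_equal(nrow(two$results), 2L)
  expect_identical(two$bestHyperparameters$epochs, 15L)
  expect_lte(two$results$cvAccuracy[1], 0.6)
  expect_gte(max(two$results$cvAccuracy, na.rm = TRUE),
             two$results$cvAccuracy[1])

  grid <- list(eta = c(0.1, 0.3), max_depth = c(2L, 4L))
  gs <- gridSearch(baseSpec("XGB"), grid, d$X, d$y, folds = 4L, seed = 2)
  expect_equal(nrow(gs$results), 4L)  # full Cartesian product evaluated
  expect_true(all(gs$results$cvAccuracy[gs$best] >=
                  gs$results$cvAccuracy, na.rm = TRUE))
})

test_that("the trained ensemble records provenance and recovers a planted motif", {
  ws <- simulateWindows(120, 120, defaultEnrichmentProfile(strength = 1),
                        seed = 21)
  sp <- splitWindows(ws, 0.8, seed = 21)
  model <- trainEnsemble(sp$train, seed = 21)
  expect_s4_class(model, "I6maVoteModel")
  expect_identical(modelEncoder(model), "ONEHOT2")
  expect_identical(names(baseModels(model)),
                   c("RF", "LDA", "MLP", "SGD", "XGB"))
  expect_identical(voteThreshold(model), 3L)
  expect_identical(modelMetadata(model)$seed, 21L)
  expect_gt(heldOutAccuracy(model, sp$test), 0.9)

  # determinism: identical seeds give identical vote patterns
  model2 <- trainEnsemble(sp$train, seed = 21)
  expect_identical(predict(model2, sp$test), predict(model, sp$test))
})

test_that("a lone random forest recovers strong synthetic enrichment", {
  ws <- simulateWindows(150, 150, defaultEnrichmentProfile(strength = 1),
                        seed = 31)
  sp <- splitWindows(ws, 0.8, seed = 31)
  cvX <- encodeWindows(sp$train, "ONEHOT2")
  fit <- trainBase(baseSpec("RF", seed = 31), cvX, windowLabels(sp$train))
  pred <- predictBase(fit, encodeWindows(sp$test, "ONEHOT2"))
  expect_gt(mean(pred == windowLabels(sp$test)), 0.9)
})

test_that("ensemble labels equal recomputed majority votes and validation is strict", {
  ws <- simulateWindows(60, 60, defaultEnrichmentProfile(strength = 0.8),
                        seed = 41)
  model <- trainEnsemble(ws, seed = 41)
  probe <- simulateWindows(40, 40, defaultEnrichmentProfile(strength = 0.8),
                           seed = 42)
  pred <- predict(model, probe)
  votes <- as.matrix(pred[, paste0("vote_", c("RF", "LDA", "MLP", "SGD", "XGB"))])
  expect_identical(pred$ensemble_label,
                   apply(votes, 1L, majorityVote, threshold = 3L))
  # permuting base-model order never changes the decision
  expect_identical(pred$ensemble_label,
                   apply(votes[, c(3, 5, 1, 4, 2)], 1L, majorityVote,
                         threshold = 3L))

  # wrong length or non-A center is rejected with offending ids listed
  expect_error(predict(model, c(bad1 = "ACGT")), "bad1")
  offcenter <- randomWindows(1, seed = 43)
  substr(offcenter, 21, 21) <- "C"
  expect_error(predict(model, c(bad2 = unname(offcenter))), "bad2")
})

test_that("saved models round-trip to identical predictions", {
  ws <- simulateWindows(50, 50, defaultEnrichmentProfile(strength = 1),
                        seed = 51)
  model <- trainEnsemble(ws, seed = 51)
  probe <- simulateWindows(25, 25, defaultEnrichmentProfile(strength = 1),
                           seed = 52)
  before <- predict(model, probe)
  path <- tempfile(fileext = ".rds")
  saveEnsemble(model, path)
  restored <- loadEnsemble(path)
  expect_identical(predict(restored, probe), before)
  expect_identical(modelMetadata(restored)$version,
                   as.character(utils::packageVersion("i6maVote")))
  saveRDS(list(a = 1), path)
  expect_error(loadEnsemble(path), "not an i6maVote model")
})
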