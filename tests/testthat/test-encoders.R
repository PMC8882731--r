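# The six feature encoders, their codebook and their invariants.

test_that("tokenize enumerates overlapping k-mers 5'->3'", {
  expect_identical(tokenize("ACGTNA", 2), c("AC", "CG", "GT", "TN", "NA"))
  expect_identical(tokenize("A", 1), "A")
  expect_identical(tokenize("ACGT", 3), c("ACG", "CGT"))
  expect_error(tokenize("AC", 3), "shorter")
})

test_that("the dinucleotide codebook is lexicographic with A<C<G<T<N", {
  cb <- kmerCodebook(2)
  expect_length(cb, 25L)
  expect_identical(cb[1:3], c("AA", "AC", "AG"))
  expect_identical(cb[24:25], c("NT", "NN"))
  expect_false(anyDuplicated(cb) > 0)
})

test_that("mononucleotide one-hot reproduces the ACGTNA layout", {
  expect_equal(encodeOneHot1("ACGTNA"),
               c(1,0,0,0,0, 0,1,0,0,0, 0,0,1,0,0, 0,0,0,1,0, 0,0,0,0,1,
                 1,0,0,0,0))
  expect_equal(encodeOneHot1("A"), c(1, 0, 0, 0, 0))
  expect_equal(encodeOneHot1("NN"), c(0,0,0,0,1, 0,0,0,0,1))
})

test_that("dinucleotide one-hot has codebook indices and exact dimensions", {
  v <- encodeOneHot2("AA")
  expect_equal(which(v == 1), 1L)
  expect_length(v, 25L)
  expect_length(encodeOneHot2("ACGTNA"), 125L)
  w41 <- randomWindows(1, seed = 4)
  expect_length(encodeOneHot2(w41), 1000L)
  expect_equal(sum(encodeOneHot2(w41)), 40)
})

test_that("one-hot row sums equal the number of encoded units", {
  for (s in randomWindows(20, L = 12, seed = 5, centerA = FALSE)) {
    expect_equal(sum(encodeOneHot1(s)), nchar(s))
    expect_equal(sum(encodeOneHot2(s)), nchar(s) - 1)
    expect_true(all(encodeOneHot1(s) %in% c(0, 1)))
    expect_true(all(encodeOneHot2(s) %in% c(0, 1)))
  }
})

test_that("accumulated frequencies match hand-computed prefixes", {
  expect_equal(encodeAMNF("ACGTNA"), c(1, 1/2, 1/3, 1/4, 1/5, 2/6))
  expect_equal(round(encodeAMNF("ACGTNA"), 2), c(1, .5, .33, .25, .2, .33))
  expect_equal(encodeAMNF("AAAA"), rep(1, 4))
  expect_equal(encodeAMNF("AT"), c(1, 0.5))
  expect_equal(encodeADNF("ACGTNA"), c(1, 1/2, 1/3, 1/4, 1/5))
  expect_equal(encodeADNF("AAA"), c(1, 1))
  expect_equal(encodeADNF("ACAC"), c(1, 1/2, 2/3))
  expect_error(encodeADNF("A"), "length >= 2")
})

test_that("accumulated encodings are prefix-consistent and in (0,1]", {
  for (s in randomWindows(25, L = 15, seed = 6, centerA = FALSE)) {
    am <- encodeAMNF(s)
    ad <- encodeADNF(s)
    expect_true(all(am > 0 & am <= 1))
    t <- sample(2:14, 1)
    pre <- substr(s, 1, t)
    expect_equal(encodeAMNF(pre), am[1:t])
    expect_equal(encodeADNF(pre), ad[1:(t - 1)])
  }
})

test_that("physicochemical encoding multiplies counts by table values", {
  # one property, AA = 2.0, everything else 1.0: "AAA" has two AA tokens
  tab <- toyPropertyTable(2, as.list(stats::setNames(rep(1, 25), kmerCodebook(2))))
  v <- propertyValues(tab); v["AA", 1] <- 2
  tab <- PropertyTable(v, 2)
  out <- encodePCP("AAA", tab)
  expect_equal(out[["AA.P01"]], 2 * 2.0)
  expect_equal(sum(out != 0), 1L)  # all other tokens have count 0

  tab3 <- toyPropertyTable(3, list(ACG = 0.5, CGT = -1.0))
  out3 <- encodePCP("ACGT", tab3)
  expect_equal(out3[["ACG.P01"]], 0.5)
  expect_equal(out3[["CGT.P01"]], -1.0)
  expect_equal(sum(out3 != 0), 2L)

  zeros <- toyPropertyTable(2, list())
  expect_equal(sum(encodePCP("ACGTNA", zeros)), 0)
})

test_that("physicochemical encoding is linear in the table and supports frequencies", {
  tab <- defaultPropertyTable(2)
  s <- randomWindows(1, seed = 8)
  expect_equal(encodePCP(s, scalePropertyTable(tab, 3)), 3 * encodePCP(s, tab))
  raw <- encodePCP(s, tab)
  rel <- encodePCP(s, tab, normalizeCounts = TRUE)
  expect_equal(rel, raw / 40)  # 40 overlapping dinucleotides in a 41-nt window
})

test_that("bundled default tables have the documented shape", {
  d <- defaultPropertyTable(2)
  expect_identical(dim(propertyValues(d)), c(25L, 15L))
  t <- defaultPropertyTable(3)
  expect_identical(dim(propertyValues(t)), c(125L, 11L))
  # N-containing tokens carry no signal in the bundled tables
  expect_true(all(propertyValues(d)[grepl("N", rownames(propertyValues(d))), ] == 0))
  expect_length(encodePCP("ACGTNA", d), 375L)
  expect_length(encodePCP(randomWindows(1, seed = 1), t), 1375L)
})

test_that("a property table with a missing or duplicate token is rejected", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(token = kmerCodebook(2)[-1], P01 = 1)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPropertyTable(tsv, 2), "exactly the 25")
})

test_that("fusion concatenates encodings in the listed order", {
  expect_equal(encodeFused("ACGTNA", c("AMNF", "ADNF")),
               c(encodeAMNF("ACGTNA"), encodeADNF("ACGTNA")))
  w41 <- randomWindows(1, seed = 10)
  expect_length(encodeFused(w41, c("ONEHOT1", "ONEHOT2")), 205 + 1000)
  expect_equal(encodeFused(w41, c("ONEHOT2", "ONEHOT2")),
               rep(encodeOneHot2(w41), 2))
  expect_error(encodeFused(w41, "ONEHOT2"), "two encoders")
})

test_that("encodeWindows preserves rows, is deterministic and permutation-equivariant", {
  seqs <- randomWindows(6, seed = 12)
  ws <- windowSet(seqs, rep(c(1, 0), 3))
  X <- encodeWindows(ws, "ONEHOT2")
  expect_identical(dim(X), c(6L, 1000L))
  expect_identical(rownames(X), windowIds(ws))
  expect_identical(X, encodeWindows(ws, "ONEHOT2"))
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(encodeWindows(ws[perm], "ONEHOT2"), X[perm, ],
               ignore_attr = TRUE)
  # identical windows encode identically
  same <- windowSet(rep(seqs[1], 3), c(1, 1, 1))
  Xs <- encodeWindows(same, "AMNF")
  expect_equal(Xs[1, ], Xs[3, ], ignore_attr = TRUE)
  # heterogeneous lengths are rejected
  bad <- windowSet(c(a = "ACGTA", b = "ACGTACG"), c(1, 0))
  expect_error(encodeWindows(bad, "AMNF"), "heterogeneous")
})

test_that("feature matrices export as id,label,f0..., CSV", {
  ws <- windowSet(randomWindows(3, L = 5, seed = 13), c(1, 0, 1))
  X <- encodeWindows(ws, "ONEHOT1")
  path <- tempfile(fileext = ".csv")
  writeFeatureMatrix(ws, X, path)
  back <- read.csv(path)
  expect_identical(names(back)[1:3], c("id", "label", "f0"))
  expect_equal(nrow(back), 3L)
  expect_equal(as.matrix(back[, -(1:2)]), X, ignore_attr = TRUE)
})
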