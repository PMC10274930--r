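test_that("reversal flips orientations, reverses order and is an involution", {
  expect_identical(reverseISeq(c(1L, -2L)), c(2L, -1L))
  expect_identical(reverseISeq(c(1L, -1L)), c(1L, -1L))   # palindrome
  set.seed(4)
  for (i in 1:20) {
    s <- sample(c(-9:-1, 1:9), sample(1:8, 1), replace = TRUE)
    expect_identical(reverseISeq(reverseISeq(s)), s)
  }
})

test_that("constructed integer overlaps are classified correctly", {
  iseqs <- list(a = c(1L, 2L, 3L, 4L), b = c(3L, 4L, 5L))
  ov <- integerOverlaps(iseqs)
  expect_identical(nrow(ov), 1L)
  expect_identical(ov$kind, "dovetail")
  expect_identical(ov$strand, "same")
  expect_identical(ov$aEnd, "suffix")
  expect_identical(ov$len, 2L)

  # opposite-strand containment: rev(b) = [2+,3+] is a run inside a
  iseqs2 <- list(a = c(1L, 2L, 3L), b = c(-3L, -2L))
  ov2 <- integerOverlaps(iseqs2)
  expect_identical(ov2$kind, "containment")
  expect_identical(ov2$strand, "opposite")
  expect_identical(ov2$contained, "b")
  expect_identical(ov2$shift, 1L)
})

test_that("integer overlap detection matches the brute-force oracle", {
  for (seed in 1:15) {
    iseqs <- randomISeqInstance(seed)
    got <- integerOverlaps(iseqs, minIov = 1)
    want <- oracleIntegerOverlaps(iseqs, minIov = 1)
    expect_identical(iovKey(got), iovKey(want), label = paste("seed", seed))
  }
})

test_that("integer overlaps are symmetric under whole-set reversal", {
  iseqs <- randomISeqInstance(77)
  ov1 <- integerOverlaps(iseqs)
  ov2 <- integerOverlaps(lapply(iseqs, reverseISeq))
  expect_identical(nrow(ov1), nrow(ov2))
  expect_identical(sort(ov1$len), sort(ov2$len))
  expect_identical(table(ov1$kind), table(ov2$kind))
})

test_that("graph construction drops contained sequences and reduces exactly", {
  iseqs <- list(a = c(1L, 2L, 3L), b = c(2L, 3L, 4L))
  g <- buildIntegerGraph(iseqs)
  expect_length(integerSeqs(g), 2L)
  expect_identical(length(unique(graphArcs(g)$edgeId)), 1L)

  # contained node absent
  iseqs2 <- list(a = c(1L, 2L, 3L, 4L), b = c(2L, 3L))
  g2 <- buildIntegerGraph(iseqs2)
  expect_identical(g2@dropped, "b")
  expect_length(integerSeqs(g2), 1L)

  # chain a->b->c with consistent direct a->c: direct edge reduced
  iseqs3 <- list(a = c(1L, 2L, 3L), b = c(2L, 3L, 4L), c = c(3L, 4L, 5L))
  g3 <- buildIntegerGraph(iseqs3)
  a3 <- graphArcs(g3)
  expect_identical(length(unique(a3$edgeId)), 2L)
  expect_false(any(a3$from == "a" & a3$to == "c"))
})

test_that("aggressive cleaning keeps the best edge per side and clips tips", {
  # out-overlaps {3, 1}: the length-1 edge is cut
  iseqs <- list(a = c(1L, 2L, 3L, 4L), b = c(2L, 3L, 4L, 5L), c = c(4L, 9L))
  g <- buildIntegerGraph(iseqs)
  expect_identical(length(unique(graphArcs(g)$edgeId)), 2L)
  gc <- aggressiveClean(g, tipNodes = 0L)   # no tip clipping here
  a <- graphArcs(gc)
  expect_identical(length(unique(a$edgeId)), 1L)
  expect_false(any(a$to == "c" | a$from == "c"))

  # cleaning a simple path is the identity
  iseqs2 <- list(a = c(1L, 2L), b = c(2L, 3L), c = c(3L, 4L))
  g2 <- buildIntegerGraph(iseqs2)
  gc2 <- aggressiveClean(g2, tipNodes = 2L)
  expect_identical(sort(names(integerSeqs(gc2))), c("a", "b", "c"))
  expect_identical(length(unique(graphArcs(gc2)$edgeId)), 2L)
})

test_that("integer contigs concatenate member sequences beyond the overlap", {
  # single node passes through unchanged
  ig1 <- buildIntegerGraph(list(a = c(1L, 2L)))
  c1 <- integerContigs(ig1)
  expect_identical(c1$contigs[[1]], c(1L, 2L))

  # a=[1,2,3], b=[3,4] with a length-1 dovetail -> [1,2,3,4]
  ig2 <- buildIntegerGraph(list(a = c(1L, 2L, 3L), b = c(3L, 4L)))
  c2 <- integerContigs(ig2)
  expect_length(c2$contigs, 1L)
  expect_identical(c2$contigs[[1]], c(1L, 2L, 3L, 4L))

  # canonical orientation: result equals the smaller of itself and reverse
  for (ct in c2$contigs)
    expect_true(duograph:::.iseqLeq(ct, reverseISeq(ct)))

  # contig elements never invent nodes
  got <- sort(unique(abs(c2$contigs[[1]])))
  expect_identical(got, sort(unique(abs(unlist(list(c(1L, 2L, 3L), c(3L, 4L)))))))
})

test_that("no contig spans a branch point of the cleaned integer graph", {
  iseqs <- randomISeqInstance(5, nSeqs = 16)
  ig <- aggressiveClean(buildIntegerGraph(iseqs))
  cc <- integerContigs(ig)
  deg <- duograph:::.outDeg(graphArcs(ig))
  for (nm in names(cc$provenance)) {
    p <- cc$provenance[[nm]]
    if (length(p) < 3) next
    inner <- p[-c(1, length(p))]
    for (v in inner) {
      expect_lte(duograph:::.outDegOf(deg, v, "+"), 1L)
      expect_lte(duograph:::.outDegOf(deg, v, "-"), 1L)
    }
  }
})
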