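test_that("a tiling of reads becomes a chain of nodes and dovetail edges", {
  reads <- tilingReads()
  ov <- findReadOverlaps(reads, minOvlp = 250, maxDiv = 0)
  g <- buildStringGraph(reads, ov)
  expect_identical(nrow(graphNodes(g)), 3L)
  expect_identical(length(unique(graphArcs(g)$edgeId)), 2L)  # consecutive pairs

  # longer reads make the skip overlap t1-t3 reportable, then reducible
  readsL <- tilingReads(22, n = 3, step = 400, len = 1200)
  ovL <- findReadOverlaps(readsL, minOvlp = 250, maxDiv = 0)
  gL <- buildStringGraph(readsL, ovL)
  expect_identical(length(unique(graphArcs(gL)$edgeId)), 3L)
  g2 <- transitiveReduction(gL, fuzz = 10)
  expect_identical(length(unique(graphArcs(g2)$edgeId)), 2L) # t1t3 reduced
  # bidirected consistency: reverse statement of every arc present
  a <- graphArcs(g2)
  key <- paste(a$from, a$fromOrient, a$to, a$toOrient, a$edgeId)
  rkey <- paste(a$to, chartr("+-", "-+", a$toOrient), a$from,
                chartr("+-", "-+", a$fromOrient), a$edgeId)
  expect_true(all(rkey %in% key))
})

test_that("keeping contained reads preserves the second haplotype's walk", {
  fx <- toyContainedFixture()
  ov <- findReadOverlaps(fx$acc, minOvlp = fx$minOvlp, maxDiv = 0)
  gF <- buildStringGraph(fx$acc, ov, keepContained = FALSE)
  expect_false(any(c("h11", "h12") %in% graphNodes(gF)$id))
  gT <- buildStringGraph(fx$acc, ov, keepContained = TRUE)
  expect_true(all(c("h11", "h12") %in% graphNodes(gT)$id))
  expect_true(all(graphNodes(gT)[c("h11", "h12"), "contained"] |
                    graphNodes(gT)$contained[graphNodes(gT)$id %in% c("h11", "h12")]))
  # dropping all contained reads fragments one haplotype
  expect_gt(duograph:::.nComponents(gF), duograph:::.nComponents(gT))
})

test_that("transitive reduction matches the brute-force oracle and is a fixed point", {
  for (seed in c(2, 7, 13)) {
    reads <- tilingReads(seed, n = 12, step = 300, len = 1100)
    ov <- findReadOverlaps(reads, minOvlp = 250, maxDiv = 0)
    g <- buildStringGraph(reads, ov)
    want <- setdiff(unique(graphArcs(g)$edgeId), oracleReducedEdgeIds(g, 10))
    got <- transitiveReduction(g, fuzz = 10)
    expect_setequal(unique(graphArcs(got)$edgeId), want)
    again <- transitiveReduction(got, fuzz = 10)
    expect_identical(sort(unique(graphArcs(again)$edgeId)),
                     sort(unique(graphArcs(got)$edgeId)))
  }
})

test_that("short dead-end spurs are clipped and clean chains are untouched", {
  set.seed(77)
  G <- oracleRandSeq(4000)
  reads <- c(a = substr(G, 1, 1000), b = substr(G, 601, 1600),
             c = substr(G, 1201, 2200), d = substr(G, 1801, 2800),
             e = substr(G, 2401, 3400))
  # a spur: follows the genome to a's end, then diverges into junk
  reads["spur"] <- paste0(substr(G, 601, 1000), oracleRandSeq(200))
  ov <- findReadOverlaps(reads, minOvlp = 250, maxDiv = 0)
  g <- transitiveReduction(buildStringGraph(reads, ov), 10)
  gc <- cleanGraph(g, tipLen = 1000, minEdgeReads = 1)
  expect_false("spur" %in% graphNodes(gc)$id)
  expect_true(all(c("a", "b", "c", "d", "e") %in% graphNodes(gc)$id))
  # idempotent on the already clean chain
  gc2 <- cleanGraph(gc, tipLen = 1000, minEdgeReads = 1)
  expect_identical(graphNodes(gc2)$id, graphNodes(gc)$id)
})

hetBubbleReads <- function(perBranch = 2) {
  set.seed(42)
  X <- oracleRandSeq(600); Y <- oracleRandSeq(600); mid <- oracleRandSeq(200)
  m1 <- mid; substr(m1, 100, 100) <- "A"
  m2 <- mid; substr(m2, 100, 100) <- "C"
  hap1 <- paste0(X, m1, Y); hap2 <- paste0(X, m2, Y)
  # A stops short of the SNV at position 700 so both branches join it
  reads <- c(A = substr(hap1, 1, 690), D = substr(hap1, 951, 1400))
  if (perBranch == 2) {
    reads["B1"] <- substr(hap1, 501, 1000); reads["B2"] <- substr(hap1, 651, 1150)
    reads["C1"] <- substr(hap2, 501, 1000); reads["C2"] <- substr(hap2, 651, 1150)
  } else {
    reads["B"] <- substr(hap1, 501, 1150)
    reads["C1"] <- substr(hap2, 501, 1000); reads["C2"] <- substr(hap2, 651, 1150)
  }
  reads
}

test_that("heterozygous bubbles with adequate read support survive cleaning", {
  reads <- hetBubbleReads(perBranch = 2)
  ov <- findReadOverlaps(reads, minOvlp = 100, maxDiv = 0)
  g <- transitiveReduction(buildStringGraph(reads, ov), 10)
  gc <- cleanGraph(g, tipLen = 0, minEdgeReads = 2)
  expect_true(all(c("B1", "B2", "C1", "C2") %in% graphNodes(gc)$id))

  # a single-read branch against a two-read branch is popped as artifact
  reads1 <- hetBubbleReads(perBranch = 1)
  ov1 <- findReadOverlaps(reads1, minOvlp = 100, maxDiv = 0)
  g1 <- transitiveReduction(buildStringGraph(reads1, ov1), 10)
  gc1 <- cleanGraph(g1, tipLen = 0, minEdgeReads = 2)
  expect_false("B" %in% graphNodes(gc1)$id)
  expect_true(all(c("C1", "C2") %in% graphNodes(gc1)$id))
})

test_that("unitig construction collapses chains and reproduces the genome", {
  # linear chain of 5 reads -> one unitig, no edges
  reads <- tilingReads(3, n = 5, step = 400, len = 1000)
  ov <- findReadOverlaps(reads, minOvlp = 250, maxDiv = 0)
  g <- transitiveReduction(buildStringGraph(reads, ov), 10)
  mu <- makeUnitigs(g)
  expect_identical(nrow(graphNodes(mu$graph)), 1L)
  expect_identical(nrow(graphArcs(mu$graph)), 0L)
  expect_identical(graphNodes(mu$graph)$len, 400L * 4L + 1000L)

  # perfect bubble -> 4 unitigs, 4 edges
  readsB <- hetBubbleReads(perBranch = 2)
  ovB <- findReadOverlaps(readsB, minOvlp = 100, maxDiv = 0)
  gB <- transitiveReduction(buildStringGraph(readsB, ovB), 10)
  muB <- makeUnitigs(gB)
  expect_identical(nrow(graphNodes(muB$graph)), 4L)
  expect_identical(length(unique(graphArcs(muB$graph)$edgeId)), 4L)

  # error-free repeat-free haploid simulation: one unitig per chromosome,
  # spelling the genome exactly
  spec <- simGenomeSpec(ploidy = 1L, chromLengths = c(20000L, 15000L),
                        hetRate = 0, teloLen = 200L, seed = 6L)
  gen <- simulateGenome(spec)
  rd <- simulateReads(gen, simReadSpec("accurate", meanLen = 2000, lenSd = 200,
                                       minLen = 800, coverage = 10, seed = 7L))
  ovS <- findReadOverlaps(rd$seqs, minOvlp = 250, maxDiv = 0)
  gS <- transitiveReduction(buildStringGraph(rd$seqs, ovS, keepContained = FALSE,
                                             minEdgeOvlp = 600L), 10)
  muS <- makeUnitigs(gS)
  expect_identical(nrow(graphNodes(muS$graph)), 2L)
  spelled <- sort(graphNodes(muS$graph)$seq)
  truth <- sort(vapply(gen$haplotypes$hap1, function(s)
    min(s, oracleRevcomp(s)), character(1)))
  canon <- sort(vapply(spelled, function(s) min(s, oracleRevcomp(s)), character(1)))
  expect_identical(unname(canon), unname(truth))
})
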