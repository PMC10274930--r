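test_that("a read spelled from a unitig walk chains through exactly that walk", {
  fx <- toyIncorporationFixture()
  read <- spellSequence(c(1L, 3L, 4L), fx$ug)
  al <- alignUL(c(q = read), fx$ug)
  ch <- al$alignments$q$chain
  expect_identical(ch$node, c("u1", "u3", "u4"))
  expect_identical(ch$orient, c("+", "+", "+"))
  # reverse complement gives the reverse walk
  alr <- alignUL(c(q = duograph:::.revcomp(read)), fx$ug)
  chr <- alr$alignments$q$chain
  expect_identical(chr$node, c("u4", "u3", "u1"))
  expect_identical(chr$orient, c("-", "-", "-"))
})

test_that("integer encoding is a pure projection and drops unaligned reads", {
  al <- list(alignments = list(
    a = list(ul = "a", chain = data.frame(node = c("u1", "u2"),
                                          orient = c("+", "-"))),
    b = list(ul = "b", chain = data.frame(node = character(0),
                                          orient = character(0)))))
  enc <- encodeInteger(al)
  expect_identical(enc, list(a = c(1L, -2L)))
})

test_that("edge support weights count distinct covering ultra-long reads", {
  asm <- toyContainedAssembly()
  # the junction into the homozygous tail is covered by exactly two
  # ultra-long reads
  expect_identical(edgeSupportBetween(asm, "h5", "h8"), 2L)

  # no ultra-long data -> all supports zero
  ug0 <- computeEdgeSupport(list(), asm$ug)
  expect_true(all(graphArcs(ug0)$support == 0L))

  # doubling every read doubles every support (linearity)
  dbl <- c(asm$iseqs, setNames(asm$iseqs, paste0(names(asm$iseqs), "_copy")))
  ug2 <- computeEdgeSupport(dbl, asm$ug)
  expect_identical(graphArcs(ug2)$support, 2L * graphArcs(asm$ug)$support)

  # unknown unitig id is a consistency error
  expect_error(computeEdgeSupport(list(x = c(1L, 999L)), asm$ug), "unknown")
})

test_that("ultra-long coverage rescues the critical contained read only", {
  asm <- toyContainedAssembly()
  expect_identical(asm$rescue$critical, "h12")
  expect_identical(asm$rescue$removable, "h11")

  # no ultra-long data: every contained read is removable
  al0 <- list(alignments = list())
  r0 <- rescueContained(al0, asm$ug, minRescue = 2)
  expect_setequal(r0$removable, c("h11", "h12"))
  expect_length(r0$critical, 0)

  # with minRescue = 1, no read covered by any chain is removable
  r1 <- rescueContained(asm$alignments, asm$ug, minRescue = 1)
  covered <- names(r1$coverCounts)[r1$coverCounts >= 1]
  expect_length(intersect(r1$removable, covered), 0)
})

test_that("every integer sequence is a walk in the unitig graph", {
  asm <- toyContainedAssembly()
  lut <- duograph:::.arcLookup(graphArcs(asm$ug))
  for (e in asm$iseqs) {
    if (length(e) < 2) next
    nm <- paste0("u", abs(e)); oo <- ifelse(e < 0, "-", "+")
    for (j in seq_len(length(e) - 1))
      expect_false(is.null(lut[[paste(nm[j], oo[j], nm[j + 1], oo[j + 1],
                                      sep = "\r")]]))
  }
})

test_that("support and rescue are invariant under reverse-complemented input", {
  fx <- toyContainedFixture()
  asm <- toyContainedAssembly(fx)
  rcUl <- vapply(fx$ul, duograph:::.revcomp, character(1))
  al <- alignUL(rcUl, asm$ug)
  iseqs <- encodeInteger(al)
  ugRc <- computeEdgeSupport(iseqs, asm$ug)
  expect_identical(graphArcs(ugRc)$support, graphArcs(asm$ug)$support)
  resc <- rescueContained(al, asm$ug, minRescue = 2)
  expect_identical(resc$critical, "h12")
  expect_identical(resc$removable, "h11")
})

weightedCleanFixture <- function(s1, s2, ov1 = 300L, ov2 = 100L) {
  set.seed(9)
  nodes <- data.frame(id = c("A", "B", "C"), len = 1000L, contained = FALSE,
                      seq = vapply(1:3, function(i) oracleRandSeq(1000),
                                   character(1)), stringsAsFactors = FALSE)
  arcs <- duograph:::.addEdges(duograph:::.emptyArcs(),
                               from = c("A", "A"), fromOrient = c("+", "+"),
                               to = c("B", "C"), toOrient = c("+", "+"),
                               ovlp = c(ov1, ov2))
  arcs$support[arcs$edgeId == 1L] <- s1
  arcs$support[arcs$edgeId == 2L] <- s2
  new("StringGraph", nodes = nodes, arcs = arcs, params = list())
}

test_that("weighted cleaning follows the support rules side by side", {
  # supports {2, 0}: the unsupported competitor is cut, A merges with B
  g <- weightedCleanFixture(2L, 0L)
  wc <- weightedClean(g, minSupport = 1)
  expect_length(wc$dropped, 1L)
  expect_identical(nrow(graphNodes(wc$graph)), 2L)
  expect_true(1700L %in% graphNodes(wc$graph)$len)

  # supports {2, 3}: both kept, ambiguity deferred
  g2 <- weightedCleanFixture(2L, 3L)
  wc2 <- weightedClean(g2, minSupport = 1)
  expect_length(wc2$dropped, 0L)
  expect_identical(nrow(graphNodes(wc2$graph)), 3L)

  # supports {0, 0}: fall back to the longest-overlap edge
  g3 <- weightedCleanFixture(0L, 0L, ov1 = 300L, ov2 = 100L)
  wc3 <- weightedClean(g3, minSupport = 1)
  expect_length(wc3$dropped, 1L)
  expect_true(1700L %in% graphNodes(wc3$graph)$len)
})

test_that("integer sequences remap through a condensation and split at cuts", {
  g <- weightedCleanFixture(2L, 0L)
  iseqs <- list(x = c(1L, 2L),      # A -> B : survives, collapses to one unitig
                y = c(1L, 3L))      # A -> C : cut, splits into fragments
  names(g@nodes$id) <- NULL
  g@nodes$id <- c("u1", "u2", "u3")
  g@arcs$from <- sub("A", "u1", sub("B", "u2", sub("C", "u3", g@arcs$from)))
  g@arcs$to <- sub("A", "u1", sub("B", "u2", sub("C", "u3", g@arcs$to)))
  wc <- weightedClean(g, iseqs = iseqs, minSupport = 1)
  expect_identical(length(wc$iseqs$x), 1L)           # merged into one element
  expect_identical(sum(grepl("^y", names(wc$iseqs))), 2L)  # split fragments
})
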