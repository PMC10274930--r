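test_that("FASTA and FASTQ round trips are identity and input is normalized", {
  set.seed(31)
  n <- 100
  seqs <- setNames(vapply(sample(50:300, n, replace = TRUE), oracleRandSeq,
                          character(1)), paste0("r", seq_len(n)))
  fa <- tempfile(fileext = ".fa")
  writeSeqs(seqs, fa)
  back <- readSeqs(fa)
  expect_identical(names(back), names(seqs))
  expect_identical(unname(as.character(back)), unname(seqs))

  fq <- tempfile(fileext = ".fq")
  seqs["ul1"] <- oracleRandSeq(60000)   # ultra-long records must survive too
  writeSeqs(seqs, fq, format = "fastq")
  backq <- readSeqs(fq)
  expect_identical(unname(as.character(backq)), unname(seqs))
  expect_identical(nchar(S4Vectors::mcols(backq)$qual), nchar(unname(seqs)))
  seqs <- seqs[names(seqs) != "ul1"]

  # case normalization and multi-line records
  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">r1", "acg", "taa"), f2)
  expect_identical(unname(as.character(readSeqs(f2))), "ACGTAA")

  # duplicate ids rejected
  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "GGGG"), f3)
  expect_error(readSeqs(f3), "duplicate")
})

test_that("GFA writing is strand-canonical and round trips the graph", {
  fx <- toyIncorporationFixture()
  path <- tempfile(fileext = ".gfa")
  writeGfa(fx$ug, path)
  lines <- readLines(path)
  expect_identical(lines[1], "H\tVN:Z:1.0")
  expect_identical(sum(startsWith(lines, "S\t")), 7L)
  llines <- lines[startsWith(lines, "L\t")]
  expect_identical(length(llines), 7L)   # one line per bidirected edge
  # no link stated together with its reverse-complement statement
  f <- strsplit(llines, "\t")
  stmt <- vapply(f, function(x) paste(x[2:5], collapse = " "), character(1))
  rev <- vapply(f, function(x) paste(x[4], chartr("+-", "-+", x[5]), x[2],
                                     chartr("+-", "-+", x[3])), character(1))
  expect_length(intersect(stmt, rev), 0)

  back <- readGfa(path)
  expect_setequal(graphNodes(back)$id, graphNodes(fx$ug)$id)
  canon <- function(g) {
    a <- graphArcs(g)
    s1 <- paste(a$from, a$fromOrient, a$to, a$toOrient, a$ovlp)
    s2 <- paste(a$to, chartr("+-", "-+", a$toOrient), a$from,
                chartr("+-", "-+", a$fromOrient), a$ovlp)
    sort(pmin(s1, s2)[!duplicated(a$edgeId)])
  }
  expect_identical(canon(back), canon(fx$ug))

  # empty graph -> header-only
  empty <- new("StringGraph")
  p2 <- tempfile(fileext = ".gfa")
  writeGfa(empty, p2)
  expect_identical(readLines(p2), "H\tVN:Z:1.0")
})

test_that("PAF output is tab-delimited, 0-based half-open, and re-parses", {
  p <- tempfile(fileext = ".paf")
  writePaf(list(), p)
  expect_identical(length(readLines(p)), 0L)

  al <- list(list(ul = "q", ulLen = 10000L, score = 50,
                  chain = data.frame(node = "u1", orient = "+",
                                     ulStart = 0L, ulEnd = 1000L,
                                     nodeStart = 500L, nodeEnd = 1500L,
                                     anchors = 60L)))
  writePaf(al, p, unitigLens = c(u1 = 5000L))
  df <- readPaf(p)
  expect_identical(nrow(df), 1L)
  expect_identical(df$qstart, 0L)
  expect_identical(df$qend, 1000L)
  expect_identical(df$tstart, 500L)
  expect_identical(df$tend, 1500L)
  expect_identical(df$strand, "+")

  # reverse-orientation coordinates land on the target forward strand
  al[[1]]$chain$orient <- "-"
  writePaf(al, p, unitigLens = c(u1 = 5000L))
  df <- readPaf(p)
  expect_identical(df$tstart, 5000L - 1500L)
  expect_identical(df$tend, 5000L - 500L)
  expect_identical(df$strand, "-")
})

test_that("toy assembly graphs survive a GFA round trip isomorphically", {
  asm <- toyContainedAssembly()
  p <- tempfile(fileext = ".gfa")
  writeGfa(asm$ug, p)
  back <- readGfa(p)
  expect_identical(nrow(graphNodes(back)), nrow(graphNodes(asm$ug)))
  expect_identical(length(unique(graphArcs(back)$edgeId)),
                   length(unique(graphArcs(asm$ug)$edgeId)))
  # support tags survive
  a1 <- graphArcs(asm$ug); a2 <- graphArcs(back)
  expect_identical(sort(a2$support[!duplicated(a2$edgeId)]),
                   sort(a1$support[!duplicated(a1$edgeId)]))
})
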