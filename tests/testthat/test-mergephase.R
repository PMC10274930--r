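# a two-unitig graph with a genuine 100 bp sequence overlap
consistentPair <- function(seed = 12) {
  set.seed(seed)
  s1 <- oracleRandSeq(1000)
  s2 <- paste0(substr(s1, 901, 1000), oracleRandSeq(700))
  nodes <- data.frame(id = c("u1", "u2"), len = c(1000L, 800L),
                      contained = FALSE, seq = c(s1, s2),
                      stringsAsFactors = FALSE)
  arcs <- duograph:::.addEdges(duograph:::.emptyArcs(), "u1", "+", "u2", "+", 100L)
  new("StringGraph", nodes = nodes, arcs = arcs, params = list())
}

test_that("walk spelling trims overlaps and respects orientation", {
  ug <- consistentPair()
  expect_identical(spellSequence(1L, ug), graphNodes(ug)$seq[1])
  expect_identical(spellSequence(-1L, ug),
                   duograph:::.revcomp(graphNodes(ug)$seq[1]))
  s <- spellSequence(c(1L, 2L), ug)
  expect_identical(nchar(s), 1700L)
  expect_identical(s, paste0(graphNodes(ug)$seq[1],
                             substr(graphNodes(ug)$seq[2], 101, 800)))
  expect_error(spellSequence(c(2L, 1L), ug), "missing edge")
  expect_error(spellSequence(c(1L, 9L), ug), "unknown unitig")
})

test_that("incorporation keeps one residual unitig in the worked example", {
  fx <- toyIncorporationFixture()
  ic <- integerContigs(aggressiveClean(buildIntegerGraph(fx$iseqs)))
  expect_length(ic$contigs, 2L)
  mg <- incorporateContigs(fx$ug, ic)
  nd <- graphNodes(mg)
  expect_identical(nd$id[nd$origin == "residual"], "u7")
  expect_identical(sum(nd$origin == "contig"), 2L)
  # the shared unitigs u3 and u6 back two contig nodes each
  counts <- table(abs(unlist(nodeElements(mg)[nd$id[nd$origin == "contig"]])))
  expect_identical(as.integer(counts[c("3", "6")]), c(2L, 2L))
  # boundary edges reconnect both contigs to the residual unitig
  a <- graphArcs(mg)
  expect_setequal(a$from[a$to == "u7" & a$toOrient == "+"],
                  nd$id[nd$origin == "contig"])

  # empty contig set: merged graph isomorphic to the unitig graph
  mg0 <- incorporateContigs(fx$ug, list())
  expect_identical(sort(graphNodes(mg0)$id), sort(graphNodes(fx$ug)$id))
  expect_true(all(graphNodes(mg0)$origin == "residual"))
  expect_identical(length(unique(graphArcs(mg0)$edgeId)),
                   length(unique(graphArcs(fx$ug)$edgeId)))

  # a contig referencing an unknown unitig is a consistency error
  expect_error(incorporateContigs(fx$ug, list(cx = c(1L, 99L))), "unknown unitig")
})

test_that("marker sets are haplotype-specific and pairwise disjoint", {
  set.seed(33)
  base <- oracleRandSeq(400)
  alt <- base
  substr(alt, 200, 200) <- if (substr(base, 200, 200) == "A") "C" else "A"
  mk <- buildMarkers(list(h1 = base, h2 = alt), k = 31)
  expect_gt(length(mk$h1), 0)
  expect_lte(length(mk$h1), 31)            # only k-mers spanning the SNV
  expect_lte(length(mk$h2), 31)
  expect_length(intersect(mk$h1, mk$h2), 0)

  # identical sources have no specific markers
  mk0 <- buildMarkers(list(a = base, b = base), k = 31)
  expect_length(mk0$a, 0)
  expect_length(mk0$b, 0)
  expect_error(buildMarkers(list(x = base)), "at least 2")

  # four sources from a tetraploid simulation: pairwise disjoint
  gen <- simulateGenome(simGenomeSpec(ploidy = 4L, chromLengths = 20000L,
                                      hetRate = 0.005, teloLen = 200L, seed = 3L))
  mk4 <- buildMarkers(lapply(gen$haplotypes, unname), k = 31)
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(mk4[[i]], mk4[[j]]), 0)
})

test_that("marker assignment counts only haplotype-informative k-mers", {
  gen <- simulateGenome(simGenomeSpec(ploidy = 2L, chromLengths = 20000L,
                                      hetRate = 0.003, teloLen = 200L, seed = 9L))
  mk <- buildMarkers(lapply(gen$haplotypes, unname), k = 31)
  h1 <- gen$haplotypes$hap1[[1]]
  # a homozygous window scores zero everywhere
  snv <- gen$snvs$pos
  gaps <- which(diff(sort(snv)) > 1200)
  g1 <- sort(snv)[gaps[1]]
  hom <- substr(h1, g1 + 200, g1 + 800)
  mg <- new("MergedGraph",
            nodes = data.frame(id = c("n1", "n2"), origin = "residual",
                               len = c(nchar(hom), 1000L)),
            elements = list(n1 = 1L, n2 = 2L),
            seqs = c(n1 = hom, n2 = substr(h1, snv[1] - 400, snv[1] + 600)),
            arcs = duograph:::.emptyArcs(), params = list())
  cnt <- assignMarkers(mg, mk)
  expect_identical(unname(cnt["n1", ]), c(0L, 0L))
  # a node containing hap1-specific SNVs scores hap1 only
  expect_gt(cnt["n2", "hap1"], 0)
  expect_identical(unname(cnt["n2", "hap2"]), 0L)
  # counting bound: totals cannot exceed the marker set size
  expect_lte(sum(cnt[, "hap1"]), length(mk$hap1))
})

test_that("graph binning separates haplotypes and degenerates on homozygous input", {
  cfg <- list(seed = 3,
              genome = list(ploidy = 2L, chromLengths = 16000L, hetRate = 0.008,
                            repeats = list(), teloLen = 200L),
              hifi = list(meanLen = 1600, lenSd = 160, minLen = 700, coverage = 12),
              ul = list(meanLen = 8000, lenSd = 800, minLen = 4000, coverage = 12),
              params = list(minContigLen = 1500L))
  res <- runPipeline(cfg, verbose = FALSE)
  dom <- res$bins$hap1$nodeLabels
  for (h in names(res$bins)) {
    b <- res$bins[[h]]
    for (p in b$provenance) {
      labs <- b$nodeLabels[p$node]
      expect_true(all(is.na(labs) | labs == h))
    }
    expect_identical(res$metrics$switchErrors[res$metrics$hap == h], 0L)
  }

  # all-homozygous genome: every haplotype emission is identical
  cfg$genome$hetRate <- 0
  res0 <- runPipeline(cfg, verbose = FALSE)
  expect_identical(unname(res0$bins$hap1$contigs),
                   unname(res0$bins$hap2$contigs))

  expect_error(graphBinning(res$merged, res$counts, "hap9"), "unknown haplotype")
})
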