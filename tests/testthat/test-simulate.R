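test_that("genome simulation records exactly the substitutions it makes", {
  spec <- simGenomeSpec(ploidy = 2L, chromLengths = 100000L, hetRate = 0.001,
                        teloLen = 300L, seed = 7L)
  g <- simulateGenome(spec)
  h1 <- strsplit(g$haplotypes$hap1[[1]], "")[[1]]
  h2 <- strsplit(g$haplotypes$hap2[[1]], "")[[1]]
  diffs <- which(h1 != h2) - 1L           # 0-based
  expect_setequal(diffs, g$snvs$pos)
  expect_gt(nrow(g$snvs), 50)             # ~100 expected at 0.001/bp
  expect_lt(nrow(g$snvs), 160)
  # each locus carries the recorded alternative allele on its haplotype
  for (i in sample(nrow(g$snvs), 20)) {
    r <- g$snvs[i, ]
    hap <- strsplit(g$haplotypes[[r$hap]][[1]], "")[[1]]
    expect_identical(hap[r$pos + 1], r$alt)
  }
})

test_that("telomere arrays and exact repeats are stamped where specified", {
  spec <- simGenomeSpec(ploidy = 1L, chromLengths = 50000L, hetRate = 0,
                        repeats = list(list(unitLen = 4000L, loci = c(10000L, 30000L))),
                        teloMotif = "TTAGGG", teloLen = 300L, seed = 2L)
  g <- simulateGenome(spec)
  s <- g$haplotypes$hap1[[1]]
  expect_identical(nchar(s), 50000L)
  expect_identical(substr(s, 1, 6), "TTAGGG")
  copy1 <- substr(s, 10001, 14000)
  copy2 <- substr(s, 30001, 34000)
  expect_identical(copy1, copy2)          # copies exact
  expect_error(simGenomeSpec(chromLengths = 20000L,
                             repeats = list(list(unitLen = 5000L, loci = 18000L))),
               "chromosome end")
})

test_that("simulation is byte-identical under a fixed seed", {
  spec <- simGenomeSpec(ploidy = 2L, chromLengths = 20000L, hetRate = 0.002,
                        seed = 5L)
  expect_identical(simulateGenome(spec), simulateGenome(spec))
  g <- simulateGenome(spec)
  rs <- simReadSpec("accurate", meanLen = 2000, lenSd = 200, minLen = 800,
                    coverage = 5, seed = 9L)
  expect_identical(simulateReads(g, rs), simulateReads(g, rs))
})

test_that("reads hit their coverage target, length floor and truth coordinates", {
  spec <- simGenomeSpec(ploidy = 1L, chromLengths = 100000L, hetRate = 0, seed = 3L)
  g <- simulateGenome(spec)
  rd <- simulateReads(g, simReadSpec("accurate", meanLen = 10000, lenSd = 1000,
                                     minLen = 4000, coverage = 1, seed = 4L))
  total <- sum(nchar(rd$seqs))
  expect_gte(total, 90000)
  expect_lte(total, 112000)
  expect_true(all(nchar(rd$seqs) >= 4000))

  # error-free reads are exact (possibly reverse-complemented) substrings
  hap <- g$haplotypes$hap1[[1]]
  for (i in seq_len(nrow(rd$truth))) {
    r <- rd$truth[i, ]
    ref <- substr(hap, r$start + 1, r$end)
    obs <- rd$seqs[[r$id]]
    if (r$strand == "-") obs <- oracleRevcomp(obs)
    expect_identical(obs, ref)
  }
  expect_identical(parseTruthNames(rd$truth$id)$start, rd$truth$start)
  expect_error(simulateReads(g, simReadSpec("ultralong", meanLen = 200000,
                                            minLen = 150000, coverage = 1)),
               "exceeds chromosome length")
})

test_that("the ultra-long length floor is enforced", {
  spec <- simGenomeSpec(ploidy = 1L, chromLengths = 200000L, hetRate = 0, seed = 8L)
  g <- simulateGenome(spec)
  ul <- simulateReads(g, simReadSpec("ultralong", meanLen = 60000, lenSd = 8000,
                                     minLen = 50000, coverage = 3, seed = 9L))
  expect_true(all(nchar(ul$seqs) >= 50000))
})
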