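#' Contained-read worked example (two haplotypes, twelve accurate reads)
#'
#' Builds, at sequence level, the classic contained-read scenario: two
#' haplotype regions that share a 600 bp identical block and a common
#' 500 bp homozygous tail. Twelve accurate reads `h1..h12` tile the two
#' haplotypes; `h3` (haplotype 1) fully contains `h11` (a redundant
#' haplotype-1 read) and `h12` (a haplotype-2 read whose span carries no
#' informative variant). `h12` is nonetheless critical: haplotype 2 tiles
#' through it (`h7 -> h12 -> h9`), so dropping all contained reads breaks
#' the haplotype-2 walk. Seven ultra-long reads `u1..u7` cover the two
#' haplotypes; `u6` and `u7` traverse `h12`, no chain needs `h11`, and
#' the edge `h5 -> h8` into the homozygous tail is covered by `u4` and
#' `u5` (support weight 2).
#'
#' @param seed RNG seed for the backing random sequences.
#' @return list with `acc` (12 accurate reads), `ul` (7 ultra-long
#'   reads), `minOvlp` (the overlap threshold the layout was designed
#'   for, 100 bp), and the two haplotype sequences `hapA`, `hapB`.
#' @export
toyContainedFixture <- function(seed = 42L) {
  set.seed(seed)
  O <- .randSeq(3000L)                 # haplotype 1 specific + shared block
  Bpre <- .randSeq(1200L)              # haplotype 2 specific (left)
  Bsuf <- .randSeq(1200L)              # haplotype 2 specific (right)
  Tl <- .randSeq(500L)                 # homozygous tail
  M <- substr(O, 1201L, 1800L)         # identical 600 bp block
  hapA <- paste0(O, Tl)                # 3500 bp
  hapB <- paste0(Bpre, M, Bsuf, Tl)    # 3500 bp
  cut <- function(s, a, b) substr(s, a + 1L, b)
  acc <- c(
    h1 = cut(hapA, 0L, 600L),     h2 = cut(hapA, 400L, 1000L),
    h3 = cut(hapA, 800L, 2000L),  h4 = cut(hapA, 1800L, 2400L),
    h5 = cut(hapA, 2200L, 3100L), h8 = cut(hapA, 3000L, 3500L),
    h11 = cut(hapA, 900L, 1400L),
    h6 = cut(hapB, 0L, 600L),     h7 = cut(hapB, 400L, 1300L),
    h12 = cut(hapB, 1200L, 1800L), h9 = cut(hapB, 1700L, 2400L),
    h10 = cut(hapB, 2300L, 3100L))
  ul <- c(
    u1 = cut(hapA, 0L, 1200L),    u2 = cut(hapA, 300L, 2300L),
    u3 = cut(hapA, 1400L, 2900L), u4 = cut(hapA, 1900L, 3200L),
    u5 = cut(hapA, 2600L, 3350L),
    u6 = cut(hapB, 300L, 1900L),  u7 = cut(hapB, 1100L, 3350L))
  list(acc = acc, ul = ul, minOvlp = 100L, hapA = hapA, hapB = hapB)
}

#' Assemble the contained-read worked example
#'
#' Runs the real machinery on [toyContainedFixture()]: overlap detection,
#' keep-contained string graph, unitigging, ultra-long graph alignment,
#' integer encoding, edge support and contained-read rescue. Convenience
#' wrapper used by examples and the acceptance checks.
#'
#' @param fix output of [toyContainedFixture()].
#' @param minRescue rescue threshold (covering chains).
#' @return list with the overlap table, read graph `g`, unitig graph
#'   `ug` (support filled), the `map` read->unitig, alignments, integer
#'   sequences and the rescue partition.
#' @export
toyContainedAssembly <- function(fix = toyContainedFixture(), minRescue = 2L) {
  ov <- findReadOverlaps(fix$acc, k = 21L, minOvlp = fix$minOvlp, maxDiv = 0)
  g <- buildStringGraph(fix$acc, ov, keepContained = TRUE)
  g <- transitiveReduction(g, fuzz = 10L)
  mu <- makeUnitigs(g)
  al <- alignUL(fix$ul, mu$graph)
  iseqs <- encodeInteger(al)
  ug <- computeEdgeSupport(iseqs, mu$graph)
  resc <- rescueContained(al, ug, minRescue = minRescue)
  list(overlaps = ov, g = g, ug = ug, map = mu$map,
       alignments = al, iseqs = iseqs, rescue = resc)
}

#' Ultra-long support of the edge between two reads
#'
#' Looks up, on the unitig graph, the edge whose underlying read-level
#' junction joins `readA` to `readB`, and returns its ultra-long support
#' weight.
#'
#' @param asm output of [toyContainedAssembly()] (any list with `ug` and
#'   `map`).
#' @param readA,readB read ids flanking the junction.
#' @return integer support (distinct covering ultra-long reads).
#' @export
edgeSupportBetween <- function(asm, readA, readB) {
  uA <- asm$map[readA, "new"]; uB <- asm$map[readB, "new"]
  if (is.na(uA) || is.na(uB)) stop("unknown read")
  a <- asm$ug@arcs
  if (uA == uB) stop("reads lie on the same unitig; no edge between them")
  hit <- a[a$from == uA & a$to == uB, , drop = FALSE]
  if (!nrow(hit)) stop("no edge between the unitigs of ", readA, " and ", readB)
  hit$support[1L]
}

#' Graph-incorporation worked example
#'
#' A schematic unitig graph of seven unitigs (`u1..u7`) forming two
#' haplotype paths through shared nodes, plus four ultra-long integer
#' sequences whose integer contigs cover `u1..u6`. After incorporation
#' the only residual unitig is `u7`; the shared unitigs `u3` and `u6`
#' back two contig nodes each.
#'
#' @param seed RNG seed for the placeholder unitig sequences.
#' @return list with `ug` (unitig [StringGraph]), `iseqs` (named list of
#'   signed integer vectors).
#' @export
toyIncorporationFixture <- function(seed = 7L) {
  set.seed(seed)
  ids <- paste0("u", 1:7)
  nodes <- data.frame(id = ids, len = 1000L, contained = FALSE,
                      seq = vapply(1:7, function(i) .randSeq(1000L), character(1)),
                      stringsAsFactors = FALSE)
  arcs <- .emptyArcs()
  arcs <- .addEdges(arcs,
                    from = c("u1", "u2", "u3", "u3", "u4", "u5", "u6"),
                    fromOrient = rep("+", 7L),
                    to = c("u3", "u3", "u4", "u5", "u6", "u6", "u7"),
                    toOrient = rep("+", 7L), ovlp = rep(100L, 7L))
  ug <- new("StringGraph", nodes = nodes, arcs = arcs,
            params = list(schematic = TRUE))
  validObject(ug)
  iseqs <- list(s1 = c(1L, 3L, 4L), s2 = c(3L, 4L, 6L),
                s3 = c(2L, 3L, 5L), s4 = c(3L, 5L, 6L))
  list(ug = ug, iseqs = iseqs)
}

#' Heterozygous genome with an ultra-long-resolvable repeat and a
#' critical contained read
#'
#' The canonical fixture behind the hybrid-assembly premise: an exact
#' repeat longer than the accurate reads but shorter than the ultra-long
#' reads, stamped at two loci of a heterozygous diploid chromosome.
#' Accurate-read-only assembly must fragment at the repeat; the hybrid
#' pipeline must not.
#'
#' The fixture additionally embeds the critical-contained-read geometry
#' at a homozygous block (an SNV-free segment stamped once): haplotype-2
#' coverage is thinned across the block to a minimal designed tiling -
#' the local coverage dip that makes containment matter - so that the
#' block-interior haplotype-2 read `B` is (a) exactly contained in a
#' haplotype-1 read spanning the block boundary and (b) the only
#' connection between haplotype 2's flanks. Dropping all contained reads
#' therefore breaks the haplotype-2 walk, while ultra-long chains
#' traverse `B` and rescue it.
#'
#' @param seed base RNG seed.
#' @param chromLen chromosome length (bp).
#' @param repeatLen exact repeat length (bp); longer than the accurate
#'   mean read length, shorter than the ultra-long mean.
#' @param hetRate heterozygosity between the two haplotypes.
#' @return list with `genome`, `hifi`, `ul` (simulation outputs;
#'   `hifi$seqs` includes the designed cassette reads), `criticalRead`
#'   (the id of `B`), `containerRead`, and `params` (overlap/alignment
#'   parameters matched to the read scale).
#' @export
ulRepeatFixture <- function(seed = 5L, chromLen = 32000L, repeatLen = 4000L,
                            hetRate = 0.008) {
  blockLen <- 3000L
  b0 <- as.integer(round(chromLen * 0.78))            # homozygous block start
  gspec <- simGenomeSpec(
    ploidy = 2L, chromLengths = chromLen, hetRate = hetRate,
    repeats = list(list(unitLen = repeatLen,
                        loci = c(round(chromLen * 0.22), round(chromLen * 0.53))),
                   list(unitLen = blockLen, loci = b0)),
    teloMotif = "TTAGGG", teloLen = 200L, seed = seed)
  genome <- simulateGenome(gspec)
  hifi <- simulateReads(genome, simReadSpec("accurate", meanLen = 2000,
                                            lenSd = 200, minLen = 800,
                                            coverage = 12, seed = seed + 1L))
  ul <- simulateReads(genome, simReadSpec("ultralong", meanLen = 12000,
                                          lenSd = 1200, minLen = 6000,
                                          coverage = 12, seed = seed + 2L))
  # thin both haplotypes across the block (the local coverage dip), then
  # lay the designed tilings: haplotype 1 walks the block through its
  # flank-marked reads A1-A2-A3; haplotype 2 needs the block-interior
  # read B, which is exactly contained in the boundary-crossing A2
  zone <- c(b0 - 2500L, b0 + blockLen + 500L)
  tr <- hifi$truth
  drop <- tr$id[tr$end > zone[1] & tr$start < zone[2]]
  hifi$seqs <- hifi$seqs[setdiff(names(hifi$seqs), drop)]
  hifi$truth <- tr[!(tr$id %in% drop), ]
  cut <- function(hap, s, e) substr(genome$haplotypes[[hap]][[1]], s + 1L, e)
  mk <- function(hap, s, e, tag) setNames(cut(hap, s, e),
    sprintf("acc%s!h%d!c1!%d!%d!+", tag, hap, s, e))
  cassette <- c(
    mk(2L, b0 - 3200L, b0 + 600L, "H1"),
    mk(2L, b0 + 200L, b0 + 1400L, "B"),
    mk(2L, b0 + 1000L, b0 + blockLen + 1300L, "H3"),
    mk(1L, b0 - 3360L, b0 - 560L, "A1"),
    mk(1L, b0 - 900L, b0 + 1500L, "A2"),
    mk(1L, b0 + 1140L, b0 + 4440L, "A3"))
  hifi$seqs <- c(hifi$seqs, cassette)
  hifi$truth <- rbind(hifi$truth, parseTruthNames(names(cassette)))
  list(genome = genome, hifi = hifi, ul = ul,
       criticalRead = names(cassette)[2],
       containerRead = names(cassette)[5],
       params = list(k = 21L, minOvlp = 250L, maxDiv = 0, fuzz = 10L,
                     tipLen = 0L, minEdgeReads = 1L, edgeMinOvlp = 600L,
                     minRescue = 2L, markerK = 31L,
                     minMarkers = 2L, domRatio = 2.0))
}
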