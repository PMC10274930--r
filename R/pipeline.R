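#' Default end-to-end configuration
#'
#' Study conditions for the flagship diploid run: a 2 x 500 kb diploid
#' chromosome with a 30 kb exact repeat stamped at two loci, 0.002/bp
#' heterozygosity, error-free accurate reads of mean 15 kb at 10x per
#' haplotype and ultra-long reads of mean 80 kb (minimum 40 kb, the
#' desk-scale analogue of the >= 50 kb input filter) at 15x. Every value
#' can be overridden through the nested `config` list or YAML file.
#'
#' @param seed base seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(ploidy = 2L, chromLengths = 500000L, hetRate = 0.002,
                  repeats = list(list(unitLen = 30000L,
                                      loci = c(120000L, 300000L))),
                  teloMotif = "TTAGGG", teloLen = 300L,
                  seed = 10000L + seed),
    hifi = list(meanLen = 15000, lenSd = 1500, minLen = 5000, coverage = 10,
                errorRate = 0, seed = 20000L + seed),
    ul = list(meanLen = 80000, lenSd = 8000, minLen = 40000, coverage = 15,
              errorRate = 0, seed = 30000L + seed),
    params = list(k = 21L, minOvlp = 250L, maxDiv = 0, fuzz = 10L,
                  tipLen = NA_integer_,       # derived from the error model
                  minEdgeReads = NA_integer_, alignK = 17L, alignW = 11L,
                  maxGap = 2000L, minAnchors = 3L, minRescue = 2L,
                  edgeMinOvlp = NA_integer_,  # derived: 0.3 x accurate mean
                  minSupport = 1L, minIov = 1L, tipNodes = 2L,
                  markerK = 31L, minMarkers = 2L, domRatio = 2.0,
                  minContigLen = 5000L),
    hifiOnly = FALSE, dumpStages = FALSE)
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])) && nm != "repeats")
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full double-graph assembly pipeline
#'
#' Simulates the genome and reads per the configuration (or uses
#' supplied read sets), then runs overlap detection, backbone string
#' graph construction with contained reads kept, ultra-long graph
#' alignment, contained-read rescue, support-weighted cleaning, the
#' integer graph, contig incorporation, marker-based graph binning and
#' truth evaluation. With `hifiOnly = TRUE` the ultra-long stages are
#' skipped and the classic contained-read-free string graph is binned
#' directly (the accurate-read-only baseline).
#'
#' @param config nested list (see [defaultConfig()]), or path to a YAML
#'   file of overrides; partial configs are merged over the defaults.
#' @param outDir optional output directory for artifacts (per-haplotype
#'   FASTA, GFA, integer sequence/contig TSV, metrics TSV/JSON).
#' @param reads optional list with `hifi` and `ul` (named character
#'   vectors) to assemble instead of simulating; truth metrics are then
#'   computed only when a `genome` element is also supplied.
#' @param verbose log one line per stage.
#' @return list with all intermediate and final artifacts: `genome`,
#'   `overlaps`, `readGraph`, `unitigGraph`, `rescue`, `iseqs`,
#'   `integerGraph`, `contigs`, `merged`, `markers`, `counts`, `bins`,
#'   `metrics` (data.frame, one row per haplotype), `config`.
#' @export
runPipeline <- function(config = list(), outDir = NULL, reads = NULL,
                        verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultConfig(if (!is.null(config$seed)) config$seed else 1L),
                      config)
  p <- cfg$params
  # tips and weak bubble branches are error artifacts; with error-free
  # accurate reads every dead-end chain and every branch is real sequence
  # (for example the other haplotype's chromosome-end stub), so cleaning
  # them would bake the wrong allele into the backbone
  errFree <- cfg$hifi$errorRate == 0
  if (is.na(p$tipLen))
    p$tipLen <- if (errFree) 0L else as.integer(3 * cfg$hifi$meanLen)
  if (is.na(p$minEdgeReads)) p$minEdgeReads <- if (errFree) 1L else 2L
  if (is.na(p$edgeMinOvlp)) p$edgeMinOvlp <- as.integer(round(0.3 * cfg$hifi$meanLen))
  say <- function(...) if (verbose) message(sprintf(...))

  genome <- NULL
  if (is.null(reads)) {
    gspec <- simGenomeSpec(ploidy = cfg$genome$ploidy,
                           chromLengths = cfg$genome$chromLengths,
                           hetRate = cfg$genome$hetRate,
                           repeats = cfg$genome$repeats,
                           teloMotif = cfg$genome$teloMotif,
                           teloLen = cfg$genome$teloLen,
                           seed = cfg$genome$seed)
    genome <- simulateGenome(gspec)
    say("simulate: ploidy %d, %d chromosome(s), %d SNV loci",
        gspec$ploidy, length(gspec$chromLengths), nrow(genome$snvs))
    hifi <- simulateReads(genome, simReadSpec("accurate",
      meanLen = cfg$hifi$meanLen, lenSd = cfg$hifi$lenSd,
      minLen = cfg$hifi$minLen, coverage = cfg$hifi$coverage,
      errorRate = cfg$hifi$errorRate, seed = cfg$hifi$seed))
    ul <- simulateReads(genome, simReadSpec("ultralong",
      meanLen = cfg$ul$meanLen, lenSd = cfg$ul$lenSd,
      minLen = cfg$ul$minLen, coverage = cfg$ul$coverage,
      errorRate = cfg$ul$errorRate, seed = cfg$ul$seed))
    accSeqs <- hifi$seqs; ulSeqs <- ul$seqs
    say("simulate: %d accurate reads (%.1f Mb), %d ultra-long reads (%.1f Mb)",
        length(accSeqs), sum(nchar(accSeqs)) / 1e6,
        length(ulSeqs), sum(nchar(ulSeqs)) / 1e6)
  } else {
    genome <- reads$genome
    accSeqs <- if (is.character(reads$hifi)) reads$hifi else reads$hifi$seqs
    ulSeqs <- if (is.character(reads$ul)) reads$ul else reads$ul$seqs
  }

  ov <- findReadOverlaps(accSeqs, k = p$k, minOvlp = p$minOvlp,
                         maxDiv = p$maxDiv)
  say("overlap: %d placements (%d containments)",
      nrow(ov), sum(ov$kind != "dovetail"))

  stages <- list()
  if (cfg$hifiOnly) {
    g <- buildStringGraph(accSeqs, ov, keepContained = FALSE,
                          minEdgeOvlp = p$edgeMinOvlp)
    g <- transitiveReduction(g, fuzz = p$fuzz)
    g <- cleanGraph(g, tipLen = p$tipLen, minEdgeReads = p$minEdgeReads)
    mu <- makeUnitigs(g)
    ugF <- mu$graph
    say("hifi graph: %d unitigs (accurate-only baseline)", nrow(ugF@nodes))
    rescue <- NULL; iseqsF <- list(); igc <- NULL
    ic <- list(contigs = list(), provenance = list())
  } else {
    g1 <- buildStringGraph(accSeqs, ov, keepContained = TRUE,
                           minEdgeOvlp = p$edgeMinOvlp)
    g1 <- transitiveReduction(g1, fuzz = p$fuzz)
    g1 <- cleanGraph(g1, tipLen = p$tipLen, minEdgeReads = p$minEdgeReads)
    mu1 <- makeUnitigs(g1)
    say("hifi graph: %d nodes / %d unitigs, %d contained kept",
        nrow(g1@nodes), nrow(mu1$graph@nodes), sum(g1@nodes$contained))
    al1 <- alignUL(ulSeqs, mu1$graph, k = p$alignK, w = p$alignW,
                   maxGap = p$maxGap, minAnchors = p$minAnchors)
    rescue <- rescueContained(al1, mu1$graph, minRescue = p$minRescue)
    say("rescue: %d critical, %d removable contained reads",
        length(rescue$critical), length(rescue$removable))
    g2 <- buildStringGraph(accSeqs, ov, keepContained = TRUE,
                           dropReads = rescue$removable,
                           minEdgeOvlp = p$edgeMinOvlp)
    g2 <- transitiveReduction(g2, fuzz = p$fuzz)
    g2 <- cleanGraph(g2, tipLen = p$tipLen, minEdgeReads = p$minEdgeReads)
    mu2 <- makeUnitigs(g2)
    al2 <- alignUL(ulSeqs, mu2$graph, k = p$alignK, w = p$alignW,
                   maxGap = p$maxGap, minAnchors = p$minAnchors)
    iseqs <- encodeInteger(al2)
    ug2 <- computeEdgeSupport(iseqs, mu2$graph)
    wc <- weightedClean(ug2, minSupport = p$minSupport)
    ugF <- wc$graph
    # third alignment pass: chains on the merged post-clean unitigs are
    # cleaner than remapped ones (fewer junctions, no stale adjacencies)
    al3 <- alignUL(ulSeqs, ugF, k = p$alignK, w = p$alignW,
                   maxGap = p$maxGap, minAnchors = p$minAnchors)
    iseqsF <- encodeInteger(al3)
    say("ul align: %d integer sequences on %d unitigs (%d after weighted clean)",
        length(iseqs), nrow(mu2$graph@nodes), nrow(ugF@nodes))
    ig <- buildIntegerGraph(iseqsF, minIov = p$minIov)
    igc <- aggressiveClean(ig, tipNodes = p$tipNodes)
    ic <- integerContigs(igc)
    say("integer graph: %d nodes -> %d integer contigs",
        length(ig@iseqs), length(ic$contigs))
    g <- g2
    stages <- list(readGraphKeep = g1, unitigGraphKeep = mu1$graph)
  }
  mg <- incorporateContigs(ugF, ic)
  say("incorporate: %d contig nodes + %d residual unitigs",
      sum(mg@nodes$origin == "contig"), sum(mg@nodes$origin == "residual"))

  markers <- NULL; counts <- NULL; bins <- NULL; metrics <- NULL
  if (!is.null(genome)) {
    sources <- lapply(genome$haplotypes, unname)
    markers <- buildMarkers(sources, k = p$markerK)
    counts <- assignMarkers(mg, markers)
    bins <- binAllHaplotypes(mg, counts, minMarkers = p$minMarkers,
                             domRatio = p$domRatio)
    rows <- list()
    for (h in names(bins)) {
      b <- bins[[h]]
      labelPaths <- lapply(b$provenance, function(pp) b$nodeLabels[pp$node])
      mt <- truthMetrics(b$contigs, genome$haplotypes[[h]],
                         teloMotif = cfg$genome$teloMotif,
                         minLen = p$minContigLen, labelPaths = labelPaths,
                         mode = if (cfg$hifi$errorRate > 0 ||
                                    cfg$ul$errorRate > 0) "kmer" else "exact")
      rows[[h]] <- data.frame(hap = h, as.data.frame(mt),
                              stringsAsFactors = FALSE)
      say("metrics %s: %d contigs (%d >= %d bp), N50 %d, coverage %.3f, %d switch errors, %d T2T",
          h, mt$nContigs, mt$nContigsGeMin, p$minContigLen, mt$n50,
          mt$coverage, mt$switchErrors, mt$t2tCount)
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
  }

  res <- c(list(genome = genome, overlaps = ov, readGraph = g,
                unitigGraph = ugF, rescue = rescue, iseqs = iseqsF,
                integerGraph = igc, contigs = ic, merged = mg,
                markers = markers, counts = counts, bins = bins,
                metrics = metrics, config = cfg), stages)
  if (!is.null(outDir)) .writeArtifacts(res, outDir, cfg)
  res
}

.writeArtifacts <- function(res, outDir, cfg) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeGfa(res$merged, file.path(outDir, "final_graph.gfa"))
  writeGfa(res$unitigGraph, file.path(outDir, "unitig_graph.gfa"))
  if (isTRUE(cfg$dumpStages) && !is.null(res$unitigGraphKeep))
    writeGfa(res$unitigGraphKeep, file.path(outDir, "unitig_graph_keep.gfa"))
  if (length(res$iseqs)) {
    df <- data.frame(ul = names(res$iseqs),
                     elements = vapply(res$iseqs, function(e)
                       paste(ifelse(e < 0, paste0("-", abs(e)), paste0("+", e)),
                             collapse = ","), character(1)))
    write.table(df, file.path(outDir, "integer_sequences.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (length(res$contigs$contigs)) {
    df <- data.frame(contig = names(res$contigs$contigs),
                     elements = vapply(res$contigs$contigs, function(e)
                       paste(ifelse(e < 0, paste0("-", abs(e)), paste0("+", e)),
                             collapse = ","), character(1)))
    write.table(df, file.path(outDir, "integer_contigs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$bins)) {
    for (h in names(res$bins))
      writeSeqs(res$bins[[h]]$contigs, file.path(outDir, paste0(h, ".fa")))
  }
  if (!is.null(res$metrics)) {
    write.table(res$metrics, file.path(outDir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$metrics, file.path(outDir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(outDir)
}
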