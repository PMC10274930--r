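#' Build the backbone string graph from reads and overlaps
#'
#' Nodes are reads; edges are dovetail overlaps. Edges are taken from
#' overlaps with divergence at most `maxEdgeDiv` (default 0: with
#' corrected-grade accurate reads only perfect overlaps define edges,
#' which keeps haplotype branches separate while truly homozygous and
#' exact-repeat regions still collapse). When a pair admits several
#' placements the longest is kept (ties: smaller `aStart`, then same
#' strand first).
#'
#' With `keepContained = TRUE` contained reads stay in the graph as
#' flagged nodes, connected through their own genuine dovetail overlaps
#' (any dovetail implied by a containment placement is itself a reported
#' overlap, because the contained read matches its container exactly).
#' With `keepContained = FALSE` contained reads are dropped before node
#' creation, giving the classic string graph.
#'
#' @param seqs named character vector (or DNAStringSet) of reads.
#' @param overlaps data.frame from [findReadOverlaps()].
#' @param keepContained keep contained reads as provisional nodes.
#' @param maxEdgeDiv maximum divergence of an overlap used as an edge.
#' @param dropReads read ids removed outright (used to delete removable
#'   contained reads after ultra-long rescue).
#' @param minEdgeOvlp minimum overlap length (bp) for an overlap to
#'   become an edge. Within-haplotype adjacencies at adequate coverage
#'   overlap by most of a read length, while a perfect cross-haplotype
#'   overlap must fit inside an SNV-free window and is therefore short;
#'   a threshold of a few tenths of the read length suppresses spurious
#'   haplotype-bridging edges without costing real connectivity.
#'   Truly homozygous stretches longer than the reads, and exact
#'   repeats, still collapse. As a safeguard against local coverage
#'   dips, a read end whose overlaps all fall below the threshold keeps
#'   its single longest overlap, so the filter can thin branches but
#'   never disconnect a read end. 0 disables the filter.
#' @return a read-level [StringGraph].
#' @export
buildStringGraph <- function(seqs, overlaps, keepContained = TRUE,
                             maxEdgeDiv = 0, dropReads = character(0),
                             minEdgeOvlp = 0L) {
  if (!is.character(seqs)) seqs <- setNames(as.character(seqs), names(seqs))
  ids <- names(seqs)
  bad <- setdiff(unique(c(overlaps$aId, overlaps$bId)), ids)
  if (length(bad)) stop("overlap references unknown read: ", bad[1L])
  ov <- overlaps[overlaps$identity >= 1 - maxEdgeDiv - 1e-12, , drop = FALSE]
  cls <- classifyContained(ov, ids)
  removed <- as.character(dropReads)
  if (!keepContained) removed <- union(removed, cls$contained)
  present <- setdiff(ids, removed)

  dov <- ov[ov$kind == "dovetail" & ov$aId %in% present & ov$bId %in% present, ,
            drop = FALSE]
  if (nrow(dov)) {
    sameFirst <- as.integer(dov$strand != "same")
    o <- order(dov$aId, dov$bId, -dov$ovLen, dov$aStart, sameFirst)
    dov <- dov[o, , drop = FALSE]
    dov <- dov[!duplicated(dov[, c("aId", "bId")]), , drop = FALSE]
  }
  lens <- nchar(seqs)
  if (nrow(dov) && minEdgeOvlp > 0L) {
    # side of each read the overlap uses: suffix (+) or prefix (-)
    aSide <- paste0(dov$aId, ifelse(dov$aEnd == lens[dov$aId], "+", "-"))
    bSide <- paste0(dov$bId, ifelse(dov$bEnd == lens[dov$bId], "+", "-"))
    sideMax <- tapply(rep(dov$ovLen, 2L), c(aSide, bSide), max)[c(aSide, bSide)]
    aMax <- sideMax[seq_len(nrow(dov))]
    bMax <- sideMax[nrow(dov) + seq_len(nrow(dov))]
    keep <- dov$ovLen >= minEdgeOvlp |
      (dov$ovLen == aMax & aMax < minEdgeOvlp) |
      (dov$ovLen == bMax & bMax < minEdgeOvlp)
    dov <- dov[keep, , drop = FALSE]
  }
  nodes <- data.frame(id = present, len = as.integer(lens[present]),
                      contained = present %in% cls$contained,
                      seq = unname(seqs[present]), stringsAsFactors = FALSE)
  arcs <- .emptyArcs()
  if (nrow(dov)) {
    la <- lens[dov$aId]; lb <- lens[dov$bId]
    from <- character(nrow(dov)); fo <- character(nrow(dov))
    to <- character(nrow(dov)); oo <- character(nrow(dov))
    for (r in seq_len(nrow(dov))) {
      if (dov$strand[r] == "same") {
        if (dov$aEnd[r] == la[r] && dov$bStart[r] == 0L) {
          from[r] <- dov$aId[r]; fo[r] <- "+"; to[r] <- dov$bId[r]; oo[r] <- "+"
        } else if (dov$aStart[r] == 0L && dov$bEnd[r] == lb[r]) {
          from[r] <- dov$bId[r]; fo[r] <- "+"; to[r] <- dov$aId[r]; oo[r] <- "+"
        } else stop("internal: inconsistent dovetail placement")
      } else {
        if (dov$aEnd[r] == la[r] && dov$bEnd[r] == lb[r]) {
          from[r] <- dov$aId[r]; fo[r] <- "+"; to[r] <- dov$bId[r]; oo[r] <- "-"
        } else if (dov$aStart[r] == 0L && dov$bStart[r] == 0L) {
          from[r] <- dov$aId[r]; fo[r] <- "-"; to[r] <- dov$bId[r]; oo[r] <- "+"
        } else stop("internal: inconsistent dovetail placement")
      }
    }
    arcs <- .addEdges(arcs, from, fo, to, oo, dov$ovLen)
  }
  g <- new("StringGraph", nodes = nodes, arcs = arcs,
           params = list(keepContained = keepContained, maxEdgeDiv = maxEdgeDiv,
                         minEdgeOvlp = minEdgeOvlp,
                         nContained = sum(nodes$contained),
                         containers = cls$containers))
  validObject(g)
  g
}

#' Transitive reduction of a string graph
#'
#' Removes every edge implied by a two-edge path of the input graph whose
#' total extension length matches the edge's within `fuzz` bp. The
#' removal set is defined against the input edge set (not the shrinking
#' one), so it is order-independent and, because extension lengths
#' decrease strictly along evidence, connectivity between read ends is
#' preserved.
#'
#' @param g a [StringGraph].
#' @param fuzz tolerated length discrepancy (bp).
#' @return the reduced [StringGraph].
#' @export
transitiveReduction <- function(g, fuzz = 10L) {
  len <- setNames(g@nodes$len, g@nodes$id)
  g@arcs <- .transReduceArcs(g@arcs, len, fuzz)
  g@params$fuzz <- fuzz
  g
}

# shared reduction core: removes arcs implied by a two-edge path of the
# INPUT arc set with extension-length agreement within fuzz
.transReduceArcs <- function(a, len, fuzz) {
  if (!nrow(a)) return(a)
  ext <- len[a$to] - a$ovlp
  byFrom <- split(seq_len(nrow(a)), .okey(a$from, a$fromOrient))
  drop <- logical(nrow(a))
  for (k in names(byFrom)) {
    rows <- byFrom[[k]]
    if (length(rows) < 2L) next
    maxExt <- max(ext[rows])
    for (i in rows) {                     # evidence first hop v -> w
      w <- a$to[i]; ow <- a$toOrient[i]
      if (.okey(w, ow) == k) next         # self continuation guard
      second <- byFrom[[.okey(w, ow)]]
      if (is.null(second)) next
      for (j in second) {                 # second hop w -> x
        if (a$to[j] == a$from[i] || a$to[j] == w) next
        tot <- ext[i] + ext[j]
        if (tot > maxExt + fuzz) next
        hit <- rows[a$to[rows] == a$to[j] & a$toOrient[rows] == a$toOrient[j] &
                      abs(ext[rows] - tot) <= fuzz & rows != i]
        drop[hit] <- TRUE
      }
    }
  }
  if (any(drop)) a <- .dropEdges(a, unique(a$edgeId[drop]))
  a
}

.pathBp <- function(g, p) {
  len <- setNames(g@nodes$len, g@nodes$id)
  total <- sum(len[p$node])
  if (nrow(p) > 1L) {
    a <- g@arcs
    for (j in seq_len(nrow(p) - 1L)) {
      hit <- a$from == p$node[j] & a$fromOrient == p$orient[j] &
        a$to == p$node[j + 1L] & a$toOrient == p$orient[j + 1L]
      total <- total - a$ovlp[which(hit)[1L]]
    }
  }
  total
}

#' Conservative cleaning of the backbone graph
#'
#' Removes short dead-end chains (tips) and pops bubble branches carried
#' by fewer than `minEdgeReads` reads. Cleaning at this stage is
#' deliberately conservative: competing edges at branch points are left
#' alone because ultra-long support will arbitrate them later
#' ([weightedClean()]); heterozygous bubbles whose branches are each
#' supported by `minEdgeReads` or more reads are retained as the phasing
#' substrate.
#'
#' @param g a transitively reduced [StringGraph].
#' @param tipLen maximum chain length (bp) removed as a tip.
#' @param minEdgeReads bubble branches with fewer member reads are
#'   popped as artifacts.
#' @return the cleaned [StringGraph].
#' @export
cleanGraph <- function(g, tipLen = 45000L, minEdgeReads = 2L) {
  for (round in 1:5) {
    changed <- FALSE
    # --- tips -------------------------------------------------------------
    mp <- .maximalPaths(g@nodes$id, g@arcs)
    deg <- .outDeg(g@arcs)
    toDrop <- character(0)
    for (p in mp$paths) {
      np <- nrow(p)
      outEnd <- .outDegOf(deg, p$node[np], p$orient[np])
      outStart <- .outDegOf(deg, p$node[1L], .flipO(p$orient[1L]))
      deadEnd <- outEnd == 0L
      deadStart <- outStart == 0L
      if (xor(deadEnd, deadStart) && .pathBp(g, p) < tipLen)
        toDrop <- c(toDrop, p$node)
    }
    if (length(toDrop)) {
      g@nodes <- g@nodes[!(g@nodes$id %in% toDrop), , drop = FALSE]
      g@arcs <- .dropNodesArcs(g@arcs, toDrop)
      changed <- TRUE
    }
    # --- low-support bubble branches -------------------------------------
    pop <- .popWeakBubbles(g, minEdgeReads)
    if (length(pop)) {
      g@nodes <- g@nodes[!(g@nodes$id %in% pop), , drop = FALSE]
      g@arcs <- .dropNodesArcs(g@arcs, pop)
      changed <- TRUE
    }
    if (!changed) break
  }
  g@params$tipLen <- tipLen
  g@params$minEdgeReads <- minEdgeReads
  g
}

# walk a non-branching chain from (v,o) for at most maxN nodes; returns
# list(nodes, endNode, endOrient) where endNode/endOrient is the first
# oriented node after the chain (branch or dead end), or NULL
.walkChain <- function(g, v, o, deg, maxN = 30L) {
  nodes <- character(0)
  repeat {
    outs <- g@arcs[g@arcs$from == v & g@arcs$fromOrient == o, , drop = FALSE]
    if (nrow(outs) != 1L) return(list(nodes = nodes, endNode = NULL))
    w <- outs$to[1L]; ow <- outs$toOrient[1L]
    indegW <- .outDegOf(deg, w, .flipO(ow))
    if (indegW > 1L || .outDegOf(deg, w, ow) != 1L)
      return(list(nodes = nodes, endNode = w, endOrient = ow))
    nodes <- c(nodes, w)
    if (length(nodes) > maxN) return(list(nodes = nodes, endNode = NULL))
    v <- w; o <- ow
  }
}

.popWeakBubbles <- function(g, minEdgeReads) {
  deg <- .outDeg(g@arcs)
  a <- g@arcs
  pop <- character(0)
  keys <- names(deg)[deg == 2L]
  for (k in keys) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    v <- parts[1L]; o <- parts[2L]
    outs <- a[a$from == v & a$fromOrient == o, , drop = FALSE]
    if (nrow(outs) != 2L) next
    b1 <- .walkChain(g, outs$to[1L], outs$toOrient[1L], deg)
    b2 <- .walkChain(g, outs$to[2L], outs$toOrient[2L], deg)
    if (is.null(b1$endNode) || is.null(b2$endNode)) next
    if (b1$endNode != b2$endNode || b1$endOrient != b2$endOrient) next
    br1 <- c(outs$to[1L], b1$nodes); br2 <- c(outs$to[2L], b2$nodes)
    if (length(intersect(br1, br2))) next
    n1 <- length(br1); n2 <- length(br2)
    if (n1 < minEdgeReads && n2 >= minEdgeReads) pop <- c(pop, br1)
    else if (n2 < minEdgeReads && n1 >= minEdgeReads) pop <- c(pop, br2)
  }
  unique(pop)
}

#' Collapse maximal non-branching paths into unitigs
#'
#' @param g a cleaned read-level (or unitig-level) [StringGraph].
#' @param idPrefix prefix for the new unitig identifiers.
#' @return list with `graph` (unitig-level [StringGraph] whose `members`
#'   table records read placements) and `map` (old node -> new node,
#'   orientation, index and bp offset within the path).
#' @export
makeUnitigs <- function(g, idPrefix = "u") {
  .condenseGraph(g, idPrefix)
}
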