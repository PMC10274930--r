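#' Align ultra-long reads to the unitig graph
#'
#' Minimizer anchors (window minima of canonical k-mer codes) are
#' collected per unitig, collapsed into per-unitig linear segments along
#' exact diagonals (the substitution-only error model needs no indel
#' band), and chained across unitig-graph edges by dynamic programming.
#' A transition across an edge is allowed when the implied gap on both
#' the read and the graph is at most `maxGap`; its penalty is
#' `gapPen * |read gap - graph gap|`, and anchors already covered by the
#' previous segment do not score again. Ties between equal-scoring routes
#' prefer fewer chain nodes, then longer nodes, then the smaller unitig
#' id, so a chain skips a redundant contained node when a longer
#' container explains the same read interval.
#'
#' @param ulSeqs named character vector (or DNAStringSet) of ultra-long
#'   reads.
#' @param ug unitig-level [StringGraph] (from [makeUnitigs()]).
#' @param k,w minimizer k-mer size and window.
#' @param maxGap maximum implied gap (bp) across an edge transition.
#' @param gapPen penalty per bp of gap-length discrepancy.
#' @param gapSlack discrepancy below this many bp is not penalized: it is
#'   within the positional resolution of minimizer anchors (about one
#'   window plus one k-mer), and penalizing it would break score ties
#'   between equivalent routes pseudo-randomly instead of leaving them to
#'   the deterministic tie-break. Defaults to `k + w`.
#' @param minAnchors chains with fewer total anchors are reported
#'   unaligned.
#' @param minUniqueTerm terminal chain elements are kept only when
#'   anchored by at least this many uniquely-placed minimizers (k-mers
#'   occurring once in the whole unitig index). A read may start or end
#'   inside repeat sequence, where every anchor is multi-placed and any
#'   choice among the repeat copies would be arbitrary; such terminal
#'   elements are trimmed, and repeat traversal is left to the reads
#'   that extend into unique sequence on both sides.
#' @return list with `alignments` (named list; each has `ul`, `ulLen`,
#'   `chain` data.frame (node, orient, ulStart, ulEnd, nodeStart,
#'   nodeEnd, anchors; node coordinates in traversal orientation) and
#'   `score`) and `unaligned` (character vector of read ids).
#' @export
alignUL <- function(ulSeqs, ug, k = 17L, w = 11L, maxGap = 2000L,
                    gapPen = 0.01, gapSlack = k + w, minAnchors = 3L,
                    minUniqueTerm = 3L) {
  if (!is.character(ulSeqs)) ulSeqs <- setNames(as.character(ulSeqs), names(ulSeqs))
  stopifnot(is(ug, "StringGraph"))
  ulen <- setNames(ug@nodes$len, ug@nodes$id)

  # index EVERY unitig k-mer (reads are minimizer-sketched): anchor
  # counts over identical sequences are then exactly equal whatever the
  # unitig boundaries, so equivalent routes tie exactly and fall through
  # to the deterministic tie-break
  idxL <- lapply(seq_len(nrow(ug@nodes)), function(i) {
    ck <- .canonKmers(ug@nodes$seq[i], k)
    keep <- which(!is.na(ck$code))
    if (!length(keep)) return(NULL)
    data.table(code = ck$code[keep], upos = keep - 1L, ufwd = ck$fwd[keep],
               unitig = ug@nodes$id[i])
  })
  idx <- rbindlist(idxL[!vapply(idxL, is.null, logical(1))])
  alignments <- list(); unaligned <- character(0)
  if (!nrow(idx)) return(list(alignments = alignments, unaligned = names(ulSeqs)))
  idx[, cnt := .N, by = code]
  setkey(idx, code)

  # predecessor lookup: for oriented unitig (u,o), which oriented unitigs
  # have an arc into it, and with what overlap
  a <- ug@arcs
  predKey <- .okey(a$to, a$toOrient)
  preds <- split(data.frame(from = a$from, fromOrient = a$fromOrient,
                            ovlp = a$ovlp, stringsAsFactors = FALSE), predKey)

  for (ulId in names(ulSeqs)) {
    s <- ulSeqs[[ulId]]
    qsk <- .minimizerSketch(s, k, w)
    if (!nrow(qsk)) { unaligned <- c(unaligned, ulId); next }
    q <- data.table(code = qsk$code, qpos = qsk$pos, qfwd = qsk$fwd)
    hits <- idx[q, on = "code", allow.cartesian = TRUE, nomatch = NULL]
    if (!nrow(hits)) { unaligned <- c(unaligned, ulId); next }
    same <- hits$ufwd == hits$qfwd
    tl <- ulen[hits$unitig]
    tpos <- ifelse(same, hits$upos, tl - k - hits$upos)  # traversal coords
    segdt <- data.table(unitig = hits$unitig,
                        orient = ifelse(same, "+", "-"),
                        diag = hits$qpos - tpos, qpos = hits$qpos, tpos = tpos,
                        cnt = hits$cnt)
    segs <- segdt[, .(ulStart = min(qpos), ulEnd = max(qpos) + k,
                      nodeStart = min(tpos), nodeEnd = max(tpos) + k,
                      anchors = .N, uniq = sum(cnt == 1L),
                      ulPos = list(sort(qpos))),
                  by = .(unitig, orient, diag)]
    setorder(segs, ulStart, ulEnd, unitig, orient)
    S <- nrow(segs)
    segKey <- .okey(segs$unitig, segs$orient)
    segIdxByKey <- split(seq_len(S), segKey)

    dp <- segs$anchors * 1.0
    nNodes <- rep(1L, S); totLen <- unname(ulen[segs$unitig]); pred <- rep(0L, S)
    sUlStart <- segs$ulStart; sUlEnd <- segs$ulEnd
    sNodeStart <- segs$nodeStart; sNodeEnd <- segs$nodeEnd
    sUnitig <- segs$unitig
    segLen <- unname(ulen[sUnitig])
    for (i in seq_len(S)) {
      pk <- preds[[segKey[i]]]
      if (is.null(pk)) next
      js <- integer(0); ovs <- integer(0)
      for (pi in seq_len(nrow(pk))) {
        jj <- segIdxByKey[[.okey(pk$from[pi], pk$fromOrient[pi])]]
        if (!is.null(jj)) { js <- c(js, jj); ovs <- c(ovs, rep(pk$ovlp[pi], length(jj))) }
      }
      if (!length(js)) next
      ok <- js != i & sUlStart[js] <= sUlStart[i] & sUlEnd[js] < sUlEnd[i]
      js <- js[ok]; ovs <- ovs[ok]
      if (!length(js)) next
      ulGap <- sUlStart[i] - sUlEnd[js]
      graphGap <- (segLen[js] - sNodeEnd[js]) + sNodeStart[i] - ovs
      ok <- ulGap <= maxGap & graphGap <= maxGap & graphGap >= -(ovs + 2L * k)
      js <- js[ok]; ulGap <- ulGap[ok]; graphGap <- graphGap[ok]
      if (!length(js)) next
      # count only anchors strictly after the previous segment's last
      # anchor start (ulEnd - k), so every anchor scores exactly once and
      # equivalent routes tie exactly
      up <- segs$ulPos[[i]]
      contrib <- length(up) - findInterval(sUlEnd[js] - k, up)
      cand <- dp[js] + contrib - gapPen * pmax(0, abs(ulGap - graphGap) - gapSlack)
      o <- order(-cand, nNodes[js], -totLen[js], sUnitig[js], js)[1L]
      if (cand[o] > dp[i] + 1e-9) {
        j <- js[o]
        dp[i] <- cand[o]; nNodes[i] <- nNodes[j] + 1L
        totLen[i] <- totLen[j] + segLen[i]; pred[i] <- j
      }
    }
    bi <- which(dp == max(dp))
    if (length(bi) > 1L) {
      o <- order(nNodes[bi], -totLen[bi], segs$unitig[bi])
      bi <- bi[o[1L]]
    }
    chainIdx <- bi
    while (pred[chainIdx[1L]] != 0L) chainIdx <- c(pred[chainIdx[1L]], chainIdx)
    # trim repeat-ambiguous terminal elements
    while (length(chainIdx) > 1L && segs$uniq[chainIdx[1L]] < minUniqueTerm)
      chainIdx <- chainIdx[-1L]
    while (length(chainIdx) > 1L && segs$uniq[chainIdx[length(chainIdx)]] < minUniqueTerm)
      chainIdx <- chainIdx[-length(chainIdx)]
    ch <- segs[chainIdx, .(node = unitig, orient, ulStart, ulEnd,
                           nodeStart, nodeEnd, anchors)]
    score <- dp[bi]
    if (sum(ch$anchors) < minAnchors) { unaligned <- c(unaligned, ulId); next }
    alignments[[ulId]] <- list(ul = ulId, ulLen = nchar(s),
                               chain = as.data.frame(ch), score = score)
  }
  list(alignments = alignments, unaligned = unaligned)
}

#' Project chained alignments to integer sequences
#'
#' Keeps only the oriented unitig identifiers of each chain ("integer
#' space"): +id for forward traversal, -id for reverse. Unaligned reads
#' are absent from the output.
#'
#' @param alignments `alignments` element of [alignUL()] output (or the
#'   full output list).
#' @return named list of signed integer vectors.
#' @export
encodeInteger <- function(alignments) {
  if (!is.null(alignments$alignments)) alignments <- alignments$alignments
  out <- lapply(alignments, function(al) {
    ch <- al$chain
    if (is.null(ch) || !nrow(ch)) return(NULL)
    ids <- as.integer(sub("^[A-Za-z]+", "", ch$node))
    ifelse(ch$orient == "-", -ids, ids)
  })
  out[!vapply(out, is.null, logical(1))]
}

.unitigName <- function(ids, prefix = "u") paste0(prefix, abs(ids))
.elemOrient <- function(ids) ifelse(ids < 0L, "-", "+")

# arc lookup table keyed by directed statement
.arcLookup <- function(arcs) {
  setNames(as.list(seq_len(nrow(arcs))),
           paste(arcs$from, arcs$fromOrient, arcs$to, arcs$toOrient, sep = "\r"))
}

#' Count ultra-long support for every unitig-graph edge
#'
#' `support(e)` is the number of distinct ultra-long reads whose integer
#' sequence contains `e`'s oriented unitig pair in either direction.
#'
#' @param iseqs named list of signed integer vectors ([encodeInteger()]).
#' @param ug unitig-level [StringGraph].
#' @param prefix unitig id prefix used in the graph.
#' @return `ug` with the `support` column of its arcs filled.
#' @export
computeEdgeSupport <- function(iseqs, ug, prefix = "u") {
  a <- ug@arcs
  if (nrow(a)) a$support <- 0L
  known <- ug@nodes$id
  lut <- .arcLookup(a)
  pairs <- list(); pi <- 0L
  for (ulId in names(iseqs)) {
    e <- iseqs[[ulId]]
    nm <- .unitigName(e, prefix)
    badIds <- setdiff(nm, known)
    if (length(badIds)) stop("integer sequence '", ulId,
                             "' references unknown unitig ", badIds[1L])
    if (length(e) < 2L) next
    oo <- .elemOrient(e)
    for (j in seq_len(length(e) - 1L)) {
      row <- lut[[paste(nm[j], oo[j], nm[j + 1L], oo[j + 1L], sep = "\r")]]
      if (is.null(row)) next
      pi <- pi + 1L
      pairs[[pi]] <- c(ulId, a$edgeId[row])
    }
  }
  if (pi) {
    m <- unique(do.call(rbind, pairs))
    tab <- table(m[, 2L])
    eid <- as.integer(names(tab))
    a$support <- as.integer(tab[match(as.character(a$edgeId), names(tab))])
    a$support[is.na(a$support)] <- 0L
  }
  ug@arcs <- a
  ug
}

#' Rescue critical contained reads with ultra-long coverage
#'
#' A contained read is critical when at least `minRescue` distinct
#' ultra-long chains traverse a unitig interval that fully contains its
#' placement; other contained reads are removable. With no ultra-long
#' data every contained read is removable and the graph degenerates to
#' the classic string graph.
#'
#' @param alignments output of [alignUL()] on the keep-contained graph.
#' @param ug the unitig-level [StringGraph] that was aligned to.
#' @param minRescue minimum number of covering ultra-long chains.
#' @param slack coverage tolerance (bp) absorbing the anchor resolution
#'   of the aligner (about one minimizer window plus one k-mer).
#' @return list with `critical`, `removable` (character vectors of read
#'   ids) and `coverCounts` (named integer vector).
#' @export
rescueContained <- function(alignments, ug, minRescue = 2L, slack = 30L) {
  if (!is.null(alignments$alignments)) alignments <- alignments$alignments
  m <- ug@members
  cm <- m[m$contained, , drop = FALSE]
  if (!nrow(cm))
    return(list(critical = character(0), removable = character(0),
                coverCounts = setNames(integer(0), character(0))))
  ulen <- setNames(ug@nodes$len, ug@nodes$id)
  counts <- setNames(rep(0L, nrow(cm)), cm$read)
  for (al in alignments) {
    ch <- al$chain
    if (is.null(ch) || !nrow(ch)) next
    hit <- rep(FALSE, nrow(cm))
    for (j in seq_len(nrow(ch))) {
      rows <- which(cm$unitig == ch$node[j])
      if (!length(rows)) next
      L <- ulen[[ch$node[j]]]
      fs <- if (ch$orient[j] == "-") L - ch$nodeEnd[j] else ch$nodeStart[j]
      fe <- if (ch$orient[j] == "-") L - ch$nodeStart[j] else ch$nodeEnd[j]
      hit[rows] <- hit[rows] | (fs <= cm$start[rows] + slack &
                                  fe >= cm$end[rows] - slack)
    }
    counts[hit] <- counts[hit] + 1L
  }
  list(critical = unique(cm$read[counts >= minRescue]),
       removable = unique(cm$read[counts < minRescue]),
       coverCounts = counts)
}

#' Support-weighted cleaning of the unitig graph
#'
#' At every node side with more than one edge: if at least one edge has
#' ultra-long support >= `minSupport`, all zero-support competitors on
#' that side are cut; if no edge is supported, only the longest-overlap
#' edge is retained (the classic length heuristic as fallback). The graph
#' is re-unitigged afterwards and the integer sequences are remapped onto
#' the merged unitigs (and split where an adjacency they used was cut).
#'
#' @param ug unitig-level [StringGraph] with support filled
#'   ([computeEdgeSupport()]).
#' @param iseqs named list of signed integer vectors to remap (optional).
#' @param minSupport support threshold.
#' @param prefix unitig id prefix of `ug` (and of the re-unitigged graph).
#' @return list with `graph` (re-unitigged [StringGraph]), `iseqs`
#'   (remapped integer sequences) and `map`.
#' @export
weightedClean <- function(ug, iseqs = NULL, minSupport = 1L, prefix = "u") {
  a <- ug@arcs
  dropIds <- integer(0)
  if (nrow(a)) {
    byFrom <- split(seq_len(nrow(a)), .okey(a$from, a$fromOrient))
    for (rows in byFrom) {
      if (length(rows) < 2L) next
      s <- a$support[rows]
      if (any(s >= minSupport)) {
        dropIds <- c(dropIds, a$edgeId[rows[s == 0L]])
      } else {
        len <- setNames(ug@nodes$len, ug@nodes$id)
        o <- order(-a$ovlp[rows], -len[a$to[rows]], a$to[rows])
        dropIds <- c(dropIds, a$edgeId[rows[o[-1L]]])
      }
    }
  }
  g2 <- ug
  if (length(dropIds)) g2@arcs <- .dropEdges(a, unique(dropIds))
  cg <- .condenseGraph(g2, prefix)
  out <- list(graph = cg$graph, map = cg$map, dropped = unique(dropIds))
  if (!is.null(iseqs)) out$iseqs <- remapIntegerSeqs(iseqs, cg$map, cg$graph, prefix)
  out
}

#' Remap integer sequences through a graph condensation
#'
#' Translates each element to its new unitig, collapses runs of elements
#' absorbed into one new unitig, and splits a sequence wherever two
#' consecutive remapped elements are no longer joined by an edge (for
#' example because the edge was cut). Split fragments are suffixed
#' `.1`, `.2`, ...
#'
#' @param iseqs named list of signed integer vectors.
#' @param map condensation map (from [makeUnitigs()] / [weightedClean()]).
#' @param ug the condensed [StringGraph].
#' @param prefix unitig id prefix.
#' @return named list of signed integer vectors.
#' @export
remapIntegerSeqs <- function(iseqs, map, ug, prefix = "u") {
  lut <- .arcLookup(ug@arcs)
  res <- list()
  for (ulId in names(iseqs)) {
    e <- iseqs[[ulId]]
    nm <- .unitigName(e, prefix)
    r <- map[nm, , drop = FALSE]
    newNum <- as.integer(sub("^[A-Za-z]+", "", r$new))
    dirSign <- ifelse(r$orientInPath == "+", 1L, -1L) * sign(e)
    newE <- newNum * dirSign
    idx <- r$idx
    # collapse runs within one new unitig walked in a consistent direction
    keep <- rep(TRUE, length(newE))
    if (length(newE) > 1L) {
      for (j in 2:length(newE)) {
        # a forward traversal of the new unitig consumes old members in
        # increasing idx, a reverse traversal in decreasing idx
        if (newE[j] == newE[j - 1L] && idx[j] == idx[j - 1L] + sign(newE[j]))
          keep[j] <- FALSE
      }
    }
    newE <- newE[keep]
    if (!length(newE)) next
    # split where adjacencies are no longer edges
    nm2 <- .unitigName(newE, prefix)
    oo2 <- .elemOrient(newE)
    cut <- logical(length(newE) - 1L)
    if (length(newE) > 1L) {
      for (j in seq_len(length(newE) - 1L)) {
        cut[j] <- is.null(lut[[paste(nm2[j], oo2[j], nm2[j + 1L], oo2[j + 1L],
                                     sep = "\r")]])
      }
    }
    if (!any(cut)) {
      res[[ulId]] <- newE
    } else {
      grp <- cumsum(c(0L, cut))
      frags <- split(newE, grp)
      for (fi in seq_along(frags))
        res[[paste0(ulId, ".", fi)]] <- unname(frags[[fi]])
    }
  }
  res
}
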