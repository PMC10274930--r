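#' Reverse an integer sequence
#'
#' Reverses the element order and flips every orientation; an involution.
#'
#' @param s signed integer vector (+id forward, -id reverse).
#' @return the reversed signed integer vector.
#' @export
reverseISeq <- function(s) rev(-s)

# lexicographic comparison of signed integer vectors; elements are
# ordered by unitig id first, forward before reverse, and a shorter
# prefix wins ties. Used for canonical contig orientation.
.iseqLeq <- function(x, y) {
  n <- min(length(x), length(y))
  for (j in seq_len(n)) {
    ax <- abs(x[j]); ay <- abs(y[j])
    if (ax != ay) return(ax < ay)
    if (x[j] != y[j]) return(x[j] > 0L)   # + before -
  }
  length(x) <= length(y)
}

#' Exact overlaps between integer sequences
#'
#' Only exact matches are allowed in integer space: a dovetail of length
#' `l` means the last `l` oriented elements of `a` equal the first `l` of
#' `b` (after reversing `b` for opposite-strand placements), with
#' `l < min(length(a), length(b))`; a containment means one sequence is a
#' contiguous oriented run inside the other. All placements of length at
#' least `minIov` are reported, one row each; `a` is the sequence earlier
#' in the input.
#'
#' @param iseqs named list of signed integer vectors.
#' @param minIov minimum shared oriented elements.
#' @return data.frame with columns `a`, `b`, `strand` ("same"/
#'   "opposite"), `kind` ("dovetail"/"containment"), `aEnd` ("suffix" if
#'   the suffix of `a` overlaps the prefix of oriented `b`, "prefix" for
#'   the mirror case; NA for containments), `len` (shared elements),
#'   `shift` (containment offset of the contained sequence inside the
#'   container; NA for dovetails) and `contained` ("a"/"b"/NA).
#' @export
integerOverlaps <- function(iseqs, minIov = 1L) {
  nms <- names(iseqs)
  if (is.null(nms) || anyDuplicated(nms)) stop("integer sequences must have unique names")
  empty <- data.frame(a = character(0), b = character(0), strand = character(0),
                      kind = character(0), aEnd = character(0), len = integer(0),
                      shift = integer(0), contained = character(0),
                      stringsAsFactors = FALSE)
  n <- length(iseqs)
  if (n < 2L) return(empty)
  # candidate pairs share at least one absolute element id
  elemIdx <- list()
  for (i in seq_len(n)) {
    for (u in unique(abs(iseqs[[i]])))
      elemIdx[[as.character(u)]] <- c(elemIdx[[as.character(u)]], i)
  }
  cand <- unique(do.call(rbind, lapply(elemIdx, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })))
  if (is.null(cand)) return(empty)
  rows <- list(); ri <- 0L
  emit <- function(...) { ri <<- ri + 1L; rows[[ri]] <<- list(...) }
  for (r in seq_len(nrow(cand))) {
    ia <- cand[r, 1L]; ib <- cand[r, 2L]
    a <- iseqs[[ia]]; la <- length(a)
    for (strand in c("same", "opposite")) {
      b <- if (strand == "same") iseqs[[ib]] else reverseISeq(iseqs[[ib]])
      lb <- length(b)
      # containment: the shorter inside the longer (ties: b contained)
      if (lb <= la) {
        for (t in 0:(la - lb)) {
          if (all(a[(t + 1L):(t + lb)] == b) && lb >= minIov)
            emit(a = nms[ia], b = nms[ib], strand = strand, kind = "containment",
                 aEnd = NA_character_, len = lb, shift = t, contained = "b")
        }
      } else {
        for (t in 0:(lb - la)) {
          if (all(b[(t + 1L):(t + la)] == a) && la >= minIov)
            emit(a = nms[ia], b = nms[ib], strand = strand, kind = "containment",
                 aEnd = NA_character_, len = la, shift = t, contained = "a")
        }
      }
      # dovetails, strictly shorter than both
      maxL <- min(la, lb) - 1L
      if (maxL >= minIov) {
        for (l in minIov:maxL) {
          if (all(a[(la - l + 1L):la] == b[1:l]))
            emit(a = nms[ia], b = nms[ib], strand = strand, kind = "dovetail",
                 aEnd = "suffix", len = l, shift = NA_integer_,
                 contained = NA_character_)
          if (all(b[(lb - l + 1L):lb] == a[1:l]))
            emit(a = nms[ia], b = nms[ib], strand = strand, kind = "dovetail",
                 aEnd = "prefix", len = l, shift = NA_integer_,
                 contained = NA_character_)
        }
      }
    }
  }
  if (!ri) return(empty)
  res <- do.call(rbind, lapply(rows[seq_len(ri)], function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  res <- res[order(res$a, res$b, res$strand, res$kind, res$len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the integer graph from integer sequences
#'
#' Contained integer sequences are dropped before node creation (an
#' ultra-long read is very unlikely to be a critical contained read, so
#' containment removal is safe in integer space), edges are the longest
#' exact dovetail per oriented pair, and the graph is transitively
#' reduced exactly (fuzz 0, in element units).
#'
#' @param iseqs named list of signed integer vectors.
#' @param overlaps optional precomputed [integerOverlaps()] output.
#' @param minIov minimum overlap (elements).
#' @return an [IntegerGraph].
#' @export
buildIntegerGraph <- function(iseqs, overlaps = NULL, minIov = 1L) {
  if (is.null(overlaps)) overlaps <- integerOverlaps(iseqs, minIov)
  ct <- overlaps[overlaps$kind == "containment", , drop = FALSE]
  dropped <- unique(ifelse(ct$contained == "a", ct$a, ct$b))
  keepSeqs <- iseqs[setdiff(names(iseqs), dropped)]
  dv <- overlaps[overlaps$kind == "dovetail" &
                   overlaps$a %in% names(keepSeqs) &
                   overlaps$b %in% names(keepSeqs), , drop = FALSE]
  arcs <- .emptyArcs()
  if (nrow(dv)) {
    from <- ifelse(dv$aEnd == "suffix", dv$a, dv$b)
    to <- ifelse(dv$aEnd == "suffix", dv$b, dv$a)
    fo <- ifelse(dv$aEnd == "suffix", "+",
                 ifelse(dv$strand == "same", "+", "-"))
    oo <- ifelse(dv$aEnd == "suffix",
                 ifelse(dv$strand == "same", "+", "-"), "+")
    key <- paste(from, fo, to, oo)
    o <- order(key, -dv$len)
    sel <- o[!duplicated(key[o])]       # longest per directed statement
    arcs <- .addEdges(arcs, from[sel], fo[sel], to[sel], oo[sel], dv$len[sel])
    len <- vapply(keepSeqs, length, integer(1))
    arcs <- .transReduceArcs(arcs, len, fuzz = 0L)
  }
  g <- new("IntegerGraph", iseqs = keepSeqs, arcs = arcs,
           dropped = as.character(dropped), params = list(minIov = minIov))
  validObject(g)
  g
}

#' Aggressive cleaning of the integer graph
#'
#' Ultra-long reads are long enough to walk through repetitive and
#' homozygous regions, so ambiguity at this level is treated as noise: at
#' every side of every node with more than one edge only the
#' longest-overlap edge is kept (ties: longer neighbour sequence, then
#' smaller id), short dead-end chains of at most `tipNodes` nodes are
#' removed, and the two rules iterate to a fixed point.
#'
#' @param ig an [IntegerGraph].
#' @param tipNodes maximum node count of a removed tip.
#' @return the cleaned [IntegerGraph].
#' @export
aggressiveClean <- function(ig, tipNodes = 2L) {
  len <- vapply(ig@iseqs, length, integer(1))
  repeat {
    a <- ig@arcs
    changed <- FALSE
    if (nrow(a)) {
      dropIds <- integer(0)
      byFrom <- split(seq_len(nrow(a)), .okey(a$from, a$fromOrient))
      for (rows in byFrom) {
        if (length(rows) < 2L) next
        o <- order(-a$ovlp[rows], -len[a$to[rows]], a$to[rows])
        dropIds <- c(dropIds, a$edgeId[rows[o[-1L]]])
      }
      if (length(dropIds)) {
        ig@arcs <- .dropEdges(a, unique(dropIds))
        changed <- TRUE
      }
    }
    # integer-space tips
    mp <- .maximalPaths(names(ig@iseqs), ig@arcs)
    deg <- .outDeg(ig@arcs)
    toDrop <- character(0)
    for (p in mp$paths) {
      np <- nrow(p)
      if (np > tipNodes) next
      outEnd <- .outDegOf(deg, p$node[np], p$orient[np])
      outStart <- .outDegOf(deg, p$node[1L], .flipO(p$orient[1L]))
      if (xor(outEnd == 0L, outStart == 0L)) toDrop <- c(toDrop, p$node)
    }
    if (length(toDrop)) {
      ig@iseqs <- ig@iseqs[setdiff(names(ig@iseqs), toDrop)]
      ig@arcs <- .dropNodesArcs(ig@arcs, toDrop)
      changed <- TRUE
    }
    if (!changed) break
  }
  ig@params$tipNodes <- tipNodes
  ig
}

#' Emit integer contigs from the cleaned integer graph
#'
#' One contig per maximal non-branching path; the element list is the
#' first node's elements followed by each successor's elements beyond the
#' overlap. Every contig is emitted in canonical orientation (the
#' lexicographically smaller of itself and its reverse).
#'
#' @param ig a cleaned [IntegerGraph].
#' @return list with `contigs` (named list `c1..` of signed integer
#'   vectors) and `provenance` (named list of member sequence ids).
#' @export
integerContigs <- function(ig) {
  mp <- .maximalPaths(names(ig@iseqs), ig@arcs)
  lut <- .arcLookup(ig@arcs)
  contigs <- list(); prov <- list()
  for (pi in seq_along(mp$paths)) {
    p <- mp$paths[[pi]]
    e <- ig@iseqs[[p$node[1L]]]
    if (p$orient[1L] == "-") e <- reverseISeq(e)
    if (nrow(p) > 1L) {
      for (j in 2:nrow(p)) {
        row <- lut[[paste(p$node[j - 1L], p$orient[j - 1L], p$node[j],
                          p$orient[j], sep = "\r")]]
        if (is.null(row)) stop("internal: path step without edge")
        ov <- ig@arcs$ovlp[row]
        nxt <- ig@iseqs[[p$node[j]]]
        if (p$orient[j] == "-") nxt <- reverseISeq(nxt)
        e <- c(e, nxt[(ov + 1L):length(nxt)])
      }
    }
    re <- reverseISeq(e)
    if (!.iseqLeq(e, re)) e <- re
    id <- paste0("c", pi)
    contigs[[id]] <- e
    prov[[id]] <- p$node
  }
  list(contigs = contigs, provenance = prov)
}
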