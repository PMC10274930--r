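# Internal bidirected-graph machinery shared by the read-level string
# graph, the unitig graph and the integer graph. Arcs follow the GFA
# L-line convention; every bidirected edge is stored as two directed
# statements sharing an edgeId (a single statement when the statement is
# its own reverse, i.e. a hairpin arc).

.flipO <- function(o) chartr("+-", "-+", o)

.revcomp <- function(s) chartr("ACGTNacgtn", "TGCANtgcan", stri_reverse(s))

.orientSeq <- function(s, o) ifelse(o == "-", .revcomp(s), s)

.okey <- function(id, o) paste0(id, "\r", o)

# Append bidirected edges (vectorized). Returns the augmented arc table.
.addEdges <- function(arcs, from, fromOrient, to, toOrient, ovlp, support = 0L) {
  n <- length(from)
  if (!n) return(arcs)
  base <- if (nrow(arcs)) max(arcs$edgeId) else 0L
  eid <- base + seq_len(n)
  fwd <- data.frame(from = from, fromOrient = fromOrient, to = to,
                    toOrient = toOrient, ovlp = as.integer(ovlp),
                    support = as.integer(rep_len(support, n)), edgeId = eid,
                    stringsAsFactors = FALSE)
  rev <- data.frame(from = to, fromOrient = .flipO(toOrient), to = from,
                    toOrient = .flipO(fromOrient), ovlp = as.integer(ovlp),
                    support = as.integer(rep_len(support, n)), edgeId = eid,
                    stringsAsFactors = FALSE)
  hair <- fwd$from == rev$from & fwd$fromOrient == rev$fromOrient &
    fwd$to == rev$to & fwd$toOrient == rev$toOrient
  rbind(arcs, fwd, rev[!hair, , drop = FALSE])
}

.dropEdges <- function(arcs, edgeIds) arcs[!(arcs$edgeId %in% edgeIds), , drop = FALSE]

.dropNodesArcs <- function(arcs, nodeIds) {
  arcs[!(arcs$from %in% nodeIds | arcs$to %in% nodeIds), , drop = FALSE]
}

# out-degree of every oriented node, as a named integer vector
.outDeg <- function(arcs) {
  if (!nrow(arcs)) return(integer(0))
  tab <- table(.okey(arcs$from, arcs$fromOrient))
  setNames(as.integer(tab), names(tab))
}

.outDegOf <- function(deg, id, o) {
  d <- deg[.okey(id, o)]
  ifelse(is.na(d), 0L, d)
}

# Connected components of the underlying undirected node graph.
# Returns a named integer vector: node id -> component index.
.components <- function(nodeIds, arcs) {
  comp <- setNames(seq_along(nodeIds), nodeIds)
  if (nrow(arcs)) {
    adj <- split(c(arcs$to, arcs$from), c(arcs$from, arcs$to))
    visited <- setNames(rep(FALSE, length(nodeIds)), nodeIds)
    ci <- 0L
    for (v in nodeIds) {
      if (visited[[v]]) next
      ci <- ci + 1L
      queue <- v
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        if (visited[[u]]) next
        visited[[u]] <- TRUE
        comp[[u]] <- ci
        nb <- adj[[u]]
        if (!is.null(nb)) queue <- c(queue, nb[!visited[nb]])
      }
    }
  }
  comp
}

.nComponents <- function(g) {
  if (!nrow(g@nodes)) return(0L)
  length(unique(.components(g@nodes$id, g@arcs)))
}

# ---------------------------------------------------------------------------
# Maximal non-branching paths.
#
# An arc is mergeable when it is the unique way out of its source's side
# and the unique way into its target's side. Maximal chains of mergeable
# arcs define unitigs / contigs. Self arcs are never mergeable.
# Returns list(paths = list of data.frame(node, orient),
#              consumed = edgeIds used inside paths).
.maximalPaths <- function(nodeIds, arcs) {
  deg <- .outDeg(arcs)
  if (nrow(arcs)) {
    merge_ok <- arcs$from != arcs$to &
      .outDegOf(deg, arcs$from, arcs$fromOrient) == 1L &
      .outDegOf(deg, arcs$to, .flipO(arcs$toOrient)) == 1L
  } else merge_ok <- logical(0)
  marc <- arcs[merge_ok, , drop = FALSE]
  succ <- list(); succEdge <- list()
  if (nrow(marc)) {
    k <- .okey(marc$from, marc$fromOrient)
    succ <- setNames(as.list(paste0(marc$to, "\r", marc$toOrient)), k)
    succEdge <- setNames(as.list(marc$edgeId), k)
    hasPred <- unique(.okey(marc$to, marc$toOrient))
  } else hasPred <- character(0)

  assigned <- setNames(rep(FALSE, length(nodeIds)), nodeIds)
  paths <- list()
  consumed <- integer(0)

  walk <- function(v, o) {
    pn <- v; po <- o
    repeat {
      s <- succ[[.okey(v, o)]]
      if (is.null(s)) break
      parts <- strsplit(s, "\r", fixed = TRUE)[[1L]]
      w <- parts[1L]; ow <- parts[2L]
      if (assigned[[w]] || w %in% pn) break  # cycle guard
      consumed <<- c(consumed, succEdge[[.okey(v, o)]])
      pn <- c(pn, w); po <- c(po, ow)
      v <- w; o <- ow
    }
    data.frame(node = pn, orient = po, stringsAsFactors = FALSE)
  }

  starts <- character(0)
  for (o in c("+", "-")) starts <- c(starts, .okey(nodeIds, o))
  starts <- sort(setdiff(starts, hasPred))
  for (s in starts) {
    parts <- strsplit(s, "\r", fixed = TRUE)[[1L]]
    v <- parts[1L]
    if (assigned[[v]]) next
    p <- walk(v, parts[2L])
    assigned[p$node] <- TRUE
    paths[[length(paths) + 1L]] <- p
  }
  # circular leftovers: break at the smallest remaining id
  while (any(!assigned)) {
    v <- sort(names(assigned)[!assigned])[1L]
    p <- walk(v, "+")
    assigned[p$node] <- TRUE
    paths[[length(paths) + 1L]] <- p
  }

  # canonical direction: smaller terminal node id first
  paths <- lapply(paths, function(p) {
    if (nrow(p) == 1L) { p$orient <- "+"; return(p) }
    if (p$node[1L] > p$node[nrow(p)])
      data.frame(node = rev(p$node), orient = .flipO(rev(p$orient)),
                 stringsAsFactors = FALSE)
    else p
  })
  ord <- order(vapply(paths, function(p) p$node[1L], character(1)))
  list(paths = paths[ord], consumed = unique(consumed))
}

# ---------------------------------------------------------------------------
# Condense maximal paths of a StringGraph into a new unitig-level
# StringGraph. Works both on read-level graphs (members built from the
# nodes) and on unitig-level graphs (members composed through the paths).
# Returns list(graph, map) where map is a data.frame
# (old, new, orientInPath, idx, bpOffset, oldLen).
.condenseGraph <- function(g, idPrefix = "u") {
  mp <- .maximalPaths(g@nodes$id, g@arcs)
  paths <- mp$paths
  len <- setNames(g@nodes$len, g@nodes$id)
  seqs <- setNames(g@nodes$seq, g@nodes$id)
  contained <- setNames(g@nodes$contained, g@nodes$id)
  haveSeq <- !anyNA(seqs)

  arcKey <- .okey(paste0(g@arcs$from, "\n", g@arcs$to),
                  paste0(g@arcs$fromOrient, g@arcs$toOrient))
  arcIdx <- split(seq_len(nrow(g@arcs)), arcKey)
  findArc <- function(v, o, w, ow) {
    i <- arcIdx[[.okey(paste0(v, "\n", w), paste0(o, ow))]]
    if (is.null(i)) stop("internal: missing arc ", v, o, " -> ", w, ow)
    i[[1L]]
  }

  nP <- length(paths)
  newIds <- paste0(idPrefix, seq_len(nP))
  newLen <- integer(nP); newSeq <- rep(NA_character_, nP)
  mapL <- vector("list", nP)
  memL <- vector("list", nP)
  oldMembers <- g@members
  readLevel <- nrow(oldMembers) == 0L

  for (i in seq_len(nP)) {
    p <- paths[[i]]
    np <- nrow(p)
    off <- integer(np)
    if (np > 1L) {
      ovs <- integer(np - 1L)
      for (j in seq_len(np - 1L)) {
        a <- g@arcs[findArc(p$node[j], p$orient[j], p$node[j + 1L], p$orient[j + 1L]), ]
        ovs[j] <- a$ovlp
      }
      off <- c(0L, cumsum(len[p$node[-np]] - ovs))
    }
    newLen[i] <- off[np] + len[[p$node[np]]]
    if (haveSeq) {
      pieces <- .orientSeq(seqs[p$node], p$orient)
      if (np > 1L)
        for (j in 2L:np) pieces[j] <- substr(pieces[j], ovs[j - 1L] + 1L, len[[p$node[j]]])
      newSeq[i] <- paste(pieces, collapse = "")
    }
    mapL[[i]] <- data.frame(old = p$node, new = newIds[i], orientInPath = p$orient,
                            idx = seq_len(np), bpOffset = as.integer(off),
                            oldLen = as.integer(len[p$node]),
                            stringsAsFactors = FALSE)
    if (readLevel) {
      memL[[i]] <- data.frame(unitig = newIds[i], idx = seq_len(np), read = p$node,
                              orient = p$orient, start = as.integer(off),
                              end = as.integer(off + len[p$node]),
                              contained = unname(contained[p$node]),
                              stringsAsFactors = FALSE)
    } else {
      sub <- lapply(seq_len(np), function(j) {
        m <- oldMembers[oldMembers$unitig == p$node[j], , drop = FALSE]
        q <- p$orient[j]; F <- off[j]; L <- len[[p$node[j]]]
        if (q == "-") {
          s <- F + L - m$end; e <- F + L - m$start
          m$start <- s; m$end <- e; m$orient <- .flipO(m$orient)
        } else {
          m$start <- m$start + F; m$end <- m$end + F
        }
        m$unitig <- newIds[i]
        m
      })
      mm <- do.call(rbind, sub)
      mm <- mm[order(mm$start, mm$end), , drop = FALSE]
      mm$idx <- seq_len(nrow(mm))
      memL[[i]] <- mm
    }
  }

  map <- do.call(rbind, mapL)
  rownames(map) <- map$old
  members <- do.call(rbind, memL)
  rownames(members) <- NULL

  nodes <- data.frame(id = newIds, len = newLen,
                      contained = FALSE, seq = newSeq, stringsAsFactors = FALSE)

  # map surviving (non-consumed) edges onto path ends
  newArcs <- .emptyArcs()
  keep <- g@arcs[!(g@arcs$edgeId %in% mp$consumed), , drop = FALSE]
  if (nrow(keep)) {
    keep <- keep[!duplicated(keep$edgeId), , drop = FALSE]
    endOf <- function(v, o) {
      r <- map[v, ]
      pl <- paths[[match(r$new, newIds)]]
      npl <- nrow(pl)
      if (r$orientInPath == o) {
        if (r$idx != npl) stop("internal: branching arc leaves path interior")
        c(r$new, "+")
      } else {
        if (r$idx != 1L) stop("internal: branching arc leaves path interior")
        c(r$new, "-")
      }
    }
    startOf <- function(w, ow) {
      r <- map[w, ]
      pl <- paths[[match(r$new, newIds)]]
      npl <- nrow(pl)
      if (r$orientInPath == ow) {
        if (r$idx != 1L) stop("internal: branching arc enters path interior")
        c(r$new, "+")
      } else {
        if (r$idx != npl) stop("internal: branching arc enters path interior")
        c(r$new, "-")
      }
    }
    fr <- t(mapply(endOf, keep$from, keep$fromOrient))
    to <- t(mapply(startOf, keep$to, keep$toOrient))
    newArcs <- .addEdges(newArcs, fr[, 1L], fr[, 2L], to[, 1L], to[, 2L],
                         keep$ovlp, keep$support)
  }

  ug <- new("StringGraph", nodes = nodes, arcs = newArcs, members = members,
            params = c(g@params, list(condensedFrom = nrow(g@nodes))))
  validObject(ug)
  list(graph = ug, map = map)
}
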