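#' Spell the nucleotide sequence of a unitig walk
#'
#' Concatenates the oriented unitig sequences of a walk, trimming each
#' successor by the overlap of the joining edge.
#'
#' @param elements signed integer vector of oriented unitig ids.
#' @param ug unitig-level [StringGraph] with sequences.
#' @param prefix unitig id prefix.
#' @return a character string of length
#'   `sum(lengths) - sum(overlaps)`.
#' @export
spellSequence <- function(elements, ug, prefix = "u") {
  nm <- .unitigName(elements, prefix)
  bad <- setdiff(nm, ug@nodes$id)
  if (length(bad)) stop("walk references unknown unitig: ", bad[1L])
  oo <- .elemOrient(elements)
  seqs <- setNames(ug@nodes$seq, ug@nodes$id)
  lut <- .arcLookup(ug@arcs)
  out <- .orientSeq(seqs[[nm[1L]]], oo[1L])
  if (length(elements) > 1L) {
    for (j in 2:length(elements)) {
      row <- lut[[paste(nm[j - 1L], oo[j - 1L], nm[j], oo[j], sep = "\r")]]
      if (is.null(row))
        stop("missing edge between consecutive walk elements ",
             nm[j - 1L], oo[j - 1L], " -> ", nm[j], oo[j])
      ov <- ug@arcs$ovlp[row]
      s <- .orientSeq(seqs[[nm[j]]], oo[j])
      out <- paste0(out, substr(s, ov + 1L, nchar(s)))
    }
  }
  out
}

#' Incorporate integer contigs into the backbone unitig graph
#'
#' Every unitig appearing in any integer contig is removed from the
#' residual set; contig-backed nodes are added with their spelled
#' sequences; boundary edges are reconstructed from the unitig-graph
#' edges at the contig ends towards the remaining residual unitigs (and
#' residual-residual edges are carried over). A unitig shared by several
#' contigs backs several nodes of the final graph.
#'
#' @param ug unitig-level [StringGraph].
#' @param contigs named list of signed integer vectors (or the output of
#'   [integerContigs()]).
#' @param prefix unitig id prefix.
#' @return a [MergedGraph].
#' @export
incorporateContigs <- function(ug, contigs, prefix = "u") {
  if (!is.null(contigs$contigs)) contigs <- contigs$contigs
  allIds <- ug@nodes$id
  for (cid in names(contigs)) {
    bad <- setdiff(.unitigName(contigs[[cid]], prefix), allIds)
    if (length(bad)) stop("contig ", cid, " references unknown unitig ", bad[1L])
  }
  covered <- unique(unlist(lapply(contigs, function(e) .unitigName(e, prefix))))
  residual <- setdiff(allIds, covered)
  useqs <- setNames(ug@nodes$seq, ug@nodes$id)
  ulen <- setNames(ug@nodes$len, ug@nodes$id)

  elements <- list(); seqs <- character(0)
  ids <- character(0); origin <- character(0); lens <- integer(0)
  for (cid in names(contigs)) {
    e <- contigs[[cid]]
    sq <- spellSequence(e, ug, prefix)
    ids <- c(ids, cid); origin <- c(origin, "contig"); lens <- c(lens, nchar(sq))
    elements[[cid]] <- e
    seqs[cid] <- sq
  }
  resNum <- as.integer(sub(paste0("^", prefix), "", residual))
  for (j in seq_along(residual)) {
    rid <- residual[j]
    ids <- c(ids, rid); origin <- c(origin, "residual")
    lens <- c(lens, ulen[[rid]])
    elements[[rid]] <- resNum[j]
    seqs[rid] <- useqs[[rid]]
  }

  a <- ug@arcs
  arcs <- .emptyArcs()
  resArcs <- a[a$from %in% residual & a$to %in% residual, , drop = FALSE]
  if (nrow(resArcs)) {
    one <- resArcs[!duplicated(resArcs$edgeId), , drop = FALSE]
    arcs <- .addEdges(arcs, one$from, one$fromOrient, one$to, one$toOrient,
                      one$ovlp, one$support)
  }
  for (cid in names(contigs)) {
    e <- elements[[cid]]
    lastN <- .unitigName(e[length(e)], prefix); lastO <- .elemOrient(e[length(e)])
    outs <- a[a$from == lastN & a$fromOrient == lastO & a$to %in% residual, ,
              drop = FALSE]
    if (nrow(outs))
      arcs <- .addEdges(arcs, rep(cid, nrow(outs)), rep("+", nrow(outs)),
                        outs$to, outs$toOrient, outs$ovlp, outs$support)
    firstN <- .unitigName(e[1L], prefix); firstO <- .elemOrient(e[1L])
    ins <- a[a$to == firstN & a$toOrient == firstO & a$from %in% residual, ,
             drop = FALSE]
    if (nrow(ins))
      arcs <- .addEdges(arcs, ins$from, ins$fromOrient,
                        rep(cid, nrow(ins)), rep("+", nrow(ins)),
                        ins$ovlp, ins$support)
  }
  mg <- new("MergedGraph",
            nodes = data.frame(id = ids, origin = origin, len = lens,
                               stringsAsFactors = FALSE),
            elements = elements, seqs = seqs, arcs = arcs,
            params = list(prefix = prefix, nCovered = length(covered)))
  validObject(mg)
  mg
}

#' Build haplotype-specific k-mer marker sets
#'
#' The marker set of source `i` holds the canonical k-mers present in
#' source `i` and absent from every other source; the sets are pairwise
#' disjoint by construction. Sources emulate parental short-read k-mer
#' databases (trio mode: pass each parent the union of its two
#' haplotypes) or per-haplotype truth sequences (genetic-map emulation
#' for polyploids).
#'
#' @param sources named list; each element a character vector of
#'   sequences for one haplotype source.
#' @param k marker k-mer size.
#' @return named list of character vectors of canonical k-mers.
#' @export
buildMarkers <- function(sources, k = 31L) {
  if (length(sources) < 2L) stop("need at least 2 haplotype sources")
  if (is.null(names(sources))) stop("sources must be named")
  sets <- lapply(sources, function(ss)
    unique(unlist(lapply(ss, .canonKmerStrings, k = k), use.names = FALSE)))
  out <- list()
  for (i in seq_along(sets)) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    out[[names(sources)[i]]] <- setdiff(sets[[i]], others)
  }
  out
}

#' Count haplotype markers on every node of the final graph
#'
#' @param mg a [MergedGraph] (or unitig-level [StringGraph]).
#' @param markers named list from [buildMarkers()]; `k` is inferred from
#'   the marker strings.
#' @return integer matrix, nodes x haplotype labels: occurrences of each
#'   haplotype's markers in each node's sequence.
#' @export
assignMarkers <- function(mg, markers) {
  seqs <- nodeSeqs(mg)
  labs <- names(markers)
  out <- matrix(0L, nrow = length(seqs), ncol = length(labs),
                dimnames = list(names(seqs), labs))
  nonEmpty <- which(lengths(markers) > 0L)
  if (!length(nonEmpty)) return(out)   # fully homozygous sources
  k <- nchar(markers[[nonEmpty[1L]]][1L])
  for (nid in names(seqs)) {
    km <- .canonKmerStrings(seqs[[nid]], k)
    if (!length(km)) next
    for (h in labs) out[nid, h] <- sum(km %in% markers[[h]])
  }
  out
}

.dominantLabels <- function(counts, minMarkers = 2L, domRatio = 2.0) {
  labs <- colnames(counts)
  apply(counts, 1L, function(v) {
    mx <- max(v)
    if (mx < minMarkers) return(NA_character_)
    top <- which(v == mx)
    if (length(top) > 1L) return(NA_character_)
    second <- if (length(v) > 1L) max(v[-top]) else 0L
    if (second > 0 && mx < domRatio * second) return(NA_character_)
    labs[top]
  })
}

#' Emit one haplotype's assembly by graph binning
#'
#' Every node whose dominant marker label differs from `hap` is deleted
#' (dominance: the maximum count, requiring at least `minMarkers` markers
#' and a `domRatio` advantage over the runner-up); unlabeled nodes -
#' homozygous regions - are retained in every haplotype's emission. The
#' surviving graph's maximal non-branching paths are spelled into
#' contigs. Ploidy 2 and above use the same rule; the diploid case is
#' simply the two-label special case.
#'
#' @param mg a [MergedGraph].
#' @param counts marker count matrix from [assignMarkers()].
#' @param hap haplotype label (a column name of `counts`).
#' @param minMarkers,domRatio dominance thresholds.
#' @param dedupe drop contigs whose sequence (either strand) is an exact
#'   substring of a longer emitted contig - unlabeled residual stubs
#'   whose content an incorporated contig already spells out.
#' @return list with `hap`, `contigs` (named character vector),
#'   `provenance` (list of data.frames node/orient per contig),
#'   `nodeLabels` (dominant label per node, NA = unlabeled).
#' @export
graphBinning <- function(mg, counts, hap, minMarkers = 2L, domRatio = 2.0,
                         dedupe = TRUE) {
  if (!(hap %in% colnames(counts)))
    stop("unknown haplotype label: ", hap)
  dom <- .dominantLabels(counts, minMarkers, domRatio)
  keep <- mg@nodes$id[is.na(dom[mg@nodes$id]) | dom[mg@nodes$id] == hap]
  arcs <- mg@arcs[mg@arcs$from %in% keep & mg@arcs$to %in% keep, , drop = FALSE]
  mp <- .maximalPaths(keep, arcs)
  lut <- .arcLookup(arcs)
  seqs <- mg@seqs
  contigs <- character(0); prov <- list()
  for (pi in seq_along(mp$paths)) {
    p <- mp$paths[[pi]]
    s <- .orientSeq(seqs[[p$node[1L]]], p$orient[1L])
    if (nrow(p) > 1L) {
      for (j in 2:nrow(p)) {
        row <- lut[[paste(p$node[j - 1L], p$orient[j - 1L], p$node[j],
                          p$orient[j], sep = "\r")]]
        ov <- arcs$ovlp[row]
        nx <- .orientSeq(seqs[[p$node[j]]], p$orient[j])
        s <- paste0(s, substr(nx, ov + 1L, nchar(nx)))
      }
    }
    cid <- sprintf("%s_ctg%d", hap, pi)
    contigs[cid] <- s
    prov[[cid]] <- p
  }
  if (dedupe && length(contigs) > 1L) {
    o <- order(-nchar(contigs))
    drop <- character(0)
    for (i in seq_along(o)[-1L]) {
      ci <- contigs[[o[i]]]
      for (j in seq_len(i - 1L)) {
        if (names(contigs)[o[j]] %in% drop) next
        cj <- contigs[[o[j]]]
        if (grepl(ci, cj, fixed = TRUE) ||
            grepl(.revcomp(ci), cj, fixed = TRUE)) {
          drop <- c(drop, names(contigs)[o[i]])
          break
        }
      }
    }
    contigs <- contigs[setdiff(names(contigs), drop)]
    prov <- prov[names(contigs)]
  }
  list(hap = hap, contigs = contigs, provenance = prov,
       nodeLabels = dom)
}

#' Emit all haplotype assemblies
#'
#' @param mg a [MergedGraph].
#' @param counts marker count matrix from [assignMarkers()].
#' @param minMarkers,domRatio dominance thresholds (see
#'   [graphBinning()]).
#' @return named list of [graphBinning()] results, one per label.
#' @export
binAllHaplotypes <- function(mg, counts, minMarkers = 2L, domRatio = 2.0) {
  labs <- colnames(counts)
  setNames(lapply(labs, function(h)
    graphBinning(mg, counts, h, minMarkers, domRatio)), labs)
}
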