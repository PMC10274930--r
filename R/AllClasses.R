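#' @title Core graph classes
#' @description S4 containers for the bidirected assembly graphs used
#'   throughout the package. All three classes share one arc encoding:
#'   each bidirected edge is stored as two directed statements
#'   (from, fromOrient, to, toOrient) that share an `edgeId`, following
#'   the GFA L-line convention: the suffix of `from` read in orientation
#'   `fromOrient` overlaps the prefix of `to` read in orientation
#'   `toOrient` by `ovlp` units (bp for sequence graphs, elements for the
#'   integer graph).
#' @name duograph-classes
NULL

.emptyArcs <- function() {
  data.frame(from = character(0), fromOrient = character(0),
             to = character(0), toOrient = character(0),
             ovlp = integer(0), support = integer(0), edgeId = integer(0),
             stringsAsFactors = FALSE)
}

.emptyMembers <- function() {
  data.frame(unitig = character(0), idx = integer(0), read = character(0),
             orient = character(0), start = integer(0), end = integer(0),
             contained = logical(0), stringsAsFactors = FALSE)
}

#' StringGraph: bidirected string graph over reads or unitigs
#'
#' Nodes are reads (read-level graph) or unitigs (after condensation);
#' edges are dovetail overlaps. `nodes` has columns `id`, `len`,
#' `contained`, `seq` (NA for schematic graphs). `members` is non-empty
#' only for unitig-level graphs and records each constituent read's
#' placement `[start, end)` on the unitig's forward strand.
#'
#' @slot nodes data.frame of node id, length, contained flag, sequence.
#' @slot arcs data.frame of directed arc statements (two per edge).
#' @slot members data.frame mapping reads into unitigs.
#' @slot params list of provenance parameters.
#' @exportClass StringGraph
setClass("StringGraph",
  representation(nodes = "data.frame", arcs = "data.frame",
                 members = "data.frame", params = "list"),
  prototype(nodes = data.frame(id = character(0), len = integer(0),
                               contained = logical(0), seq = character(0),
                               stringsAsFactors = FALSE),
            arcs = .emptyArcs(), members = .emptyMembers(), params = list()))

setValidity("StringGraph", function(object) {
  n <- object@nodes; a <- object@arcs
  msg <- character(0)
  if (!all(c("id", "len", "contained", "seq") %in% names(n)))
    msg <- c(msg, "nodes must have columns id, len, contained, seq")
  if (anyDuplicated(n$id)) msg <- c(msg, "duplicate node ids")
  if (nrow(a)) {
    if (!all(a$from %in% n$id) || !all(a$to %in% n$id))
      msg <- c(msg, "arc references unknown node")
    if (!all(a$fromOrient %in% c("+", "-")) || !all(a$toOrient %in% c("+", "-")))
      msg <- c(msg, "arc orientations must be + or -")
    len <- setNames(n$len, n$id)
    if (any(a$ovlp >= pmin(len[a$from], len[a$to])))
      msg <- c(msg, "arc overlap must be shorter than both incident nodes")
    # bidirected symmetry: every statement has its reverse under the same edgeId
    key <- paste(a$from, a$fromOrient, a$to, a$toOrient, a$edgeId)
    rkey <- paste(a$to, .flipO(a$toOrient), a$from, .flipO(a$fromOrient), a$edgeId)
    if (!all(rkey %in% key)) msg <- c(msg, "missing reverse arc statement")
  }
  if (length(msg)) msg else TRUE
})

#' IntegerGraph: string graph over integer-encoded ultra-long reads
#'
#' Each node is an ultra-long read encoded as a signed integer vector of
#' oriented unitig identifiers (+id forward, -id reverse). Edges are
#' exact suffix-prefix overlaps in integer space; `ovlp` counts shared
#' elements.
#'
#' @slot iseqs named list of signed integer vectors (graph nodes).
#' @slot arcs data.frame of directed arc statements (two per edge).
#' @slot dropped character vector of contained sequences removed at
#'   construction.
#' @slot params list of provenance parameters.
#' @exportClass IntegerGraph
setClass("IntegerGraph",
  representation(iseqs = "list", arcs = "data.frame",
                 dropped = "character", params = "list"),
  prototype(iseqs = list(), arcs = .emptyArcs(),
            dropped = character(0), params = list()))

setValidity("IntegerGraph", function(object) {
  a <- object@arcs
  msg <- character(0)
  if (nrow(a)) {
    if (!all(a$from %in% names(object@iseqs)) || !all(a$to %in% names(object@iseqs)))
      msg <- c(msg, "arc references unknown integer sequence")
    len <- vapply(object@iseqs, length, integer(1))
    if (any(a$ovlp < 1L) || any(a$ovlp > pmin(len[a$from], len[a$to])))
      msg <- c(msg, "integer overlap length out of range")
  }
  if (length(msg)) msg else TRUE
})

#' MergedGraph: final assembly graph after contig incorporation
#'
#' Nodes are either integer-contig-backed (`origin == "contig"`) or
#' residual unitigs of the backbone (`origin == "residual"`). `elements`
#' stores each node's walk through the backbone unitig graph as a signed
#' integer vector; a unitig id may back several nodes.
#'
#' @slot nodes data.frame with columns id, origin, len.
#' @slot elements named list of signed integer unitig walks per node.
#' @slot seqs named character vector of spelled node sequences.
#' @slot arcs data.frame of directed arc statements (two per edge).
#' @slot params list of provenance parameters.
#' @exportClass MergedGraph
setClass("MergedGraph",
  representation(nodes = "data.frame", elements = "list", seqs = "character",
                 arcs = "data.frame", params = "list"),
  prototype(nodes = data.frame(id = character(0), origin = character(0),
                               len = integer(0), stringsAsFactors = FALSE),
            elements = list(), seqs = character(0), arcs = .emptyArcs(),
            params = list()))

setValidity("MergedGraph", function(object) {
  msg <- character(0)
  if (!all(object@nodes$origin %in% c("contig", "residual")))
    msg <- c(msg, "node origin must be 'contig' or 'residual'")
  if (nrow(object@arcs)) {
    if (!all(object@arcs$from %in% object@nodes$id) ||
        !all(object@arcs$to %in% object@nodes$id))
      msg <- c(msg, "arc references unknown node")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn graphNodes number of nodes and edges shown compactly
#' @export
setMethod("show", "StringGraph", function(object) {
  lvl <- if (nrow(object@members)) "unitig-level" else "read-level"
  cat(sprintf("StringGraph (%s): %d nodes, %d edges", lvl,
              nrow(object@nodes), length(unique(object@arcs$edgeId))))
  if (any(object@nodes$contained))
    cat(sprintf(", %d contained", sum(object@nodes$contained)))
  cat("\n")
})

setMethod("show", "IntegerGraph", function(object) {
  cat(sprintf("IntegerGraph: %d integer sequences, %d edges, %d contained dropped\n",
              length(object@iseqs), length(unique(object@arcs$edgeId)),
              length(object@dropped)))
})

setMethod("show", "MergedGraph", function(object) {
  cat(sprintf("MergedGraph: %d contig nodes + %d residual unitigs, %d edges\n",
              sum(object@nodes$origin == "contig"),
              sum(object@nodes$origin == "residual"),
              length(unique(object@arcs$edgeId))))
})

#' Accessors for graph objects
#'
#' `graphNodes()` returns the node table, `graphArcs()` the directed arc
#' statements (two per bidirected edge), `graphMembers()` the read
#' membership table of a unitig-level [StringGraph], `integerSeqs()` the
#' integer sequences of an [IntegerGraph], and `nodeElements()` the
#' backbone walks of a [MergedGraph].
#'
#' @param x a graph object.
#' @return a data.frame (or named list for the list-valued accessors).
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname graphNodes
#' @export
setGeneric("graphArcs", function(x) standardGeneric("graphArcs"))
#' @rdname graphNodes
#' @export
setGeneric("graphMembers", function(x) standardGeneric("graphMembers"))
#' @rdname graphNodes
#' @export
setGeneric("integerSeqs", function(x) standardGeneric("integerSeqs"))
#' @rdname graphNodes
#' @export
setGeneric("nodeElements", function(x) standardGeneric("nodeElements"))
#' @rdname graphNodes
#' @export
setGeneric("nodeSeqs", function(x) standardGeneric("nodeSeqs"))

#' @rdname graphNodes
setMethod("graphNodes", "StringGraph", function(x) x@nodes)
#' @rdname graphNodes
setMethod("graphNodes", "MergedGraph", function(x) x@nodes)
#' @rdname graphNodes
setMethod("graphArcs", "StringGraph", function(x) x@arcs)
#' @rdname graphNodes
setMethod("graphArcs", "IntegerGraph", function(x) x@arcs)
#' @rdname graphNodes
setMethod("graphArcs", "MergedGraph", function(x) x@arcs)
#' @rdname graphNodes
setMethod("graphMembers", "StringGraph", function(x) x@members)
#' @rdname graphNodes
setMethod("integerSeqs", "IntegerGraph", function(x) x@iseqs)
#' @rdname graphNodes
setMethod("nodeElements", "MergedGraph", function(x) x@elements)
#' @rdname graphNodes
setMethod("nodeSeqs", "StringGraph", function(x) setNames(x@nodes$seq, x@nodes$id))
#' @rdname graphNodes
setMethod("nodeSeqs", "MergedGraph", function(x) x@seqs)
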