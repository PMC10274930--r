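#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]. Sequences are
#' uppercased, multi-line FASTA records are joined, and duplicate
#' identifiers are rejected. FASTQ qualities, when present, are kept in
#' `mcols(x)$qual`.
#'
#' @param path input file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return a [Biostrings::DNAStringSet] named by record id, in file order.
#' @export
readSeqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  x <- tryCatch(
    readDNAStringSet(path, format = format,
                     with.qualities = identical(format, "fastq")),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  # strip FASTA descriptions; keep the first token as the id
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id in '", path, "': ",
         names(x)[duplicated(names(x))][1L], call. = FALSE)
  if (any(nchar(names(x)) == 0L)) stop("empty sequence id in '", path, "'")
  if (any(lengths(x) == 0L)) stop("zero-length sequence in '", path, "'")
  ql <- if (identical(format, "fastq")) as.character(mcols(x)$qualities) else NULL
  x <- DNAStringSet(toupper(as.character(x)))
  if (!is.null(ql)) mcols(x)$qual <- ql
  x
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a named character vector or [Biostrings::DNAStringSet].
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @param qual optional per-record quality strings (FASTQ); defaults to
#'   `"I"` over the read length.
#' @return invisibly, `path`.
#' @export
writeSeqs <- function(x, path, format = c("fasta", "fastq"), qual = NULL) {
  format <- match.arg(format)
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- DNAStringSet(x)
  }
  if (format == "fastq") {
    # written directly: ultra-long records exceed the fixed line buffer
    # of the C fastq writer in Biostrings
    if (is.null(qual)) qual <- strrep("I", width(x))
    if (any(nchar(qual) != width(x)))
      stop("quality strings must match sequence lengths")
    writeLines(paste0("@", names(x), "\n", as.character(x), "\n+\n", qual),
               path)
  } else {
    writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' @importFrom Biostrings width
NULL

# ---------------------------------------------------------------------------
# GFA 1.0

#' Write an assembly graph as GFA 1.0
#'
#' One `S` line per node and one `L` line per bidirected edge, emitted
#' once in canonical orientation (the lexicographically smaller of the
#' two directed statements). Overlaps are written as `<int>M`; ultra-long
#' support is carried in the custom integer tag `ul:i`; node origin of a
#' [MergedGraph] in `or:Z`.
#'
#' @param graph a [StringGraph] or [MergedGraph].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeGfa <- function(graph, path) {
  validObject(graph)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  if (!nrow(graph@nodes)) return(invisible(path))
  if (is(graph, "MergedGraph")) {
    ids <- graph@nodes$id
    seqs <- ifelse(is.na(graph@seqs[ids]) | !nzchar(graph@seqs[ids]), "*",
                   graph@seqs[ids])
    writeLines(paste0("S\t", ids, "\t", seqs, "\tLN:i:", graph@nodes$len,
                      "\tor:Z:", graph@nodes$origin), con)
  } else {
    seqs <- ifelse(is.na(graph@nodes$seq), "*", graph@nodes$seq)
    writeLines(paste0("S\t", graph@nodes$id, "\t", seqs,
                      "\tLN:i:", graph@nodes$len), con)
  }
  a <- graph@arcs
  if (nrow(a)) {
    # one L line per edge, in the lexicographically smaller of the two
    # directed statements (strand-canonical emission)
    stmt <- paste(a$from, a$fromOrient, a$to, a$toOrient, sep = "\t")
    o <- order(a$edgeId, stmt)
    a2 <- a[o, , drop = FALSE][!duplicated(a$edgeId[o]), , drop = FALSE]
    writeLines(paste0("L\t", a2$from, "\t", a2$fromOrient, "\t", a2$to, "\t",
                      a2$toOrient, "\t", a2$ovlp, "M\tul:i:", a2$support), con)
  }
  invisible(path)
}

#' Read a GFA 1.0 assembly graph
#'
#' Parses `S` and `L` lines into a [StringGraph]. Segments written with
#' `*` sequences are restored with `NA` sequences and their `LN:i` tag
#' lengths.
#'
#' @param path GFA file path.
#' @return a [StringGraph].
#' @export
readGfa <- function(path) {
  lines <- readLines(path)
  sl <- strsplit(lines[startsWith(lines, "S\t")], "\t", fixed = TRUE)
  ll <- strsplit(lines[startsWith(lines, "L\t")], "\t", fixed = TRUE)
  tagVal <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
    if (length(hit)) sub("^[^:]+:[^:]+:", "", hit[1L]) else NA_character_
  }
  nodes <- if (length(sl)) {
    ids <- vapply(sl, `[[`, character(1), 2L)
    seqs <- vapply(sl, `[[`, character(1), 3L)
    lens <- vapply(sl, function(f) {
      ln <- tagVal(f[-(1:3)], "LN")
      if (!is.na(ln)) as.integer(ln) else nchar(f[[3L]])
    }, integer(1))
    data.frame(id = ids, len = lens, contained = FALSE,
               seq = ifelse(seqs == "*", NA_character_, seqs),
               stringsAsFactors = FALSE)
  } else data.frame(id = character(0), len = integer(0), contained = logical(0),
                    seq = character(0), stringsAsFactors = FALSE)
  arcs <- .emptyArcs()
  if (length(ll)) {
    fr <- vapply(ll, `[[`, character(1), 2L)
    fo <- vapply(ll, `[[`, character(1), 3L)
    to <- vapply(ll, `[[`, character(1), 4L)
    oo <- vapply(ll, `[[`, character(1), 5L)
    ov <- as.integer(sub("M$", "", vapply(ll, `[[`, character(1), 6L)))
    ul <- vapply(ll, function(f) {
      v <- tagVal(f[-(1:6)], "ul"); if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
    bad <- !(fr %in% nodes$id) | !(to %in% nodes$id)
    if (any(bad)) stop("GFA link references unknown segment: ",
                       paste(unique(c(fr[bad], to[bad])), collapse = ", "))
    arcs <- .addEdges(arcs, fr, fo, to, oo, ov, ul)
  }
  g <- new("StringGraph", nodes = nodes, arcs = arcs,
           params = list(source = path))
  validObject(g)
  g
}

# ---------------------------------------------------------------------------
# PAF

#' Write ultra-long graph alignments as PAF
#'
#' One line per linear alignment segment of each chained ultra-long
#' alignment; coordinates are 0-based half-open, target coordinates on
#' the unitig forward strand. The chain score is carried in the `cs:i`
#' tag and the anchor count in `cm:i`.
#'
#' @param alignments list of chained alignments as produced by [alignUL()].
#' @param path output file path.
#' @param ulLens optional named lengths of the ultra-long reads (bp);
#'   taken from the alignment objects when present.
#' @param unitigLens named lengths of the target unitigs (bp).
#' @return invisibly, `path`.
#' @export
writePaf <- function(alignments, path, ulLens = NULL, unitigLens = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (al in alignments) {
    ch <- al$chain
    if (is.null(ch) || !nrow(ch)) next
    qlen <- if (!is.null(al$ulLen)) al$ulLen
            else if (!is.null(ulLens)) ulLens[[al$ul]] else NA_integer_
    for (j in seq_len(nrow(ch))) {
      tl <- if (!is.null(unitigLens)) unitigLens[[ch$node[j]]]
            else if (!is.null(ch$nodeLen)) ch$nodeLen[j] else NA_integer_
      # traversal coords -> forward-strand target coords
      ts <- ch$nodeStart[j]; te <- ch$nodeEnd[j]
      if (ch$orient[j] == "-") { ts2 <- tl - te; te <- tl - ch$nodeStart[j]; ts <- ts2 }
      writeLines(paste(al$ul, qlen, ch$ulStart[j], ch$ulEnd[j],
                       ifelse(ch$orient[j] == "-", "-", "+"),
                       ch$node[j], tl, ts, te,
                       ch$anchors[j], max(te - ts, ch$ulEnd[j] - ch$ulStart[j]),
                       255L,
                       paste0("cs:i:", round(al$score)),
                       paste0("cm:i:", ch$anchors[j]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a PAF alignment file
#'
#' @param path PAF file path.
#' @return data.frame with the 12 standard PAF columns
#'   (qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
#'   nmatch, alen, mapq).
#' @export
readPaf <- function(path) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  lines <- readLines(path)
  if (!length(lines))
    return(setNames(data.frame(matrix(nrow = 0, ncol = 12)), cols))
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    qname = vapply(f, `[[`, character(1), 1L),
    qlen = as.integer(vapply(f, `[[`, character(1), 2L)),
    qstart = as.integer(vapply(f, `[[`, character(1), 3L)),
    qend = as.integer(vapply(f, `[[`, character(1), 4L)),
    strand = vapply(f, `[[`, character(1), 5L),
    tname = vapply(f, `[[`, character(1), 6L),
    tlen = as.integer(vapply(f, `[[`, character(1), 7L)),
    tstart = as.integer(vapply(f, `[[`, character(1), 8L)),
    tend = as.integer(vapply(f, `[[`, character(1), 9L)),
    nmatch = as.integer(vapply(f, `[[`, character(1), 10L)),
    alen = as.integer(vapply(f, `[[`, character(1), 11L)),
    mapq = as.integer(vapply(f, `[[`, character(1), 12L)),
    stringsAsFactors = FALSE)
  df
}
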