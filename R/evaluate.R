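#' Contig N50
#'
#' The largest length L such that contigs of length at least L sum to at
#' least half the total assembly length.
#'
#' @param lengths numeric vector of positive contig lengths.
#' @return the N50 (same units as the input).
#' @export
contigN50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

# exact placements of `pattern` (one orientation) on `subject`; anchors
# on a short prefix, then verifies full equality, so arbitrarily long
# contigs are handled
.exactPlacements <- function(pattern, subject) {
  lp <- nchar(pattern); ls <- nchar(subject)
  if (lp > ls) return(integer(0))
  aw <- min(lp, 64L)
  anchor <- substr(pattern, 1L, aw)
  hits <- Biostrings::start(matchPattern(anchor, subject))
  hits <- hits[hits + lp - 1L <= ls]
  hits[vapply(hits, function(st)
    substr(subject, st, st + lp - 1L) == pattern, logical(1))]
}

.teloSignal <- function(s, motif, window) {
  n <- nchar(s)
  w <- min(window, n)
  left <- substr(s, 1L, w); right <- substr(s, n - w + 1L, n)
  rc <- .revcomp(motif)
  hasL <- grepl(motif, left, fixed = TRUE) || grepl(rc, left, fixed = TRUE)
  hasR <- grepl(motif, right, fixed = TRUE) || grepl(rc, right, fixed = TRUE)
  hasL && hasR
}

#' Evaluate an assembly against a truth haplotype
#'
#' Coverage is measured by exact-match tiling of contigs (both strands)
#' onto the truth chromosomes (`mode = "exact"`, appropriate for
#' error-free simulations) or by canonical k-mer containment
#' (`mode = "kmer"`). Switch errors are counted as adjacent flips between
#' two different non-missing marker labels along each contig's node
#' path. A contig counts as telomere-to-telomere when the telomere motif
#' (or its reverse complement) occurs within `teloWindow` bp of both of
#' its ends.
#'
#' @param assembly named character vector of contig sequences.
#' @param truth named character vector of the haplotype's truth
#'   chromosome sequences.
#' @param teloMotif telomere motif.
#' @param minLen length filter for `nContigsGeMin` (the desk-scale
#'   analogue of a 500 kb filter).
#' @param labelPaths optional list (one element per contig) of node
#'   marker labels (NA = unlabeled) used for switch-error counting.
#' @param mode `"exact"` or `"kmer"`.
#' @param k k-mer size for `mode = "kmer"`.
#' @param teloWindow how far from a contig end the telomere motif may
#'   sit.
#' @return list with `nContigs`, `nContigsGeMin`, `totalLen`, `n50`,
#'   `coverage`, `switchErrors`, `t2tCount`.
#' @export
truthMetrics <- function(assembly, truth, teloMotif = "TTAGGG",
                         minLen = 5000L, labelPaths = NULL,
                         mode = c("exact", "kmer"), k = 31L,
                         teloWindow = 1000L) {
  mode <- match.arg(mode)
  if (missing(truth) || is.null(truth)) stop("truth sequences are required")
  lens <- nchar(assembly)
  nContigs <- length(assembly)
  totalLen <- sum(lens)
  n50 <- if (nContigs) contigN50(lens) else 0L

  if (mode == "exact") {
    covered <- 0; truthTotal <- 0
    for (chrom in truth) {
      truthTotal <- truthTotal + nchar(chrom)
      if (!nContigs) next
      iv <- list()
      for (ctg in assembly) {
        for (s in c(ctg, .revcomp(ctg))) {
          st <- .exactPlacements(s, chrom)
          if (length(st)) iv[[length(iv) + 1L]] <-
              IRanges(start = st, width = nchar(s))
        }
      }
      if (length(iv))
        covered <- covered + sum(width(reduce(do.call(c, iv))))
    }
    coverage <- if (truthTotal) covered / truthTotal else 0
  } else {
    tk <- unique(unlist(lapply(truth, .canonKmerStrings, k = k),
                        use.names = FALSE))
    ak <- unique(unlist(lapply(assembly, .canonKmerStrings, k = k),
                        use.names = FALSE))
    coverage <- if (length(tk)) mean(tk %in% ak) else 0
  }

  switchErrors <- 0L
  if (!is.null(labelPaths)) {
    for (lp in labelPaths) {
      lp <- lp[!is.na(lp)]
      if (length(lp) > 1L)
        switchErrors <- switchErrors + sum(lp[-1L] != lp[-length(lp)])
    }
  }
  t2t <- sum(vapply(assembly, .teloSignal, logical(1),
                    motif = teloMotif, window = teloWindow))
  list(nContigs = nContigs, nContigsGeMin = sum(lens >= minLen),
       totalLen = unname(totalLen), n50 = unname(n50), coverage = coverage,
       switchErrors = switchErrors, t2tCount = unname(t2t))
}
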