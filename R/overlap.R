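#' All-vs-all suffix-prefix and containment overlaps among accurate reads
#'
#' Candidate read pairs are found by shared canonical k-mer seeding
#' (every k-mer of every read is indexed; queries are sampled at a stride
#' that guarantees a seed inside any true overlap of length >= `minOvlp`).
#' Each distinct (pair, relative strand, diagonal) candidate is then
#' verified by gapless mismatch counting over the full implied placement,
#' which is exact for the substitution-only error model. Every placement
#' whose overlap region is at least `minOvlp` long and whose divergence
#' is at most `maxDiv` is reported exactly once; `a` is always the read
#' that comes first in the input.
#'
#' Non-ACGT bases (N) mismatch every base, including N itself.
#'
#' @param seqs named character vector (or DNAStringSet) of reads.
#' @param k seed k-mer size (11..25).
#' @param minOvlp minimum overlap length (bp), must be >= k.
#' @param maxDiv maximum divergence (1 - identity) of a reported overlap.
#' @return data.frame with one row per overlap placement: `aId`, `bId`,
#'   `strand` ("same"/"opposite"), `aStart`, `aEnd`, `bStart`, `bEnd`
#'   (0-based half-open, forward strand of each read), `kind`
#'   ("dovetail", "a_contains_b", "b_contains_a"), `identity`, `ovLen`.
#' @export
findReadOverlaps <- function(seqs, k = 21L, minOvlp = 250L, maxDiv = 0.02) {
  if (!is.character(seqs)) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("reads must have unique names")
  if (k < 11L || k > 25L) stop("k must be in 11..25")
  if (minOvlp < k) stop("minOvlp must be >= k")
  n <- length(seqs)
  empty <- data.frame(aId = character(0), bId = character(0), strand = character(0),
                      aStart = integer(0), aEnd = integer(0), bStart = integer(0),
                      bEnd = integer(0), kind = character(0), identity = numeric(0),
                      ovLen = integer(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ids <- names(seqs)
  lens <- nchar(seqs)

  fwdInt <- lapply(seqs, utf8ToInt)
  rcInt <- lapply(seqs, function(s) utf8ToInt(.revcomp(s)))

  idxL <- vector("list", n)
  for (i in seq_len(n)) {
    ck <- .canonKmers(seqs[[i]], k)
    keep <- which(!is.na(ck$code))
    idxL[[i]] <- data.table(code = ck$code[keep], pos = keep - 1L,
                            fwd = ck$fwd[keep], read = i)
  }
  idx <- rbindlist(idxL)
  if (!nrow(idx)) return(empty)
  setkey(idx, code)

  stride <- max(1L, as.integer(floor((minOvlp - k + 1L) / 2L)))
  qry <- rbindlist(lapply(idxL, function(d) {
    if (!nrow(d)) return(d)
    d[seq(1L, nrow(d), by = stride)]
  }))
  data.table::setnames(qry, c("code", "qpos", "qfwd", "qread"))

  hits <- idx[qry, on = "code", allow.cartesian = TRUE, nomatch = NULL]
  hits <- hits[qread < read]
  if (!nrow(hits)) return(empty)
  li <- lens[hits$read]
  sameStrand <- hits$fwd == hits$qfwd
  dvec <- ifelse(sameStrand, hits$qpos - hits$pos,
                 hits$qpos - (li - k - hits$pos))
  cand <- unique(data.table(a = hits$qread, b = hits$read,
                            same = sameStrand, d = as.integer(dvec)))

  cA <- cand$a; cB <- cand$b; cS <- cand$same; cD <- cand$d
  out <- vector("list", length(cA))
  nc <- utf8ToInt("N")
  m <- 0L
  for (r in seq_along(cA)) {
    ai <- cA[r]; bi <- cB[r]
    la <- lens[[ai]]; lb <- lens[[bi]]
    d <- cD[r]
    s <- max(0L, d); e <- min(la, d + lb)
    Lr <- e - s
    if (Lr < minOvlp) next
    av <- fwdInt[[ai]][(s + 1L):e]
    bv <- if (cS[r]) fwdInt[[bi]][(s - d + 1L):(e - d)]
          else rcInt[[bi]][(s - d + 1L):(e - d)]
    mism <- sum(av != bv | av == nc)
    if (mism > maxDiv * Lr) next
    kind <- if (d >= 0L && d + lb <= la) "a_contains_b"
            else if (d <= 0L && d + lb >= la) "b_contains_a"
            else "dovetail"
    bS <- s - d; bE <- e - d
    if (!cS[r]) { t <- lb - bE; bE <- lb - bS; bS <- t }
    m <- m + 1L
    out[[m]] <- list(aId = ids[ai], bId = ids[bi],
                     strand = if (cS[r]) "same" else "opposite",
                     aStart = s, aEnd = e, bStart = bS, bEnd = bE,
                     kind = kind, identity = 1 - mism / Lr, ovLen = Lr)
  }
  if (!m) return(empty)
  res <- do.call(rbind, lapply(out[seq_len(m)], function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  res <- res[order(res$aId, res$bId, res$strand, res$aStart, res$bStart), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Partition reads into contained and uncontained
#'
#' A read is contained when at least one overlap reports it as the fully
#' covered side (the overlap spans the whole read). Mutual containments
#' (identical placements) keep the earlier read as the container.
#'
#' @param overlaps data.frame from [findReadOverlaps()].
#' @param readIds optional universe of read ids (for the uncontained
#'   side); defaults to the ids appearing in `overlaps`.
#' @return list with `contained` and `uncontained` character vectors and
#'   `containers`, a named list mapping each contained read to its
#'   containers.
#' @export
classifyContained <- function(overlaps, readIds = NULL) {
  if (is.null(readIds)) readIds <- unique(c(overlaps$aId, overlaps$bId))
  contRead <- c(overlaps$bId[overlaps$kind == "a_contains_b"],
                overlaps$aId[overlaps$kind == "b_contains_a"])
  container <- c(overlaps$aId[overlaps$kind == "a_contains_b"],
                 overlaps$bId[overlaps$kind == "b_contains_a"])
  contained <- unique(contRead)
  containers <- split(container, contRead)
  # a container that is itself contained stays listed; the caller decides
  list(contained = contained,
       uncontained = setdiff(readIds, contained),
       containers = containers[contained])
}
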