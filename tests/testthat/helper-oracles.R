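# Independent brute-force oracles and small random-instance generators.

oracleRandSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                   collapse = "")

oracleRevcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# all-pairs, both strands, all diagonal placements, direct comparison
oracleOverlaps <- function(seqs, minOvlp, maxDiv = 0) {
  ids <- names(seqs)
  n <- length(seqs)
  ints <- lapply(seqs, utf8ToInt)
  rcints <- lapply(seqs, function(s) utf8ToInt(oracleRevcomp(s)))
  nc <- utf8ToInt("N")
  rows <- list()
  for (ia in seq_len(n - 1)) for (ib in (ia + 1):n) {
    la <- nchar(seqs[[ia]]); lb <- nchar(seqs[[ib]])
    for (strand in c("same", "opposite")) {
      bv <- if (strand == "same") ints[[ib]] else rcints[[ib]]
      for (d in (-(lb - 1)):(la - 1)) {
        s <- max(0L, d); e <- min(la, d + lb)
        L <- e - s
        if (L < minOvlp) next
        av <- ints[[ia]][(s + 1):e]
        bb <- bv[(s - d + 1):(e - d)]
        mism <- sum(av != bb | av == nc)
        if (mism > maxDiv * L) next
        kind <- if (d >= 0 && d + lb <= la) "a_contains_b"
                else if (d <= 0 && d + lb >= la) "b_contains_a"
                else "dovetail"
        bS <- s - d; bE <- e - d
        if (strand == "opposite") { t <- lb - bE; bE <- lb - bS; bS <- t }
        rows[[length(rows) + 1]] <- data.frame(
          aId = ids[ia], bId = ids[ib], strand = strand, aStart = s, aEnd = e,
          bStart = bS, bEnd = bE, kind = kind, identity = 1 - mism / L,
          ovLen = L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$aId, out$bId, out$strand, out$aStart, out$bStart), , drop = FALSE]
}

ovlKey <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$aId, df$bId, df$strand, df$aStart, df$aEnd, df$bStart, df$bEnd,
             df$kind, df$ovLen, sep = "|"))
}

# brute-force transitive-reduction oracle: an edge is removable iff some
# two-edge path of the ORIGINAL graph implies it within fuzz
oracleReducedEdgeIds <- function(g, fuzz) {
  a <- graphArcs(g)
  len <- setNames(graphNodes(g)$len, graphNodes(g)$id)
  ext <- len[a$to] - a$ovlp
  removable <- logical(nrow(a))
  for (ci in seq_len(nrow(a))) {
    v <- a$from[ci]; ov <- a$fromOrient[ci]
    x <- a$to[ci]; ox <- a$toOrient[ci]
    for (i in seq_len(nrow(a))) {
      if (i == ci) next
      if (a$from[i] != v || a$fromOrient[i] != ov) next
      w <- a$to[i]; ow <- a$toOrient[i]
      if (w == v && ow == ov) next
      for (j in seq_len(nrow(a))) {
        if (a$from[j] != w || a$fromOrient[j] != ow) next
        if (a$to[j] != x || a$toOrient[j] != ox) next
        if (a$to[j] == v || a$to[j] == w) next
        if (abs(ext[ci] - (ext[i] + ext[j])) <= fuzz) removable[ci] <- TRUE
      }
    }
  }
  unique(a$edgeId[removable])
}

# brute-force integer-overlap oracle: all pairs, both orientations, all
# shifts, direct vector comparison
oracleIntegerOverlaps <- function(iseqs, minIov = 1L) {
  nms <- names(iseqs)
  rows <- list()
  n <- length(iseqs)
  for (ia in seq_len(n - 1)) for (ib in (ia + 1):n) {
    a <- iseqs[[ia]]; la <- length(a)
    for (strand in c("same", "opposite")) {
      b <- if (strand == "same") iseqs[[ib]] else rev(-iseqs[[ib]])
      lb <- length(b)
      if (lb <= la) {
        for (t in 0:(la - lb)) if (lb >= minIov && all(a[(t + 1):(t + lb)] == b))
          rows[[length(rows) + 1]] <- data.frame(
            a = nms[ia], b = nms[ib], strand = strand, kind = "containment",
            aEnd = NA_character_, len = lb, shift = t, contained = "b",
            stringsAsFactors = FALSE)
      } else {
        for (t in 0:(lb - la)) if (la >= minIov && all(b[(t + 1):(t + la)] == a))
          rows[[length(rows) + 1]] <- data.frame(
            a = nms[ia], b = nms[ib], strand = strand, kind = "containment",
            aEnd = NA_character_, len = la, shift = t, contained = "a",
            stringsAsFactors = FALSE)
      }
      if (min(la, lb) - 1 >= minIov) {
        for (l in minIov:(min(la, lb) - 1)) {
          if (all(a[(la - l + 1):la] == b[1:l]))
            rows[[length(rows) + 1]] <- data.frame(
              a = nms[ia], b = nms[ib], strand = strand, kind = "dovetail",
              aEnd = "suffix", len = l, shift = NA_integer_,
              contained = NA_character_, stringsAsFactors = FALSE)
          if (all(b[(lb - l + 1):lb] == a[1:l]))
            rows[[length(rows) + 1]] <- data.frame(
              a = nms[ia], b = nms[ib], strand = strand, kind = "dovetail",
              aEnd = "prefix", len = l, shift = NA_integer_,
              contained = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

iovKey <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$a, df$b, df$strand, df$kind, ifelse(is.na(df$aEnd), ".", df$aEnd),
             df$len, ifelse(is.na(df$shift), ".", df$shift), sep = "|"))
}

# a small genome and reads tiled from it, some planted as exact
# substrings of others (contained)
randomReadInstance <- function(seed, nReads = 8, genomeLen = 2500,
                               readLen = c(500, 900), nContained = 2) {
  set.seed(seed)
  g <- oracleRandSeq(genomeLen)
  reads <- character(0)
  for (i in seq_len(nReads)) {
    len <- sample(readLen[1]:readLen[2], 1)
    s <- sample(0:(genomeLen - len), 1)
    r <- substr(g, s + 1, s + len)
    if (runif(1) < 0.5) r <- oracleRevcomp(r)
    reads[paste0("r", i)] <- r
  }
  for (i in seq_len(nContained)) {
    host <- sample(names(reads), 1)
    hl <- nchar(reads[[host]])
    len <- sample(250:min(400, hl - 10), 1)
    s <- sample(0:(hl - len), 1)
    r <- substr(reads[[host]], s + 1, s + len)
    if (runif(1) < 0.5) r <- oracleRevcomp(r)
    reads[paste0("c", i)] <- r
  }
  reads
}

# random signed integer sequences with planted suffix-prefix overlaps
randomISeqInstance <- function(seed, nSeqs = 12, alphabet = 15, lenRange = c(3, 10)) {
  set.seed(seed)
  out <- list()
  backbone <- sample(alphabet, 40, replace = TRUE) *
    sample(c(-1L, 1L), 40, replace = TRUE)
  for (i in seq_len(nSeqs)) {
    len <- sample(lenRange[1]:lenRange[2], 1)
    if (runif(1) < 0.7) {       # walk along a backbone so overlaps exist
      s <- sample(1:(40 - len), 1)
      e <- backbone[s:(s + len - 1)]
    } else {
      e <- sample(alphabet, len, replace = TRUE) *
        sample(c(-1L, 1L), len, replace = TRUE)
    }
    if (runif(1) < 0.5) e <- rev(-e)
    out[[paste0("s", i)]] <- as.integer(e)
  }
  out
}

# reads tiling one random region at fixed stride
tilingReads <- function(seed = 21, n = 3, step = 400, len = 1000) {
  set.seed(seed)
  g <- oracleRandSeq(step * (n - 1) + len)
  r <- vapply(seq_len(n), function(i)
    substr(g, (i - 1) * step + 1, (i - 1) * step + len), character(1))
  setNames(r, paste0("t", seq_len(n)))
}
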