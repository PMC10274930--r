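# Internal k-mer machinery. Sequences are handled as integer vectors
# (utf8 codes) with A/C/G/T mapped to 0..3; k-mer codes are exact base-4
# numbers stored as doubles, so k must stay below 26 (4^26 < 2^53) for
# the numeric paths. Marker k-mers (default k = 31) use the string path
# instead.

.BASE4 <- local({
  v <- rep(NA_real_, 256)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
  v
})

.seqCodes <- function(s) .BASE4[utf8ToInt(s)]

# k-mer codes at every start position (length n-k+1); NA where the
# window contains a non-ACGT base.
.kmerCodes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in seq_len(k)) out <- out * 4 + codes[j:(m + j - 1L)]
  out
}

# canonical codes + strand bit for every k-mer of a sequence string.
# strand TRUE means the forward k-mer is the canonical one.
.canonKmers <- function(s, k) {
  fc <- .kmerCodes(.seqCodes(s), k)
  if (!length(fc)) return(list(code = numeric(0), fwd = logical(0)))
  rcodes <- .seqCodes(.revcomp(s))
  rc <- rev(.kmerCodes(rcodes, k))  # rc[i] = code of revcomp of k-mer at i
  fwd <- !is.na(fc) & !is.na(rc) & fc <= rc
  list(code = pmin(fc, rc), fwd = fwd)
}

# sliding-window minimum over w consecutive k-mer codes; returns the
# positions (1-based k-mer start indices) of window minima (leftmost
# minimal position per window), the classic minimizer set.
.minimizerPos <- function(code, w) {
  n <- length(code)
  if (!n) return(integer(0))
  if (n <= w) {
    p <- which.min(code)
    return(if (length(p)) p else integer(0))
  }
  big <- max(code, na.rm = TRUE) + 1
  cd <- ifelse(is.na(code), big, code)
  m <- n - w + 1L
  winmin <- cd[1:m]
  for (j in 2:w) winmin <- pmin(winmin, cd[j:(m + j - 1L)])
  # leftmost minimal position per window: scan offsets right-to-left so
  # smaller offsets overwrite
  argmin <- rep(NA_integer_, m)
  for (j in w:1) {
    idx <- j:(m + j - 1L)
    hit <- cd[idx] == winmin
    argmin[hit] <- idx[hit]
  }
  sort(unique(argmin))
}

# minimizer sketch of a sequence: data.frame(pos (0-based), code, fwd)
.minimizerSketch <- function(s, k, w) {
  ck <- .canonKmers(s, k)
  if (!length(ck$code))
    return(data.frame(pos = integer(0), code = numeric(0), fwd = logical(0)))
  keep <- .minimizerPos(ck$code, w)
  keep <- keep[!is.na(ck$code[keep])]
  data.frame(pos = keep - 1L, code = ck$code[keep], fwd = ck$fwd[keep])
}

# canonical k-mer strings of a sequence (string path, any k)
.canonKmerStrings <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  rc <- .revcomp(km)
  ok <- !grepl("[^ACGT]", km)
  pmin(km[ok], rc[ok])
}
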