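#' Specify a simulated diploid/polyploid genome
#'
#' Builds and validates the specification consumed by
#' [simulateGenome()]. Haplotypes are derived from one ancestral sequence
#' per chromosome by placing SNV loci at rate `hetRate` per bp; each
#' locus substitutes a base on exactly one haplotype, so every locus is
#' haplotype-informative. Repeat elements are stamped as exact copies
#' (0 divergence unless `divergence > 0`) onto the ancestral sequence, and
#' a telomere motif array is stamped at both chromosome ends; repeat and
#' telomere intervals are excluded from SNV placement so repeats stay
#' exact across copies and haplotypes.
#'
#' @param ploidy number of haplotypes (>= 1).
#' @param chromLengths integer vector of chromosome lengths (bp).
#' @param hetRate SNV substitutions per bp between haplotypes, in
#'   `[0, 0.05]`.
#' @param repeats list of repeat elements, each a list with `unitLen`
#'   (bp), `loci` (0-based start positions, one per stamped copy; all
#'   copies are exact) and optional `chrom` (default 1) and `divergence`
#'   (per-base substitution rate applied independently per copy,
#'   default 0).
#' @param teloMotif telomere motif stamped at both chromosome ends.
#' @param teloLen length of the stamped telomere array (bp).
#' @param seed integer; fully determines the output.
#' @return a validated spec (list) of class `simGenomeSpec`.
#' @export
simGenomeSpec <- function(ploidy = 2L, chromLengths = 100000L, hetRate = 0.001,
                          repeats = list(), teloMotif = "TTAGGG",
                          teloLen = 300L, seed = 1L) {
  stopifnot(ploidy >= 1, all(chromLengths > 0), length(seed) == 1)
  if (hetRate < 0 || hetRate > 0.05)
    stop("hetRate must be in [0, 0.05]")
  for (rp in repeats) {
    if (is.null(rp$unitLen) || is.null(rp$loci))
      stop("each repeat element needs unitLen and loci")
    chrom <- if (is.null(rp$chrom)) 1L else rp$chrom
    L <- chromLengths[chrom]
    if (any(rp$loci < 0) || any(rp$loci + rp$unitLen > L))
      stop("repeat placement overlaps a chromosome end")
  }
  structure(list(ploidy = as.integer(ploidy),
                 chromLengths = as.integer(chromLengths),
                 hetRate = hetRate, repeats = repeats,
                 teloMotif = toupper(teloMotif), teloLen = as.integer(teloLen),
                 seed = as.integer(seed)),
            class = "simGenomeSpec")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a diploid/polyploid genome with ground truth
#'
#' @param spec a [simGenomeSpec()].
#' @return a list with components:
#'   * `haplotypes`: list `hap1..hapP`, each a named character vector of
#'     chromosome sequences (`chr1..`).
#'   * `snvs`: data.frame (`chrom`, `pos` 0-based, `hap`, `ref`, `alt`)
#'     recording every haplotype-informative substitution.
#'   * `repeats`: data.frame of stamped repeat intervals.
#'   * `spec`: the input spec.
#' @export
simulateGenome <- function(spec) {
  stopifnot(inherits(spec, "simGenomeSpec"))
  set.seed(spec$seed)
  nchrom <- length(spec$chromLengths)
  telo <- substr(strrep(spec$teloMotif, ceiling(spec$teloLen / nchar(spec$teloMotif))),
                 1L, spec$teloLen)
  units <- lapply(spec$repeats, function(rp) .randSeq(rp$unitLen))

  anc <- vector("list", nchrom)
  forb <- vector("list", nchrom)   # 0-based forbidden intervals for SNVs
  repRows <- list()
  for (ci in seq_len(nchrom)) {
    L <- spec$chromLengths[ci]
    v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (spec$teloLen > 0 && L >= 2 * spec$teloLen) {
      v[seq_len(spec$teloLen)] <- strsplit(telo, "")[[1L]]
      v[(L - spec$teloLen + 1L):L] <- strsplit(.revcomp(telo), "")[[1L]]
      forb[[ci]] <- rbind(c(0L, spec$teloLen), c(L - spec$teloLen, L))
    } else forb[[ci]] <- matrix(integer(0), ncol = 2)
    anc[[ci]] <- v
  }
  for (ri in seq_along(spec$repeats)) {
    rp <- spec$repeats[[ri]]
    ci <- if (is.null(rp$chrom)) 1L else rp$chrom
    ub <- strsplit(units[[ri]], "")[[1L]]
    for (locus in rp$loci) {
      copy <- ub
      div <- if (is.null(rp$divergence)) 0 else rp$divergence
      if (div > 0) {
        mut <- which(runif(length(copy)) < div)
        for (m in mut) copy[m] <- sample(setdiff(c("A", "C", "G", "T"), copy[m]), 1L)
      }
      anc[[ci]][(locus + 1L):(locus + rp$unitLen)] <- copy
      forb[[ci]] <- rbind(forb[[ci]], c(locus, locus + rp$unitLen))
      repRows[[length(repRows) + 1L]] <-
        data.frame(element = ri, chrom = ci, start = locus,
                   end = locus + rp$unitLen)
    }
  }

  snvL <- list()
  haps <- lapply(seq_len(spec$ploidy), function(h) anc)
  if (spec$ploidy > 1L && spec$hetRate > 0) {
    for (ci in seq_len(nchrom)) {
      L <- spec$chromLengths[ci]
      bad <- rep(FALSE, L)
      fb <- forb[[ci]]
      if (nrow(fb)) for (j in seq_len(nrow(fb))) bad[(fb[j, 1L] + 1L):fb[j, 2L]] <- TRUE
      loci <- which(runif(L) < spec$hetRate & !bad)
      if (!length(loci)) next
      hp <- sample.int(spec$ploidy, length(loci), replace = TRUE)
      ref <- anc[[ci]][loci]
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1), USE.NAMES = FALSE)
      for (j in seq_along(loci)) haps[[hp[j]]][[ci]][loci[j]] <- alt[j]
      snvL[[length(snvL) + 1L]] <-
        data.frame(chrom = ci, pos = loci - 1L, hap = hp, ref = ref, alt = alt)
    }
  }

  haplotypes <- lapply(seq_len(spec$ploidy), function(h) {
    s <- vapply(haps[[h]], paste, character(1), collapse = "")
    names(s) <- paste0("chr", seq_len(nchrom))
    s
  })
  names(haplotypes) <- paste0("hap", seq_len(spec$ploidy))
  snvs <- if (length(snvL)) do.call(rbind, snvL)
          else data.frame(chrom = integer(0), pos = integer(0), hap = integer(0),
                          ref = character(0), alt = character(0))
  reps <- if (length(repRows)) do.call(rbind, repRows)
          else data.frame(element = integer(0), chrom = integer(0),
                          start = integer(0), end = integer(0))
  list(haplotypes = haplotypes, snvs = snvs, repeats = reps, spec = spec)
}

#' Specify a simulated read set
#'
#' @param role `"accurate"` (HiFi-grade; defaults to error-free, as
#'   base-level error correction is assumed upstream) or `"ultralong"`.
#' @param meanLen,lenSd mean and sd of the read length distribution (bp);
#'   lengths are normal draws floored at `minLen`.
#' @param minLen minimum emitted read length (bp). Ultra-long sets
#'   typically use 50000 at genome scale, mirroring the common >= 50 kb
#'   input filter; desk-scale fixtures scale this down.
#' @param coverage fold coverage per haplotype.
#' @param errorRate per-base substitution probability (no indels).
#' @param seed integer seed.
#' @return a validated spec (list) of class `simReadSpec`.
#' @export
simReadSpec <- function(role = c("accurate", "ultralong"), meanLen = 15000,
                        lenSd = meanLen / 10, minLen = round(meanLen / 3),
                        coverage = 10, errorRate = 0, seed = 1L) {
  role <- match.arg(role)
  stopifnot(meanLen > 0, lenSd >= 0, minLen > 0, coverage > 0,
            errorRate >= 0, errorRate < 1)
  structure(list(role = role, meanLen = meanLen, lenSd = lenSd,
                 minLen = as.integer(minLen), coverage = coverage,
                 errorRate = errorRate, seed = as.integer(seed)),
            class = "simReadSpec")
}

#' Simulate reads with ground-truth provenance
#'
#' Read start positions are uniform along each haplotype chromosome
#' (reads overhanging an end are clipped, so terminal bases keep full
#' expected coverage); lengths are normal draws floored at `minLen`;
#' strands are uniform. Reads are emitted until the per-chromosome base
#' count reaches `coverage * length`, so total bases land within a few
#' percent of the target. Truth provenance (haplotype, chromosome,
#' 0-based interval, strand) is encoded in the read name and parseable
#' with [parseTruthNames()].
#'
#' @param genome output of [simulateGenome()].
#' @param spec a [simReadSpec()].
#' @return list with `seqs` (named character vector) and `truth`
#'   (data.frame id, hap, chrom, start, end, strand, len).
#' @export
simulateReads <- function(genome, spec) {
  stopifnot(inherits(spec, "simReadSpec"))
  set.seed(spec$seed)
  prefix <- if (spec$role == "accurate") "acc" else "ul"
  seqsL <- list(); truthL <- list()
  counter <- 0L
  for (h in seq_along(genome$haplotypes)) {
    for (ci in seq_along(genome$haplotypes[[h]])) {
      hseq <- genome$haplotypes[[h]][[ci]]
      L <- nchar(hseq)
      if (spec$minLen > L)
        stop("minLen (", spec$minLen, ") exceeds chromosome length (", L, ")")
      target <- spec$coverage * L
      got <- 0
      ids <- character(0); ss <- integer(0); ee <- integer(0); st <- character(0)
      while (got < target) {
        n <- max(8L, ceiling((target - got) / spec$meanLen * 1.3))
        len <- pmax(spec$minLen, round(rnorm(n, spec$meanLen, spec$lenSd)))
        s0 <- floor(runif(n, -len + 1, L))
        s <- pmax(0L, as.integer(s0))
        e <- pmin(L, as.integer(s0 + len))
        keep <- (e - s) >= spec$minLen
        strand <- sample(c("+", "-"), n, replace = TRUE)
        for (j in which(keep)) {
          if (got >= target) break
          got <- got + (e[j] - s[j])
          ss <- c(ss, s[j]); ee <- c(ee, e[j]); st <- c(st, strand[j])
        }
      }
      for (j in seq_along(ss)) {
        counter <- counter + 1L
        rs <- substr(hseq, ss[j] + 1L, ee[j])
        if (spec$errorRate > 0) {
          v <- strsplit(rs, "")[[1L]]
          mut <- which(runif(length(v)) < spec$errorRate)
          for (m in mut) v[m] <- sample(setdiff(c("A", "C", "G", "T"), v[m]), 1L)
          rs <- paste(v, collapse = "")
        }
        if (st[j] == "-") rs <- .revcomp(rs)
        id <- sprintf("%s%05d!h%d!c%d!%d!%d!%s", prefix, counter, h, ci,
                      ss[j], ee[j], st[j])
        seqsL[[id]] <- rs
        truthL[[id]] <- data.frame(id = id, hap = h, chrom = ci,
                                   start = ss[j], end = ee[j], strand = st[j],
                                   len = ee[j] - ss[j], stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truthL)
  rownames(truth) <- NULL
  list(seqs = unlist(seqsL), truth = truth, spec = spec)
}

#' Parse truth provenance from simulated read names
#'
#' @param ids character vector of read names produced by
#'   [simulateReads()].
#' @return data.frame (id, hap, chrom, start, end, strand, len).
#' @export
parseTruthNames <- function(ids) {
  f <- strsplit(ids, "!", fixed = TRUE)
  bad <- lengths(f) != 6L
  if (any(bad)) stop("not a truth-encoded read name: ", ids[bad][1L])
  data.frame(
    id = ids,
    hap = as.integer(sub("^h", "", vapply(f, `[[`, character(1), 2L))),
    chrom = as.integer(sub("^c", "", vapply(f, `[[`, character(1), 3L))),
    start = as.integer(vapply(f, `[[`, character(1), 4L)),
    end = as.integer(vapply(f, `[[`, character(1), 5L)),
    strand = vapply(f, `[[`, character(1), 6L),
    stringsAsFactors = FALSE) -> df
  df$len <- df$end - df$start
  df
}
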