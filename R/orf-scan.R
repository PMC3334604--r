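match_positions <- function(seqchr, pattern) {
  if (nchar(seqchr) < nchar(pattern)) return(integer())
  as.integer(BiocGenerics::start(
    Biostrings::matchPattern(pattern, Biostrings::DNAString(seqchr))))
}

# per-strand scan of one sequence; returns (start, stop_codon_start) pairs in
# local 1-based coordinates, one ORF per (stop, frame) anchored at the
# 5'-most qualifying ATG (or all qualifying ATGs when allStarts)
scan_orfs_one <- function(seqchr, minNt, maxNt, allStarts = FALSE) {
  atg <- match_positions(seqchr, "ATG")
  stops <- sort(c(match_positions(seqchr, "TAA"),
                  match_positions(seqchr, "TAG"),
                  match_positions(seqchr, "TGA")))
  npos <- match_positions(seqchr, "N")
  out_a <- integer(); out_p <- integer()
  for (f in 0:2) {
    A <- atg[(atg - 1L) %% 3L == f]
    P <- stops[(stops - 1L) %% 3L == f]
    if (!length(A) || !length(P)) next
    prev <- c(-2L, P[-length(P)])
    a_min <- pmax(prev + 3L, P + 3L - maxNt)
    a_max <- P + 3L - minNt
    if (allStarts) {
      for (i in seq_along(P)) {
        lo <- findInterval(a_min[i] - 1L, A) + 1L
        hi <- findInterval(a_max[i], A)
        if (lo > hi) next
        out_a <- c(out_a, A[lo:hi])
        out_p <- c(out_p, rep(P[i], hi - lo + 1L))
      }
    } else {
      idx <- findInterval(a_min - 1L, A) + 1L
      ok <- idx <= length(A)
      ok[ok] <- A[idx[ok]] <= a_max[ok]
      out_a <- c(out_a, A[idx[ok]])
      out_p <- c(out_p, P[ok])
    }
  }
  if (length(npos) && length(out_a)) {
    nin <- findInterval(out_p + 2L, npos) - findInterval(out_a - 1L, npos)
    keep <- nin == 0L
    out_a <- out_a[keep]; out_p <- out_p[keep]
  }
  list(start = out_a, stop = out_p)
}

scan_regions <- function(genome, regions, minNt, maxNt, allStarts, reverse) {
  chromLen <- setNames(Biostrings::width(genome), names(genome))
  if (is.null(regions))
    regions <- GRanges(names(genome), IRanges(1L, chromLen))
  res <- list()
  scanner <- if (reverse) scan_controls_one else scan_orfs_one
  for (i in seq_along(regions)) {
    chrom <- as.character(seqnames(regions))[i]
    rs <- start(regions)[i]; re <- end(regions)[i]
    s <- as.character(subseq(genome[[chrom]], rs, re))
    L <- nchar(s)
    fw <- scanner(s, minNt, maxNt, allStarts)
    if (length(fw$start)) {
      st <- rs - 1L + fw$start
      en <- rs - 1L + fw$stop + 2L
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = en, strand = "+",
        frame = (st - 1L) %% 3L,
        nt = substring(s, fw$start, fw$stop + 2L))
    }
    rc <- revcomp_chr(s)
    rv <- scanner(rc, minNt, maxNt, allStarts)
    if (length(rv$start)) {
      st <- rs - 1L + (L - (rv$stop + 2L) + 1L)
      en <- rs - 1L + (L - rv$start + 1L)
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = en, strand = "-",
        frame = (chromLen[[chrom]] - en) %% 3L,
        nt = substring(rc, rv$start, rv$stop + 2L))
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), nt = character()))
  df <- do.call(rbind, res)
  df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
}

build_smorfset <- function(df, genome, control) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                frame = df$frame)
  seqlengths(gr) <- setNames(Biostrings::width(genome),
                             names(genome))[seqlevels(gr)]
  SmORFSet(gr, df$nt, control = control)
}

#' Scan for candidate smORFs in six frames on both strands
#'
#' Reports, for every in-frame stop codon, the ORF anchored at the 5'-most
#' ATG that yields a length within bounds and has no intervening stop
#' (one smORF per stop/frame/strand). With \code{allStarts = TRUE} every
#' qualifying in-frame ATG is reported. ORFs containing N are dropped.
#' Lengths are counted start codon through stop codon inclusive.
#'
#' @param genome named DNAStringSet
#' @param regions GRanges to scan (e.g. non-exonic intervals); default whole
#'   chromosomes. ORFs are required to lie entirely within a region.
#' @param minNt,maxNt inclusive length bounds in nucleotides (default 30-300)
#' @param allStarts report every in-frame ATG variant instead of one ORF
#'   per stop
#' @return A [SmORFSet-class] of candidates.
#' @export
scanSmorfs <- function(genome, regions = NULL, minNt = 30L, maxNt = 300L,
                       allStarts = FALSE) {
  df <- scan_regions(genome, regions, minNt, maxNt, allStarts, reverse = FALSE)
  build_smorfset(df, genome, control = FALSE)
}

# reverse-control scan of one sequence: stop codon to the next in-frame ATG
scan_controls_one <- function(seqchr, minNt, maxNt, allStarts = FALSE) {
  atg <- match_positions(seqchr, "ATG")
  stops <- sort(c(match_positions(seqchr, "TAA"),
                  match_positions(seqchr, "TAG"),
                  match_positions(seqchr, "TGA")))
  npos <- match_positions(seqchr, "N")
  out_a <- integer(); out_p <- integer()
  for (f in 0:2) {
    A <- atg[(atg - 1L) %% 3L == f]
    P <- stops[(stops - 1L) %% 3L == f]
    if (!length(A) || !length(P)) next
    idx <- findInterval(P + 2L, A) + 1L
    ok <- idx <= length(A)
    a <- A[idx[ok]]; p <- P[ok]
    len <- a - p + 3L
    keep <- len >= minNt & len <= maxNt
    out_a <- c(out_a, p[keep])          # segment start (stop codon)
    out_p <- c(out_p, a[keep])          # ATG position; segment end = a + 2
  }
  if (length(npos) && length(out_a)) {
    nin <- findInterval(out_p + 2L, npos) - findInterval(out_a - 1L, npos)
    keep <- nin == 0L
    out_a <- out_a[keep]; out_p <- out_p[keep]
  }
  list(start = out_a, stop = out_p)
}

#' Scan for reverse (stop-to-start) control ORFs
#'
#' A reverse control runs from a stop codon (TAA/TAG/TGA) to the next
#' in-frame ATG, inclusive, under the same length bounds as candidate
#' smORFs. Controls overlapping a candidate smORF on the same strand and
#' frame are discarded so the control pool is comparable to, and
#' non-overlapping with, the candidate population.
#'
#' @inheritParams scanSmorfs
#' @param smorfs optional [SmORFSet-class] of candidates used for the
#'   same-strand/same-frame overlap exclusion
#' @return A [SmORFSet-class] with \code{isControl() == TRUE}.
#' @export
scanReverseControls <- function(genome, regions = NULL, minNt = 30L,
                                maxNt = 300L, smorfs = NULL) {
  df <- scan_regions(genome, regions, minNt, maxNt, allStarts = FALSE,
                     reverse = TRUE)
  ctrl <- build_smorfset(df, genome, control = TRUE)
  if (!is.null(smorfs) && length(smorfs) && length(ctrl)) {
    ov <- findOverlaps(smorfRanges(ctrl), smorfRanges(smorfs),
                       ignore.strand = FALSE)
    fmatch <- frameOf(ctrl)[queryHits(ov)] ==
      frameOf(smorfs)[subjectHits(ov)]
    drop <- unique(queryHits(ov)[fmatch])
    if (length(drop)) ctrl <- ctrl[-drop]
  }
  ctrl
}

#' Stratified size-matched sampling
#'
#' Draws \code{n} elements from a pool so that the sampled length
#' distribution matches a reference distribution: lengths are binned
#' (default 3-nt bins), per-bin quotas follow the reference proportions via
#' largest-remainder rounding, and elements are drawn without replacement
#' within bins. Quotas falling in bins unpopulated in the pool are
#' reallocated to the nearest populated bins with a warning.
#'
#' @param pool a [SmORFSet-class] or numeric vector of lengths
#' @param referenceLengths lengths whose distribution the sample must match
#' @param n sample size (at most the pool size)
#' @param binWidthNt bin width in nt
#' @param seed RNG seed (sampling is deterministic given the seed)
#' @return the sampled subset (SmORFSet in, SmORFSet out; otherwise sorted
#'   indices into the pool).
#' @export
sizeMatchedSample <- function(pool, referenceLengths, n, binWidthNt = 3L,
                              seed = NULL) {
  lens <- if (is(pool, "SmORFSet")) lengthNt(pool) else as.numeric(pool)
  if (!length(lens)) stop("empty pool")
  if (n > length(lens)) stop("n exceeds pool size")
  base <- min(c(lens, referenceLengths))
  pb <- (lens - base) %/% binWidthNt
  rb <- (referenceLengths - base) %/% binWidthNt
  bins <- sort(unique(c(pb, rb)))
  refc <- tabulate(match(rb, bins), length(bins))
  poolc <- tabulate(match(pb, bins), length(bins))
  target <- n * refc / sum(refc)
  alloc <- floor(target)
  rem <- target - alloc
  short <- n - sum(alloc)
  if (short > 0) {
    ord <- order(-rem, bins)
    alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1
  }
  # reallocate quota from unpopulatable bins to nearest populated ones
  over <- which(alloc > poolc)
  if (length(over)) {
    warning("reference bins unpopulated (or underpopulated) in pool; ",
            "reallocating to nearest populated bins")
    for (b in over) {
      deficit <- alloc[b] - poolc[b]
      alloc[b] <- poolc[b]
      while (deficit > 0) {
        spare <- which(alloc < poolc)
        if (!length(spare)) stop("pool cannot host the requested sample")
        nb <- spare[which.min(abs(bins[spare] - bins[b]))]
        take <- min(deficit, poolc[nb] - alloc[nb])
        alloc[nb] <- alloc[nb] + take
        deficit <- deficit - take
      }
    }
  }
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(bins), function(b) {
      cand <- which(pb == bins[b])
      if (alloc[b] == 0L) return(integer())
      if (alloc[b] == length(cand)) cand
      else cand[sample.int(length(cand), alloc[b])]
    }))
  })
  idx <- sort(idx)
  if (is(pool, "SmORFSet")) pool[idx] else idx
}
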