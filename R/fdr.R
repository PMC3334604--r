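#' Sample exon-derived peptide segments with a matched length distribution
#'
#' Positive controls for the empirical FDR framework: random segments of
#' translated exons, with lengths drawn to match a reference distribution
#' (via the same largest-remainder stratification as
#' [sizeMatchedSample()]) and uniform random start offsets. Requested
#' lengths no exon can host are reallocated to the nearest feasible length
#' with a warning.
#'
#' @param exonPeptides character vector or AAStringSet of exon translations
#' @param referenceLengths target segment lengths (amino acids)
#' @param n number of segments
#' @param seed RNG seed
#' @return character vector of n peptide segments.
#' @export
sampleExonSegments <- function(exonPeptides, referenceLengths, n, seed = NULL) {
  pep <- as.character(exonPeptides)
  if (n == 0L) return(character())
  if (!length(pep)) stop("no exon peptides supplied")
  plen <- nchar(pep)
  # per-length quotas by largest-remainder rounding of the reference
  lens <- sort(unique(referenceLengths))
  prop <- tabulate(match(referenceLengths, lens)) / length(referenceLengths)
  alloc <- floor(n * prop)
  rem <- n * prop - alloc
  short <- n - sum(alloc)
  if (short > 0) {
    ord <- order(-rem, lens)
    alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1L
  }
  with_seed(seed, {
    wanted <- rep(lens, alloc)
    wanted <- wanted[sample.int(length(wanted))]
    maxlen <- max(plen)
    bad <- wanted > maxlen
    if (any(bad)) {
      warning("no exon long enough for ", sum(bad),
              " requested length(s); reallocating to the longest feasible")
      wanted[bad] <- maxlen
    }
    vapply(wanted, function(L) {
      host <- which(plen >= L)
      i <- host[sample.int(length(host), 1L)]
      s <- sample.int(plen[i] - L + 1L, 1L)
      substr(pep[i], s, s + L - 1L)
    }, character(1))
  })
}

#' Empirical false discovery rate at a threshold
#'
#' TP is the fraction of positive-control values passing the threshold, FP
#' the fraction of negative-control values passing; FDR = FP / (TP + FP),
#' defined as 0 when no value passes. NA values never pass. Direction
#' \code{lower_better} means a value passes when it is at or below the
#' threshold (E-values, Ka/Ks).
#'
#' @param posValues positive-control values (e.g. exon-segment E-values)
#' @param ctrlValues negative-control values (reverse-control ORFs)
#' @param threshold the threshold
#' @param direction only \code{"lower_better"} is defined
#' @return the empirical FDR in [0, 1].
#' @export
empiricalFdr <- function(posValues, ctrlValues, threshold,
                         direction = "lower_better") {
  stopifnot(direction == "lower_better",
            length(posValues) > 0, length(ctrlValues) > 0)
  tp <- mean(!is.na(posValues) & posValues <= threshold)
  fp <- mean(!is.na(ctrlValues) & ctrlValues <= threshold)
  if (tp + fp == 0) 0 else fp / (tp + fp)
}

#' Empirical FDR across a threshold grid
#'
#' @inheritParams empiricalFdr
#' @param thresholdGrid sorted (ascending) thresholds
#' @return data.frame (class \code{FdrTable}): threshold, TP fraction,
#'   FP fraction, FDR.
#' @export
fdrCurve <- function(posValues, ctrlValues, thresholdGrid,
                     direction = "lower_better") {
  stopifnot(!is.unsorted(thresholdGrid))
  tp <- vapply(thresholdGrid, function(t)
    mean(!is.na(posValues) & posValues <= t), numeric(1))
  fp <- vapply(thresholdGrid, function(t)
    mean(!is.na(ctrlValues) & ctrlValues <= t), numeric(1))
  fdr <- ifelse(tp + fp == 0, 0, fp / (tp + fp))
  out <- data.frame(threshold = thresholdGrid, tp = tp, fp = fp, fdr = fdr)
  class(out) <- c("FdrTable", "data.frame")
  out
}

#' Loosest threshold meeting a target FDR
#'
#' Scans the table loosest-first (largest threshold for lower_better) and
#' returns the first threshold whose empirical FDR is at or below the
#' target, or NA when none qualifies. No monotonicity adjustment is
#' applied: raw empirical values are used directly.
#'
#' @param table an \code{FdrTable} from [fdrCurve()]
#' @param target target FDR
#' @return the selected threshold, or NA.
#' @export
thresholdForFdr <- function(table, target) {
  for (i in rev(seq_len(nrow(table))))
    if (table$fdr[i] <= target) return(table$threshold[i])
  NA_real_
}
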