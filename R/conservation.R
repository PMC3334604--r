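#' Extract the subject window around a translated-search hit
#'
#' Returns the hit span plus \code{flank} bp either side (clipped at the
#' sequence ends), oriented so that the query reads 5'->3': windows for
#' minus-strand hits are reverse-complemented. An offset map converts
#' window positions back to forward-genome coordinates.
#'
#' @param hit one row of a [translatedSearch()] result (chrom, start, end,
#'   strand)
#' @param subjectGenome named DNAStringSet
#' @param flank flank size in bp (default 300)
#' @return list: \code{seq} (oriented window), \code{chrom},
#'   \code{wStart}/\code{wEnd} (forward coordinates of the window),
#'   \code{minus}, and \code{toGenome(w)} mapping oriented window positions
#'   to forward coordinates.
#' @export
extractFlanks <- function(hit, subjectGenome, flank = 300L) {
  chrom <- as.character(hit$chrom)
  L <- Biostrings::width(subjectGenome)[match(chrom, names(subjectGenome))]
  ws <- max(1L, hit$start - flank)
  we <- min(L, hit$end + flank)
  s <- as.character(subseq(subjectGenome[[chrom]], ws, we))
  minus <- as.character(hit$strand) == "-"
  if (minus) s <- revcomp_chr(s)
  toGenome <- if (minus) function(w) we - w + 1L else function(w) ws + w - 1L
  list(seq = s, chrom = chrom, wStart = ws, wEnd = we, minus = minus,
       strand = as.character(hit$strand), toGenome = toGenome)
}

project_through <- function(qPos, wPos, p) {
  idx <- match(p, qPos)
  if (is.na(idx)) return(NA_integer_)
  if (wPos[idx] != 0L) return(wPos[idx])
  # projected into a window gap: nearest flanking window base
  before <- wPos[seq_len(idx)]
  before <- before[before != 0L]
  if (length(before)) return(before[length(before)] + 1L)
  after <- wPos[idx:length(wPos)]
  after <- after[after != 0L]
  if (length(after)) return(after[1])
  NA_integer_
}

candidate_positions <- function(wseq, center, codons, searchWindow) {
  if (is.na(center)) return(integer())
  len <- nchar(wseq)
  ts <- seq(-searchWindow %/% 3L, searchWindow %/% 3L)
  ts <- ts[order(abs(ts), ts)]
  pos <- center + 3L * ts
  pos <- pos[pos >= 1L & pos + 2L <= len]
  pos[substring(wseq, pos, pos + 2L) %in% codons]
}

#' Call conserved ORF structure for a hit window
#'
#' Globally re-aligns the query smORF to the extracted subject window
#' (free end gaps on the window), projects the query start and stop codon
#' positions through the alignment, and searches the subject within
#' \code{searchWindow} nt (in frame, nearest projection first) for an ATG
#' and an in-frame stop with no internal in-frame stop between them. A net
#' indel not divisible by 3 inside the ORF span is a frame disruption and
#' yields \code{similarity_only}.
#'
#' Categories: \code{full_orf} (both elements found, clean frame),
#' \code{start_only}, \code{stop_only}, \code{similarity_only}.
#'
#' @param query single-element [SmORFSet-class] (or an object with one nt
#'   sequence beginning ATG and ending in a stop)
#' @param flanks result of [extractFlanks()]
#' @param searchWindow nt window for start/stop relocation (default 30)
#' @param scheme nucleotide [ScoringScheme-class] for the re-alignment
#' @return a \code{ConservedOrfCall}: list with \code{category},
#'   \code{subjectOrf} (forward-strand GRanges for full_orf), \code{subjectNt},
#'   \code{identity} (percent identity of the re-alignment), and the
#'   alignment internals used by [extractCodonPairs()].
#' @export
callConservedOrf <- function(query, flanks, searchWindow = 30L,
                             scheme = dnaScheme()) {
  qnt <- as.character(ntSeq(query))[1]
  L <- nchar(qnt)
  aln <- globalAlignNt(qnt, flanks$seq, scheme)
  qPos <- aln$qPos; wPos <- aln$wPos
  matchcols <- qPos != 0L & wPos != 0L
  qch <- strsplit(qnt, "")[[1]]
  wch <- strsplit(flanks$seq, "")[[1]]
  ident <- if (any(matchcols))
    100 * mean(qch[qPos[matchcols]] == wch[wPos[matchcols]]) else 0
  call <- list(smorfId = smorfIds(query)[1], category = "similarity_only",
               subjectOrf = NULL, subjectNt = NA_character_,
               identity = ident, qnt = qnt, wseq = flanks$seq,
               qPos = qPos, wPos = wPos)
  class(call) <- "ConservedOrfCall"

  projStart <- project_through(qPos, wPos, 1L)
  projStop <- project_through(qPos, wPos, L - 2L)
  atgs <- candidate_positions(flanks$seq, projStart, "ATG", searchWindow)
  stops <- candidate_positions(flanks$seq, projStop, STOP_CODONS, searchWindow)

  # frame disruption: net indel inside the ORF span
  i1 <- match(1L, qPos); i2 <- match(L, qPos)
  if (!is.na(i1) && !is.na(i2)) {
    span <- seq(i1, i2)
    net <- sum(qPos[span] == 0L) - sum(wPos[span] == 0L)
    if (net %% 3L != 0L) {
      call$frameshift <- TRUE
      return(call)
    }
  }

  for (a in atgs) {
    for (p in stops) {
      if (p <= a || (p - a) %% 3L != 0L) next
      inner <- substring(flanks$seq, seq(a, p - 3L, 3L), seq(a + 2L, p - 1L, 3L))
      if (any(inner %in% STOP_CODONS)) next
      g1 <- flanks$toGenome(a); g2 <- flanks$toGenome(p + 2L)
      call$category <- "full_orf"
      call$subjectNt <- substr(flanks$seq, a, p + 2L)
      call$subjectOrf <- GRanges(flanks$chrom,
                                 IRanges(min(g1, g2), max(g1, g2)),
                                 strand = flanks$strand)
      call$wOrfStart <- a
      return(call)
    }
  }
  if (length(atgs) && !length(stops)) call$category <- "start_only"
  else if (length(stops) && !length(atgs)) call$category <- "stop_only"
  else call$category <- "similarity_only"
  call
}

#' Aligned codon pairs from a full_orf call
#'
#' Returns the (query codon, subject codon) pairs from alignment columns
#' where both sequences carry an ungapped full codon; the start codon is
#' included, the stop codon excluded. Pairs in which either triplet is a
#' stop codon (possible in locally frame-shifted stretches) are dropped so
#' that downstream Ka/Ks site counting is defined.
#'
#' @param call a \code{ConservedOrfCall} with category \code{full_orf}
#' @return 2-column character matrix (query, subject), possibly 0-row.
#' @export
extractCodonPairs <- function(call) {
  if (!inherits(call, "ConservedOrfCall") || call$category != "full_orf")
    stop("codon pairs are only defined for full_orf calls")
  qnt <- call$qnt
  L <- nchar(qnt)
  ncod <- L %/% 3L - 1L          # exclude the stop codon
  qPos <- call$qPos; wPos <- call$wPos
  colOf <- match(seq_len(L), qPos)
  qcod <- character(0); wcod <- character(0)
  wch <- strsplit(call$wseq, "")[[1]]
  for (c in seq_len(ncod)) {
    p <- 3L * (c - 1L) + 1L
    cols <- colOf[p:(p + 2L)]
    if (anyNA(cols) || cols[3] - cols[1] != 2L) next
    wp <- wPos[cols]
    if (any(wp == 0L)) next
    qc <- substr(qnt, p, p + 2L)
    wc <- paste0(wch[wp], collapse = "")
    if (qc %in% STOP_CODONS || wc %in% STOP_CODONS) next
    if (grepl("[^ACGT]", qc) || grepl("[^ACGT]", wc)) next
    qcod <- c(qcod, qc); wcod <- c(wcod, wc)
  }
  cbind(query = qcod, subject = wcod)
}

#' @export
print.ConservedOrfCall <- function(x, ...) {
  cat("ConservedOrfCall:", x$smorfId, "->", x$category,
      sprintf("(%.1f%% identity)", x$identity), "\n")
  invisible(x)
}
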