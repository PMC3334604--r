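#' Six-frame translation with coordinate maps
#'
#' Translates a genome in frames +0/+1/+2 (forward) and -0/-1/-2 (reverse
#' complement, offset from the reverse 5' end). Residue i of a frame maps
#' back to the forward-strand interval of its codon via [frameResidueSpan()].
#'
#' @param genome named DNAStringSet
#' @return data.frame with columns chrom, frame, strand, offset, aa (the
#'   translated sequence) and chromLen.
#' @export
sixFrameTranslate <- function(genome) {
  rows <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    rc <- revcomp_chr(s)
    for (k in 0:2) {
      for (str in c("+", "-")) {
        src <- if (str == "+") s else rc
        n <- L - k
        n <- n - n %% 3L
        aa <- if (n >= 3L) translateCodons(substr(src, k + 1L, k + n)) else ""
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, frame = paste0(str, k), strand = str, offset = k,
          aa = aa, chromLen = L, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Forward-strand span of translated-frame residues
#'
#' @param chromLen chromosome length
#' @param strand "+" or "-"
#' @param offset frame offset 0-2
#' @param i residue index (1-based), vectorised
#' @return data.frame with forward-strand start and end of each codon.
#' @export
frameResidueSpan <- function(chromLen, strand, offset, i) {
  if (strand == "+") {
    data.frame(start = offset + 3L * (i - 1L) + 1L, end = offset + 3L * i)
  } else {
    data.frame(start = chromLen - (offset + 3L * i) + 1L,
               end = chromLen - (offset + 3L * (i - 1L)))
  }
}

#' Seeded translated similarity search (six frames)
#'
#' Protein queries are searched against the six-frame translation of a
#' nucleotide subject with a seeded local-alignment strategy: word seeds
#' (all words scoring at least \code{neighborThresh} against a query word)
#' are extended ungapped with an X-drop rule, and extensions reaching
#' \code{gapTrigger} undergo a windowed gapped local alignment. Hits are
#' deduplicated per frame (overlapping subject spans keep the best score)
#' and reported with Karlin-Altschul E-values computed over the effective
#' search space (total translated residues across all six frames). Hits
#' with E-value at most \code{eMax} are returned sorted by ascending
#' E-value (ties: lowest subject start, then + before -).
#'
#' @param queries named character vector or AAStringSet of protein queries
#' @param subjectGenome named DNAStringSet
#' @param scheme protein [ScoringScheme-class]; default [blosum62Scheme()]
#' @param wordLen seed word length (default 3)
#' @param neighborThresh minimum word score for a seed (default 12)
#' @param xDrop ungapped extension X-drop, raw score units (default 16)
#' @param eMax report hits with E-value at most this (default 30)
#' @param gapTrigger ungapped score triggering gapped extension; the
#'   default scales with the search space as the raw score at which a hit
#'   would reach \code{eMax}, minus a safety margin, so chance seeds far
#'   below reportability are never gap-extended
#' @param band extra window half-width for the gapped stage (default 16)
#' @return data.frame: query, chrom, start, end, strand, frame, qStart,
#'   qEnd, raw, bits, evalue.
#' @export
translatedSearch <- function(queries, subjectGenome, scheme = blosum62Scheme(),
                             wordLen = 3L, neighborThresh = 12L, xDrop = 16L,
                             eMax = 30, gapTrigger = NULL, band = 16L) {
  qchr <- if (is.character(queries)) queries else as.character(queries)
  if (is.null(names(qchr))) names(qchr) <- paste0("q", seq_along(qchr))
  frames <- sixFrameTranslate(subjectGenome)
  nEff <- sum(nchar(frames$aa))
  qcodes <- seq_to_codes(qchr, scheme)
  scodes <- seq_to_codes(frames$aa, scheme)
  if (is.null(gapTrigger)) {
    rawAtEmax <- (log(scheme@k * max(nchar(qchr)) * nEff) - log(eMax)) /
      scheme@lambda
    gapTrigger <- max(15L, as.integer(floor(rawAtEmax)) - 8L)
  }
  hits <- cpp_seed_search(qcodes, scodes, scheme@matrix, as.integer(wordLen),
                          as.integer(neighborThresh), as.integer(xDrop),
                          scheme@gapOpen, scheme@gapExt,
                          as.integer(gapTrigger), as.integer(band),
                          as.integer(gapTrigger))
  if (!nrow(hits)) return(empty_hits())
  fr <- frames[hits$subject, ]
  sp1 <- frameResidueSpan_v(fr$chromLen, fr$strand, fr$offset, hits$s_start)
  sp2 <- frameResidueSpan_v(fr$chromLen, fr$strand, fr$offset, hits$s_end)
  out <- data.frame(
    query = names(qchr)[hits$query],
    chrom = fr$chrom,
    start = pmin(sp1$start, sp2$start),
    end = pmax(sp1$end, sp2$end),
    strand = fr$strand,
    frame = fr$frame,
    qStart = hits$q_start, qEnd = hits$q_end,
    raw = hits$score,
    stringsAsFactors = FALSE)
  m <- nchar(qchr)[hits$query]
  out$bits <- bitScore(out$raw, scheme)
  out$evalue <- alignmentEvalue(out$raw, m, nEff, scheme)
  out <- out[out$evalue <= eMax, , drop = FALSE]
  out <- out[order(out$evalue, out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nEffective") <- nEff
  out
}

frameResidueSpan_v <- function(chromLen, strand, offset, i) {
  start <- ifelse(strand == "+", offset + 3L * (i - 1L) + 1L,
                  chromLen - (offset + 3L * i) + 1L)
  end <- ifelse(strand == "+", offset + 3L * i,
                chromLen - (offset + 3L * (i - 1L)))
  data.frame(start = start, end = end)
}

empty_hits <- function() {
  data.frame(query = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), frame = character(),
             qStart = integer(), qEnd = integer(), raw = integer(),
             bits = numeric(), evalue = numeric(), stringsAsFactors = FALSE)
}

#' Nucleotide exclusion filter against a sequence database
#'
#' Removes every smORF whose best nucleotide local alignment against any
#' database record (both strands searched) reaches an E-value at or below
#' \code{eCut}. Used to purge candidates matching annotated coding
#' sequences or transposons. With an empty database the operation is the
#' identity.
#'
#' @param smorfs a [SmORFSet-class]
#' @param db DNAStringSet of exclusion sequences (e.g. CDS + transposons)
#' @param scheme nucleotide [ScoringScheme-class]; default [dnaScheme()]
#' @param eCut removal threshold on the E-value (default 1e-3)
#' @param wordLen exact-match seed length (default 8)
#' @return list with elements \code{retained}, \code{removed} (SmORFSets)
#'   and \code{evalue} (best E-value per input smORF, NA when no hit).
#' @export
nucleotideExclusionFilter <- function(smorfs, db, scheme = dnaScheme(),
                                      eCut = 1e-3, wordLen = 8L) {
  n <- length(smorfs)
  ev <- rep(NA_real_, n)
  if (length(db) && n) {
    subjects <- c(as.character(db), revcomp_chr(as.character(db)))
    nEff <- sum(nchar(subjects))
    qcodes <- seq_to_codes(as.character(ntSeq(smorfs)), scheme)
    scodes <- seq_to_codes(subjects, scheme)
    mx <- as.integer(max(scheme@matrix))
    rawAtCut <- (log(scheme@k * max(lengthNt(smorfs)) * nEff) - log(eCut)) /
      scheme@lambda
    trig <- max(20L, as.integer(floor(rawAtCut)) - 10L)
    hits <- cpp_seed_search(qcodes, scodes, scheme@matrix,
                            as.integer(wordLen), as.integer(wordLen) * mx,
                            12L, scheme@gapOpen, scheme@gapExt, trig, 16L,
                            trig)
    if (nrow(hits)) {
      m <- lengthNt(smorfs)[hits$query]
      hev <- alignmentEvalue(hits$score, m, nEff, scheme)
      best <- tapply(hev, hits$query, min)
      ev[as.integer(names(best))] <- as.numeric(best)
    }
  }
  removed <- !is.na(ev) & ev <= eCut
  list(retained = smorfs[which(!removed)], removed = smorfs[which(removed)],
       evalue = ev)
}
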