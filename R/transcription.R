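#' Read transcription evidence from an extended BED file
#'
#' BED6 plus two extra columns: \code{kind} (\code{transfrag} or
#' \code{rnaseq_contig}) and \code{substage} (required for contigs, "." for
#' transfrags). All evidence must be stranded.
#'
#' @param path BED file
#' @return stranded GRanges with mcols \code{kind} and \code{substage}.
#' @export
readEvidenceBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(kind = "character",
                                          substage = "character"))
  validateEvidence(gr)
}

validateEvidence <- function(gr) {
  if (any(!mcols(gr)$kind %in% c("transfrag", "rnaseq_contig")))
    stop("evidence kind must be transfrag or rnaseq_contig")
  if (any(as.character(strand(gr)) == "*"))
    stop("evidence must be stranded")
  sub <- mcols(gr)$substage
  contig <- mcols(gr)$kind == "rnaseq_contig"
  if (any(contig & (is.na(sub) | sub %in% c("", "."))))
    stop("rnaseq_contig evidence requires a substage label")
  mcols(gr)$substage[!contig] <- NA_character_
  gr
}

#' Per-smORF transcription evidence profile
#'
#' Same-strand overlaps (at least \code{minOverlap} shared bases) between
#' smORFs and evidence items. With \code{unstrandedTransfrags = TRUE} the
#' strand rule is relaxed for transfrags only (tiling-array fragments whose
#' original strand is unknown), never for RNA-seq contigs.
#'
#' @param smorfs [SmORFSet-class] or stranded GRanges
#' @param evidence stranded GRanges with mcols \code{kind}, \code{substage}
#' @param minOverlap minimum shared bases (default 1)
#' @param unstrandedTransfrags relax the strand rule for transfrags
#' @return data.frame, one row per smORF: nContigs, nSubstages, nTransfrags,
#'   plus a list-column \code{substages}.
#' @export
buildEvidenceProfile <- function(smorfs, evidence, minOverlap = 1L,
                                 unstrandedTransfrags = FALSE) {
  gr <- if (is(smorfs, "SmORFSet")) smorfRanges(smorfs) else smorfs
  evidence <- validateEvidence(evidence)
  contigs <- evidence[mcols(evidence)$kind == "rnaseq_contig"]
  tfr <- evidence[mcols(evidence)$kind == "transfrag"]
  ovc <- findOverlaps(gr, contigs, minoverlap = minOverlap,
                      ignore.strand = FALSE)
  ovt <- findOverlaps(gr, tfr, minoverlap = minOverlap,
                      ignore.strand = unstrandedTransfrags)
  n <- length(gr)
  substages <- vector("list", n)
  csplit <- split(subjectHits(ovc), factor(queryHits(ovc), levels = seq_len(n)))
  for (i in seq_len(n))
    substages[[i]] <- mcols(contigs)$substage[csplit[[i]]]
  data.frame(
    id = if (is.null(names(gr))) as.character(seq_len(n)) else names(gr),
    nContigs = lengths(csplit),
    nSubstages = vapply(substages, function(s) length(unique(s)), integer(1)),
    nTransfrags = tabulate(queryHits(ovt), n),
    substages = I(substages),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-evidence-of-transcription rule
#'
#' A smORF passes when, in the right orientation, it overlaps RNA-seq
#' contigs in more than one embryonic substage (\code{multi_substage}); or
#' two or more contigs in a single substage
#' (\code{multi_contig_one_substage}); or a single contig plus at least one
#' transfrag (\code{contig_plus_transfrag}). Cases are evaluated in that
#' order and the first match is assigned; anything else is \code{none}.
#'
#' @param profile data.frame from [buildEvidenceProfile()]
#' @return data.frame with columns \code{id}, \code{passes}, \code{case}.
#' @export
multipleEvidence <- function(profile) {
  case <- ifelse(profile$nSubstages > 1L, "multi_substage",
          ifelse(profile$nContigs >= 2L, "multi_contig_one_substage",
          ifelse(profile$nContigs == 1L & profile$nTransfrags >= 1L,
                 "contig_plus_transfrag", "none")))
  data.frame(id = profile$id, passes = case != "none", case = case,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster smORFs by shared (polycistronic) transcripts
#'
#' Assigns each smORF to every same-strand overlapping transcript interval
#' and partitions transcripts by the number of distinct smORFs they carry.
#' smORFs overlapping more than one transcript are flagged ambiguous.
#'
#' @param smorfs [SmORFSet-class] or stranded GRanges
#' @param transcripts stranded GRanges of transcript intervals
#' @return list: \code{assignments} (data.frame smorf/transcript),
#'   \code{transcriptSizes} (smORFs per expressed transcript),
#'   \code{counts} (single, double, more, distinctTranscripts),
#'   \code{ambiguous} (smORF indices on >1 transcript).
#' @export
clusterTranscripts <- function(smorfs, transcripts) {
  gr <- if (is(smorfs, "SmORFSet")) smorfRanges(smorfs) else smorfs
  ov <- findOverlaps(gr, transcripts, ignore.strand = FALSE)
  perTx <- tabulate(subjectHits(ov), length(transcripts))
  perSm <- tabulate(queryHits(ov), length(gr))
  sizes <- perTx[perTx > 0L]
  list(assignments = data.frame(smorf = queryHits(ov),
                                transcript = subjectHits(ov)),
       transcriptSizes = sizes,
       counts = list(single = sum(sizes == 1L), double = sum(sizes == 2L),
                     more = sum(sizes > 2L),
                     distinctTranscripts = length(sizes)),
       ambiguous = which(perSm > 1L))
}
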