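#' Read a genome (or any DNA) FASTA file
#'
#' Residues are upper-cased and validated against the ACGTN alphabet.
#'
#' @param path FASTA file
#' @return A named [Biostrings::DNAStringSet] (empty for an empty file).
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(DNAStringSet())
  # read as raw strings first so illegal residues are caught, not dropped
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  ch <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", ch)
  if (any(bad))
    stop("illegal residues in record(s): ",
         paste(head(names(x)[bad], 5), collapse = ", "))
  if (any(!nzchar(names(x)))) stop("empty FASTA header in ", path)
  setNames(DNAStringSet(ch), names(x))
}

#' Write sequence records as FASTA
#'
#' @param x a named DNAStringSet/AAStringSet or named character vector
#' @param path output file
#' @export
writeFastaRecords <- function(x, path) {
  if (is.character(x)) {
    x <- if (all(grepl("^[ACGTN]*$", x))) DNAStringSet(x) else AAStringSet(x)
  }
  writeXStringSet(x, path)
  invisible(path)
}

FEATURE_CLASSES <- c("exon", "CDS", "gene", "transposon", "transcript_evidence")

#' Read feature annotation from GFF3 or BED
#'
#' GFF3 types are mapped onto the internal feature classes (exon, CDS, gene,
#' transposon, transcript_evidence); \code{transposable_element} and
#' \code{transposable_element_insertion_site} count as transposon. Features
#' of other types are kept with their own class label. Coordinates follow
#' the 1-based closed GRanges convention internally; BED input is converted
#' on import. Strand \code{*} is rejected for transcript_evidence features.
#'
#' @param path annotation file
#' @param dialect "gff3" or "bed"
#' @return GRanges with a \code{featureClass} mcol.
#' @export
readFeatureAnnotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln)) {
      f <- strsplit(ln, "\t", fixed = TRUE)
      s <- suppressWarnings(as.integer(vapply(f, `[`, "", 4)))
      e <- suppressWarnings(as.integer(vapply(f, `[`, "", 5)))
      bad <- which(is.na(s) | is.na(e) | s > e)
      if (length(bad))
        stop("start > end (or non-numeric coordinates) at record(s) ",
             paste(head(bad, 5), collapse = ", "))
    }
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed"),
    error = function(e) stop("cannot parse ", dialect, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  cls <- if (dialect == "gff3") as.character(mcols(gr)$type)
         else if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
         else rep("feature", length(gr))
  cls[cls %in% c("transposable_element",
                 "transposable_element_insertion_site")] <- "transposon"
  mcols(gr)$featureClass <- cls
  ev <- cls == "transcript_evidence"
  if (any(ev & as.character(strand(gr)) == "*"))
    stop("transcript_evidence features must be stranded")
  gr
}

#' Complement of masked feature classes over whole chromosomes
#'
#' Returns the maximal intervals not overlapping any feature of the masked
#' classes. Masking is strand-agnostic: a feature on either strand masks
#' both strands.
#'
#' @param features GRanges with a \code{featureClass} mcol (or plain GRanges,
#'   in which case every feature masks)
#' @param chromLengths named integer vector of chromosome lengths; must cover
#'   every feature chromosome
#' @param maskClasses feature classes to mask (default exon and CDS)
#' @return unstranded, sorted, disjoint GRanges covering the unmasked bases.
#' @export
complementIntervals <- function(features, chromLengths,
                                maskClasses = c("exon", "CDS")) {
  chroms <- names(chromLengths)
  if (is.null(chroms)) stop("chromLengths must be named")
  fc <- as.character(seqnames(features))
  if (!all(fc %in% chroms))
    stop("chromLengths does not cover: ",
         paste(setdiff(unique(fc), chroms), collapse = ", "))
  if (!is.null(mcols(features)$featureClass))
    features <- features[mcols(features)$featureClass %in% maskClasses]
  mask <- granges(features)
  strand(mask) <- "*"
  full <- GRanges(chroms, IRanges(1L, as.integer(chromLengths)))
  GenomeInfoDb::seqlevels(mask) <- chroms
  GenomeInfoDb::seqlevels(full) <- chroms
  out <- GenomicRanges::setdiff(full, GenomicRanges::reduce(mask),
                                ignore.strand = TRUE)
  BiocGenerics::sort(out)
}

#' Features overlapping an interval
#'
#' Returns exactly the features sharing at least one base with the interval;
#' with \code{strandMode = "same"} only features on the same strand count.
#' Abutting features (zero shared bases) never count.
#'
#' @param set GRanges of features
#' @param interval single-range GRanges
#' @param strandMode "any" or "same"
#' @return the overlapping subset of \code{set}.
#' @export
overlapQuery <- function(set, interval, strandMode = c("any", "same")) {
  strandMode <- match.arg(strandMode)
  stopifnot(length(interval) == 1L)
  hits <- findOverlaps(interval, set, minoverlap = 1L,
                       ignore.strand = (strandMode == "any"))
  set[subjectHits(hits)]
}

#' Export a SmORFSet as BED6 (name = id, score = supplied value)
#'
#' @param smorfs a SmORFSet
#' @param path output file
#' @param score numeric scores (e.g. bit scores); recycled; default 0
#' @export
exportSmorfsBed <- function(smorfs, path, score = 0) {
  gr <- smorfRanges(smorfs)
  mcols(gr) <- NULL
  gr$name <- smorfIds(smorfs)
  gr$score <- rep_len(score, length(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
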