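#' Scoring scheme for local/global alignment and E-value statistics
#'
#' Bundles a symmetric substitution matrix, affine gap penalties (a gap of
#' length L costs \code{gapOpen + gapExt * L}) and the Karlin-Altschul
#' parameters \code{lambda} and \code{k} used to convert raw scores into
#' bit scores and E-values. The Karlin-Altschul parameters are fixed,
#' documented constants per (matrix, gap) configuration; they are not
#' re-estimated at run time.
#'
#' @slot matrix integer substitution matrix with identical row/column names
#' @slot gapOpen non-negative gap opening penalty
#' @slot gapExt non-negative gap extension penalty
#' @slot lambda Karlin-Altschul scale (> 0)
#' @slot k Karlin-Altschul prefactor (> 0)
#' @slot alphabet residue alphabet, equal to the matrix row names
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "integer", gapExt = "integer",
                 lambda = "numeric", k = "numeric", alphabet = "character"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  m <- object@matrix
  if (!identical(rownames(m), colnames(m)))
    msg <- c(msg, "matrix row and column names must be identical")
  if (!isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "substitution matrix must be symmetric")
  if (object@gapOpen < 0L || object@gapExt < 0L)
    msg <- c(msg, "gap penalties must be >= 0")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (!identical(object@alphabet, rownames(m)))
    msg <- c(msg, "alphabet must equal matrix rownames")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", nrow(object@matrix), "x", ncol(object@matrix),
      "matrix; gap", object@gapOpen, "/", object@gapExt,
      "; lambda =", object@lambda, ", K =", object@k, "\n")
})

#' BLOSUM62 protein scoring scheme
#'
#' BLOSUM62 with gap open 11 / extend 1 and the standard gapped
#' Karlin-Altschul constants for that configuration (lambda 0.267, K 0.041).
#'
#' @return A [ScoringScheme-class] object.
#' @export
blosum62Scheme <- function() {
  mat <- get_blosum62()
  new("ScoringScheme", matrix = mat, gapOpen = 11L, gapExt = 1L,
      lambda = 0.267, k = 0.041, alphabet = rownames(mat))
}

#' Nucleotide scoring scheme
#'
#' Match +2 / mismatch -3 with gap open 5 / extend 2, and the tabulated
#' Karlin-Altschul constants for the +2/-3 configuration
#' (lambda 0.634, K 0.408). N scores 0 against everything.
#'
#' @param match match reward (positive integer)
#' @param mismatch mismatch penalty (negative integer)
#' @param gapOpen,gapExt affine gap penalties
#' @param lambda,k Karlin-Altschul constants for the configuration
#' @return A [ScoringScheme-class] object.
#' @export
dnaScheme <- function(match = 2L, mismatch = -3L, gapOpen = 5L, gapExt = 2L,
                      lambda = 0.634, k = 0.408) {
  ab <- c("A", "C", "G", "T", "N")
  mat <- matrix(as.integer(mismatch), 5, 5, dimnames = list(ab, ab))
  diag(mat) <- as.integer(match)
  mat["N", ] <- 0L
  mat[, "N"] <- 0L
  new("ScoringScheme", matrix = mat, gapOpen = as.integer(gapOpen),
      gapExt = as.integer(gapExt), lambda = lambda, k = k, alphabet = ab)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

#' Set of candidate smORFs or reverse-control ORFs
#'
#' Holds genomic locations (a stranded [GenomicRanges::GRanges] with a
#' \code{frame} metadata column giving the reading frame 0-2 on the forward
#' axis), the nucleotide sequences (start codon through stop codon for
#' candidates; stop codon through ATG for reverse controls), and the
#' translations. Validity enforces the full set of smORF invariants on
#' construction: candidates begin ATG, end in TAA/TAG/TGA, have length
#' divisible by 3 within 30-300 nt, and contain no internal in-frame stop;
#' reverse controls begin with a stop codon and end ATG under the same
#' length bounds.
#'
#' @slot ranges stranded GRanges, one range per ORF, with mcol \code{frame}
#' @slot nt DNAStringSet of ORF nucleotide sequences (oriented 5'->3')
#' @slot aa AAStringSet of translations (candidates: stop excluded;
#'   controls: full translation, internal stops as \code{*})
#' @slot control logical scalar; TRUE for reverse-control ORFs
#' @export
setClass("SmORFSet",
  representation(ranges = "GRanges", nt = "DNAStringSet",
                 aa = "AAStringSet", control = "logical"))

STOP_CODONS <- c("TAA", "TAG", "TGA")

setValidity("SmORFSet", function(object) {
  msg <- character()
  n <- length(object@ranges)
  if (length(object@nt) != n || length(object@aa) != n)
    return("ranges, nt and aa must have equal length")
  if (length(object@control) != 1L) return("control must be a scalar flag")
  if (n == 0L) return(TRUE)
  w <- Biostrings::width(object@nt)
  if (any(w != BiocGenerics::width(object@ranges)))
    msg <- c(msg, "sequence widths disagree with ranges")
  if (any(w %% 3L != 0L)) msg <- c(msg, "lengths must be divisible by 3")
  if (any(w < 30L | w > 300L)) msg <- c(msg, "lengths must lie in [30, 300] nt")
  if (!all(as.character(strand(object@ranges)) %in% c("+", "-")))
    msg <- c(msg, "strand must be + or -")
  fr <- mcols(object@ranges)$frame
  if (is.null(fr) || any(!fr %in% 0:2))
    msg <- c(msg, "ranges must carry a frame mcol in 0:2")
  s <- as.character(object@nt)
  first <- substr(s, 1L, 3L)
  last <- substr(s, nchar(s) - 2L, nchar(s))
  if (isTRUE(object@control)) {
    if (!all(first %in% STOP_CODONS))
      msg <- c(msg, "control ORFs must begin with a stop codon")
    if (!all(last == "ATG"))
      msg <- c(msg, "control ORFs must end with ATG")
  } else {
    if (!all(first == "ATG")) msg <- c(msg, "smORFs must begin with ATG")
    if (!all(last %in% STOP_CODONS))
      msg <- c(msg, "smORFs must end with a stop codon")
    aa <- translateCodons(s)
    if (any(grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)))
      msg <- c(msg, "smORFs must not contain internal in-frame stops")
    if (!identical(unname(as.character(object@aa)),
                   unname(substr(aa, 1L, nchar(aa) - 1L))))
      msg <- c(msg, "aa must equal the translation of nt minus the stop")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SmORFSet
#'
#' @param ranges stranded GRanges with a \code{frame} mcol
#' @param nt character vector or DNAStringSet of ORF sequences (5'->3')
#' @param control logical; TRUE for reverse-control ORFs
#' @param ids optional ids; default \code{smorf:<chrom>:<start>-<end>:<strand>}
#'   (\code{ctrl:} for controls)
#' @return A [SmORFSet-class].
#' @export
SmORFSet <- function(ranges, nt, control = FALSE, ids = NULL) {
  nt <- DNAStringSet(nt)
  s <- as.character(nt)
  aa <- translateCodons(s)
  if (!control) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (is.null(ids)) {
    ids <- sprintf("%s:%s:%d-%d:%s", if (control) "ctrl" else "smorf",
                   as.character(seqnames(ranges)), start(ranges),
                   end(ranges), as.character(strand(ranges)))
  }
  names(ranges) <- ids
  names(nt) <- ids
  aa <- AAStringSet(aa)
  names(aa) <- ids
  new("SmORFSet", ranges = ranges, nt = nt, aa = aa, control = control)
}

#' @describeIn SmORFSet-class genomic ranges of the ORFs
#' @param x a SmORFSet
#' @export
setMethod("smorfRanges", "SmORFSet", function(x) x@ranges)

#' @describeIn SmORFSet-class nucleotide sequences
#' @export
setMethod("ntSeq", "SmORFSet", function(x) x@nt)

#' @describeIn SmORFSet-class translated sequences
#' @export
setMethod("aaSeq", "SmORFSet", function(x) x@aa)

#' @describeIn SmORFSet-class ORF identifiers
#' @export
setMethod("smorfIds", "SmORFSet", function(x) names(x@ranges))

#' @describeIn SmORFSet-class TRUE if the set holds reverse controls
#' @export
setMethod("isControl", "SmORFSet", function(x) x@control)

#' @describeIn SmORFSet-class ORF length in nucleotides (start through stop)
#' @export
setMethod("lengthNt", "SmORFSet", function(x) Biostrings::width(x@nt))

#' @describeIn SmORFSet-class peptide length (excludes the stop codon)
#' @export
setMethod("lengthAa", "SmORFSet", function(x) Biostrings::width(x@nt) / 3L - 1L)

#' @describeIn SmORFSet-class reading frame (0-2) on the forward axis
#' @export
setMethod("frameOf", "SmORFSet", function(x) mcols(x@ranges)$frame)

#' @export
setMethod("length", "SmORFSet", function(x) length(x@ranges))

#' @export
setMethod("[", "SmORFSet", function(x, i, j, ..., drop = TRUE) {
  new("SmORFSet", ranges = x@ranges[i], nt = x@nt[i], aa = x@aa[i],
      control = x@control)
})

setMethod("show", "SmORFSet", function(object) {
  cat(class(object), "of", length(object),
      if (object@control) "reverse-control ORFs" else "candidate smORFs", "\n")
  if (length(object)) {
    w <- lengthNt(object)
    cat("  length (nt): range", min(w), "-", max(w),
        ", median", stats::median(w), "\n")
    cat("  seqnames:", paste(unique(as.character(seqnames(object@ranges))),
                             collapse = ", "), "\n")
  }
})

#' @export
#' @method as.data.frame SmORFSet
as.data.frame.SmORFSet <- function(x, ...) {
  gr <- x@ranges
  data.frame(id = names(gr), chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)), frame = mcols(gr)$frame,
             length_nt = lengthNt(x), length_aa = lengthAa(x),
             nt = as.character(x@nt), aa = as.character(x@aa),
             control = x@control, row.names = NULL,
             stringsAsFactors = FALSE)
}
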