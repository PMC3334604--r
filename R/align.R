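decode_alignment <- function(res, a, b) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  aal <- ifelse(res$a_aln == 0L, "-", ach[pmax(res$a_aln, 1L)])
  bal <- ifelse(res$b_aln == 0L, "-", bch[pmax(res$b_aln, 1L)])
  list(a = paste0(aal, collapse = ""), b = paste0(bal, collapse = ""))
}

#' Optimal local alignment (affine gaps)
#'
#' Exact Smith-Waterman-style dynamic programming with affine gap costs
#' (a gap of length L costs \code{gapOpen + gapExt * L}) and a fixed,
#' deterministic traceback tie-break (diagonal, then up, then left). With
#' no positive-scoring residue pair the score is 0 and the alignment empty.
#'
#' @param a,b sequences (single character strings) over the scheme alphabet
#' @param scheme a [ScoringScheme-class]
#' @param traceback return the aligned strings as well as the score
#' @return list with \code{score}, start/end coordinates in both sequences,
#'   and (if requested) gapped alignment strings \code{aAligned}/\code{bAligned}.
#' @export
localAlign <- function(a, b, scheme, traceback = TRUE) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- seq_to_codes(a, scheme)[[1]]
  cb <- seq_to_codes(b, scheme)[[1]]
  res <- cpp_pairwise_align(ca, cb, scheme@matrix, scheme@gapOpen,
                            scheme@gapExt, 0L, traceback)
  out <- list(score = res$score)
  if (traceback) {
    out$aStart <- res$a_start; out$aEnd <- res$a_end
    out$bStart <- res$b_start; out$bEnd <- res$b_end
    al <- decode_alignment(res, a, b)
    out$aAligned <- al$a; out$bAligned <- al$b
  }
  out
}

#' Global nucleotide alignment with free end gaps on the window
#'
#' Needleman-Wunsch-style global dynamic programming with affine gaps; the
#' query must align end-to-end while leading/trailing unaligned window
#' sequence is free, so a short query aligns contiguously inside a longer
#' window. Deterministic traceback tie-break as in [localAlign()].
#'
#' @param query,window single character strings (DNA)
#' @param scheme a [ScoringScheme-class]; default [dnaScheme()]
#' @param freeWindowEnds free end gaps on the window (default TRUE)
#' @return list with \code{score}, gapped strings \code{qAligned} /
#'   \code{wAligned} (over the aligned window region only), and the 1-based
#'   window coordinates \code{wStart}/\code{wEnd} of that region.
#' @export
globalAlignNt <- function(query, window, scheme = dnaScheme(),
                          freeWindowEnds = TRUE) {
  if (!nzchar(query) || !nzchar(window)) stop("sequences must be non-empty")
  cq <- seq_to_codes(query, scheme)[[1]]
  cw <- seq_to_codes(window, scheme)[[1]]
  res <- cpp_pairwise_align(cq, cw, scheme@matrix, scheme@gapOpen,
                            scheme@gapExt, if (freeWindowEnds) 2L else 1L,
                            TRUE)
  al <- decode_alignment(res, query, window)
  list(score = res$score, qAligned = al$a, wAligned = al$b,
       qStart = res$a_start, qEnd = res$a_end,
       wStart = res$b_start, wEnd = res$b_end,
       qPos = res$a_aln, wPos = res$b_aln)
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n \exp(-\lambda S)} for raw score S, query length m and
#' effective search-space length n (for a translated search, the total
#' number of translated residues across all six frames).
#'
#' @param rawScore raw alignment score(s)
#' @param m query length
#' @param nEffective effective subject length
#' @param scheme a [ScoringScheme-class] supplying lambda and K
#' @return numeric E-value(s).
#' @export
alignmentEvalue <- function(rawScore, m, nEffective, scheme) {
  stopifnot(m > 0, nEffective > 0)
  scheme@k * m * nEffective * exp(-scheme@lambda * rawScore)
}

#' Bit score from a raw score
#'
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}.
#'
#' @inheritParams alignmentEvalue
#' @return numeric bit score(s).
#' @export
bitScore <- function(rawScore, scheme) {
  (scheme@lambda * rawScore - log(scheme@k)) / log(2)
}
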