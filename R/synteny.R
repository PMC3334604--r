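#' Read an ortholog anchor map from TSV
#'
#' Columns: query chrom, start, end, subject chrom, start, end, gene id
#' (header optional; names are normalised). Anchors are sorted by query
#' position internally, so input order never matters.
#'
#' @param path TSV file
#' @return data.frame with columns qchrom, qstart, qend, schrom, sstart,
#'   send, gene.
#' @export
readAnchorMap <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("anchor map needs 7 columns")
  names(df)[1:7] <- c("qchrom", "qstart", "qend", "schrom", "sstart",
                      "send", "gene")
  validateAnchorMap(df)
}

validateAnchorMap <- function(map) {
  stopifnot(all(c("qchrom", "qstart", "qend", "schrom", "sstart", "send")
                %in% names(map)))
  map[order(map$qchrom, map$qstart), , drop = FALSE]
}

#' Flanking ortholog anchors of a smORF
#'
#' Nearest anchors left and right of the smORF on its query chromosome;
#' either may be absent near a chromosome end.
#'
#' @param smorf single-range GRanges (or one-element SmORFSet)
#' @param map anchor map data.frame (see [readAnchorMap()])
#' @return list with \code{upstream} and \code{downstream} (each a one-row
#'   data.frame or NULL).
#' @export
flankingAnchors <- function(smorf, map) {
  if (is(smorf, "SmORFSet")) smorf <- smorfRanges(smorf)
  stopifnot(length(smorf) == 1L)
  map <- validateAnchorMap(map)
  chrom <- as.character(seqnames(smorf))
  m <- map[map$qchrom == chrom, , drop = FALSE]
  if (!nrow(m)) stop("no anchors on chromosome ", chrom)
  left <- m[m$qend <= start(smorf), , drop = FALSE]
  right <- m[m$qstart >= end(smorf), , drop = FALSE]
  list(upstream = if (nrow(left)) left[nrow(left), , drop = FALSE] else NULL,
       downstream = if (nrow(right)) right[1, , drop = FALSE] else NULL)
}

#' Synteny test for a subject hit
#'
#' A hit is syntenic when both flanking anchors exist, both map to the same
#' subject chromosome as the hit, and the hit lies within the subject
#' interval spanned by the two anchors' subject positions (min/max, so a
#' local inversion between the anchors still counts) extended by
#' \code{slackBp}. With a single flanking anchor (chromosome end), the hit
#' must lie within \code{slackBp} of that anchor's subject interval on the
#' side corresponding to the query arrangement.
#'
#' @param smorf single-range GRanges or one-element SmORFSet (query side)
#' @param hit list/one-row data.frame with subject \code{chrom},
#'   \code{start}, \code{end}
#' @param map anchor map data.frame
#' @param slackBp slack in bp (default 50000)
#' @return logical.
#' @export
isSyntenic <- function(smorf, hit, map, slackBp = 50000L) {
  fl <- flankingAnchors(smorf, map)
  up <- fl$upstream; dn <- fl$downstream
  hchrom <- as.character(hit$chrom)
  hs <- hit$start; he <- hit$end
  if (!is.null(up) && !is.null(dn)) {
    if (up$schrom != hchrom || dn$schrom != hchrom) return(FALSE)
    lo <- min(up$sstart, dn$sstart) - slackBp
    hi <- max(up$send, dn$send) + slackBp
    return(hs >= lo && he <= hi)
  }
  one <- if (!is.null(up)) up else dn
  if (is.null(one) || one$schrom != hchrom) return(FALSE)
  if (is.null(dn)) {
    # smORF right of all anchors: hit expected at/after the anchor's
    # subject position (colinear orientation), within the slack
    hs >= one$sstart && he <= one$send + slackBp
  } else {
    # smORF left of all anchors: hit expected at/before the anchor
    he <= one$send && hs >= one$sstart - slackBp
  }
}
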