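BASES <- c("A", "C", "G", "T")

codon_mutants <- function(codon, pos) {
  vapply(setdiff(BASES, substr(codon, pos, pos)), function(b) {
    m <- codon
    substr(m, pos, pos) <- b
    m
  }, character(1), USE.NAMES = FALSE)
}

ng_sites_one <- function(codon) {
  if (!codon %in% SENSE_CODONS) stop("not a sense codon: ", codon)
  s <- 0
  for (p in 1:3) {
    mut <- codon_mutants(codon, p)
    viable <- mut[CODON_TABLE[mut] != "*"]
    if (!length(viable)) next
    s <- s + sum(CODON_TABLE[viable] == CODON_TABLE[codon]) / length(viable)
  }
  c(s = s, n = 3 - s)
}

NG_SITES <- NULL  # filled lazily: 61 x 2 matrix of (s, n) per sense codon

ng_sites_table <- function() {
  if (is.null(NG_SITES)) {
    tab <- t(vapply(SENSE_CODONS, ng_sites_one, numeric(2)))
    colnames(tab) <- c("s", "n")
    utils::assignInMyNamespace("NG_SITES", tab)
  }
  NG_SITES
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for a codon
#'
#' The synonymous site count s is the sum over the three codon positions of
#' (synonymous single-nucleotide mutants) / (viable mutants), where mutants
#' to stop codons are excluded from the viable count; n = 3 - s.
#'
#' @param codon a sense codon (3-letter string over ACGT)
#' @return named numeric vector \code{c(s = ..., n = ...)}.
#' @examples
#' ngSites("TTT")  # s = 1/3
#' @export
ngSites <- function(codon) {
  tab <- ng_sites_table()
  if (!codon %in% rownames(tab)) stop("not a sense codon: ", codon)
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (rest in perms_of(v[-k]))
      out[[length(out) + 1L]] <- c(v[k], rest)
  out
}

#' Pathway-averaged substitution differences between two codons
#'
#' Counts synonymous and nonsynonymous differences averaged over all
#' minimal mutational pathways between the codons. Pathways passing through
#' stop codons are excluded; if every pathway passes through a stop, all
#' pathways are used as a fallback.
#'
#' @param c1,c2 sense codons
#' @return named numeric vector \code{c(sd = ..., nd = ...)}.
#' @export
pathwayDifferences <- function(c1, c2) {
  if (!c1 %in% SENSE_CODONS || !c2 %in% SENSE_CODONS)
    stop("codons must be sense codons")
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dp <- which(b1 != b2)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  tally <- function(allowStops) {
    sds <- numeric(0); nds <- numeric(0)
    for (ord in perms_of(dp)) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- b2[p]
        if (!allowStops && CODON_TABLE[[nxt]] == "*") { ok <- FALSE; break }
        if (CODON_TABLE[[nxt]] == CODON_TABLE[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (length(sds)) c(sd = mean(sds), nd = mean(nds)) else NULL
  }
  res <- tally(allowStops = FALSE)
  if (is.null(res)) res <- tally(allowStops = TRUE)
  res
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for aligned codon pairs
#'
#' Site counts are averaged over the two sequences; proportions of
#' differences are Jukes-Cantor corrected
#' (\eqn{d = -3/4 \ln(1 - 4p/3)}). Status semantics:
#' \itemize{
#'   \item \code{ok}: Ks > 0 and both corrections defined; ratio = Ka/Ks
#'     (0 when Ka = 0).
#'   \item \code{na_no_syn_info}: Ks = 0 (no synonymous signal); ratio NA.
#'   \item \code{na_saturated}: pS (or pN) at or beyond 3/4, correction
#'     undefined; ratio NA.
#'   \item \code{na_empty}: no codon pairs; ratio NA.
#' }
#'
#' @param codonPairs 2-column character matrix as from
#'   [extractCodonPairs()] (query, subject), possibly 0-row
#' @return list of class \code{KaKsResult} with S_sites, N_sites, Sd, Nd,
#'   pS, pN, Ka, Ks, ratio, status.
#' @export
computeKaKs <- function(codonPairs) {
  res <- list(S_sites = 0, N_sites = 0, Sd = 0, Nd = 0, pS = NA_real_,
              pN = NA_real_, Ka = NA_real_, Ks = NA_real_,
              ratio = NA_real_, status = "na_empty")
  class(res) <- "KaKsResult"
  if (is.null(codonPairs) || nrow(codonPairs) == 0L) return(res)
  tab <- ng_sites_table()
  s1 <- tab[codonPairs[, 1], "s"]; s2 <- tab[codonPairs[, 2], "s"]
  S <- (sum(s1) + sum(s2)) / 2
  N <- 3 * nrow(codonPairs) - S
  d <- vapply(seq_len(nrow(codonPairs)), function(i)
    pathwayDifferences(codonPairs[i, 1], codonPairs[i, 2]), numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  res$S_sites <- S; res$N_sites <- N; res$Sd <- Sd; res$Nd <- Nd
  res$pS <- if (S > 0) Sd / S else NA_real_
  res$pN <- if (N > 0) Nd / N else NA_real_
  res$Ks <- jc_correct(res$pS)
  res$Ka <- jc_correct(res$pN)
  if (!is.na(res$pS) && res$pS >= 0.75) { res$status <- "na_saturated"; return(res) }
  if (is.na(res$Ks) || res$Ks == 0) { res$status <- "na_no_syn_info"; return(res) }
  if (is.na(res$Ka)) { res$status <- "na_saturated"; return(res) }
  res$ratio <- res$Ka / res$Ks
  res$status <- "ok"
  res
}

#' @export
print.KaKsResult <- function(x, ...) {
  cat(sprintf("KaKsResult: Ka = %.4g, Ks = %.4g, ratio = %s [%s]\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio),
              x$status))
  invisible(x)
}

#' Bin a Ka/Ks ratio into the standard reporting categories
#'
#' Categories: \code{0} (Ka = 0 with Ks > 0), \code{(0,0.1)},
#' \code{[0.1,1)}, \code{>=1}, and \code{NA}. Every result falls in exactly
#' one category.
#'
#' @param ratio numeric ratio(s), NA allowed
#' @return factor with the five levels above.
#' @export
kaksBin <- function(ratio) {
  lv <- c("0", "(0,0.1)", "[0.1,1)", ">=1", "NA")
  out <- ifelse(is.na(ratio), "NA",
         ifelse(ratio == 0, "0",
         ifelse(ratio < 0.1, "(0,0.1)",
         ifelse(ratio < 1, "[0.1,1)", ">=1"))))
  factor(out, levels = lv)
}
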