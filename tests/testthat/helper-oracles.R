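# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (they use Biostrings' genetic code, plain loops
# and brute force) so that agreement is a real cross-check.

GC_ORACLE <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- c("TAA", "TAG", "TGA")
ORACLE_BASES <- c("A", "C", "G", "T")

random_dna_chr <- function(n, gc = 0.5) {
  paste0(sample(ORACLE_BASES, n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

random_orf_chr <- function(codons) {
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  paste0(c("ATG", sample(sense, codons - 2, replace = TRUE),
           sample(ORACLE_STOPS, 1)), collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force single-strand ORF enumeration: for every ATG walk forward to
# the first in-frame stop; keep length bounds; one ORF per stop (5'-most ATG)
oracle_orfs_strand <- function(s, minNt, maxNt) {
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  cod <- function(i) paste0(ch[i:(i + 2)], collapse = "")
  hits <- list()
  for (a in seq_len(L - 2)) {
    if (cod(a) != "ATG") next
    p <- a + 3
    while (p + 2 <= L) {
      c3 <- cod(p)
      if (c3 %in% ORACLE_STOPS) break
      p <- p + 3
    }
    if (p + 2 > L) next
    len <- p + 2 - a + 1
    if (len < minNt || len > maxNt) next
    if (any(ch[a:(p + 2)] == "N")) next
    key <- as.character(p)
    if (is.null(hits[[key]]) || hits[[key]]$a > a)
      hits[[key]] <- list(a = a, p = p)
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  df <- data.frame(start = as.integer(vapply(hits, function(h) h$a,
                                             numeric(1))),
                   end = as.integer(vapply(hits, function(h) h$p + 2,
                                           numeric(1))))
  df[order(df$start), , drop = FALSE]
}

# both strands, forward-axis coordinates, as (start, end, strand)
oracle_orfs <- function(s, minNt = 30, maxNt = 300) {
  L <- nchar(s)
  fw <- oracle_orfs_strand(s, minNt, maxNt)
  fw$strand <- rep("+", nrow(fw))
  rv <- oracle_orfs_strand(rc_chr(s), minNt, maxNt)
  rv2 <- data.frame(start = L - rv$end + 1L, end = L - rv$start + 1L,
                    strand = rep("-", nrow(rv)))
  out <- rbind(fw, rv2)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# quadratic interval-overlap scan (1-based closed intervals)
oracle_overlap <- function(qs, qe, ss, se) {
  which(ss <= qe & se >= qs)
}

# Nei-Gojobori site counts by direct single-mutant enumeration
oracle_ng_sites <- function(codon) {
  s <- 0
  for (p in 1:3) {
    syn <- 0; viable <- 0
    for (b in setdiff(ORACLE_BASES, substr(codon, p, p))) {
      m <- codon
      substr(m, p, p) <- b
      if (GC_ORACLE[[m]] == "*") next
      viable <- viable + 1
      if (GC_ORACLE[[m]] == GC_ORACLE[[codon]]) syn <- syn + 1
    }
    if (viable > 0) s <- s + syn / viable
  }
  c(s = s, n = 3 - s)
}

# pathway enumeration oracle for codon differences
oracle_pathways <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dp <- which(b1 != b2)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  perms <- if (length(dp) == 1) list(dp)
    else if (length(dp) == 2) list(dp, rev(dp))
    else {
      out <- list()
      for (i in seq_along(dp)) for (j in seq_along(dp)) for (k in seq_along(dp))
        if (length(unique(c(i, j, k))) == 3)
          out[[length(out) + 1]] <- dp[c(i, j, k)]
      out
    }
  run <- function(allowStops) {
    sds <- c(); nds <- c()
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- b2[p]
        if (!allowStops && GC_ORACLE[[nxt]] == "*") { ok <- FALSE; break }
        if (GC_ORACLE[[nxt]] == GC_ORACLE[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (length(sds)) c(sd = mean(sds), nd = mean(nds)) else NULL
  }
  res <- run(FALSE)
  if (is.null(res)) res <- run(TRUE)
  res
}

# exact U statistic by direct pair counting
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided permutation p-value for U at tiny n
oracle_u_exact_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  u0 <- oracle_u(x, y)
  mid <- n1 * length(y) / 2
  us <- apply(idx, 2, function(i) oracle_u(v[i], v[-i]))
  mean(abs(us - mid) >= abs(u0 - mid) - 1e-9)
}

# brute-force ECDF sweep for the two-sample KS statistic
oracle_ks_d <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(vapply(g, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# tiny GRanges builders
gr1 <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}
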