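#' Mann-Whitney U test (normal approximation, midrank ties)
#'
#' U from rank sums with midranks for ties; two-sided p-value from the
#' normal approximation with tie-corrected variance and continuity
#' correction, the standard large-sample treatment. When every value in
#' both samples is identical the p-value is 1 by convention.
#'
#' @param x,y numeric samples
#' @return list of class \code{TestResult}: statistic (U for x), p_value,
#'   n1, n2, method.
#' @export
mannWhitneyU <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  structure(list(statistic = U, p_value = p, n1 = n1, n2 = n2,
                 method = "Mann-Whitney U (normal approximation)"),
            class = "TestResult")
}

#' Two-sample Kolmogorov-Smirnov test (asymptotic)
#'
#' D is the supremum of the ECDF difference; the p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' n1 n2 / (n1 + n2).
#'
#' @param x,y numeric samples
#' @return list of class \code{TestResult}: statistic (D), p_value, n1,
#'   n2, method.
#' @export
ksTwoSample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  structure(list(statistic = unname(res$statistic),
                 p_value = min(1, res$p.value), n1 = length(x),
                 n2 = length(y),
                 method = "Kolmogorov-Smirnov two-sample (asymptotic)"),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(x$method, ": statistic =", x$statistic, ", p =", x$p_value,
      " (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  invisible(x)
}

#' Size summaries and cumulative length curve for a smORF pool
#'
#' Sizes are reported in codons = length_nt / 3, i.e. including the stop
#' codon (so a 300-nt smORF counts 100 codons and encodes 99 amino acids).
#'
#' @param smorfs [SmORFSet-class] or numeric vector of codon sizes
#' @return list: n, mean, sd (0 for a singleton), median, histogram
#'   (table), and \code{cumulative} (data.frame of sorted length and
#'   fraction at or below it).
#' @export
summarizeSizes <- function(smorfs) {
  sz <- if (is(smorfs, "SmORFSet")) lengthNt(smorfs) / 3 else as.numeric(smorfs)
  if (!length(sz)) stop("empty pool")
  u <- sort(unique(sz))
  cum <- data.frame(length = u,
                    fraction = vapply(u, function(v) mean(sz <= v), numeric(1)))
  list(n = length(sz), mean = mean(sz),
       sd = if (length(sz) > 1) sd(sz) else 0,
       median = median(sz), histogram = table(sz), cumulative = cum)
}
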