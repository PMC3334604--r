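test_that("site counts match single-mutant enumeration for all 61 codons", {
  expect_equal(unname(ngSites("TTT")["s"]), 1 / 3)
  expect_equal(unname(ngSites("TGG")["s"]), 0)
  expect_error(ngSites("TAA"), "sense")
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  for (cod in sense) {
    got <- ngSites(cod)
    want <- oracle_ng_sites(cod)
    expect_equal(unname(got["s"]), unname(want["s"]), tolerance = 1e-12)
    expect_equal(unname(got["s"] + got["n"]), 3)  # complementarity, exact
  }
})

test_that("pathway differences average over stop-free minimal pathways", {
  expect_equal(pathwayDifferences("AAA", "AAA"), c(sd = 0, nd = 0))
  expect_equal(pathwayDifferences("TTT", "TTC"), c(sd = 1, nd = 0))
  # sampled multi-difference pairs agree with the enumeration oracle
  set.seed(19)
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  for (i in 1:60) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    expect_equal(pathwayDifferences(c1, c2), oracle_pathways(c1, c2),
                 tolerance = 1e-12)
  }
})

test_that("computeKaKs handles the canonical worked cases", {
  # identical pair: Ka = Ks = 0, no synonymous information
  pairs <- cbind(rep("GGA", 20), rep("GGA", 20))
  r <- computeKaKs(pairs)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_equal(r$status, "na_no_syn_info")
  expect_equal(r$S_sites + r$N_sites, 60)  # 3 x pairs, exact
  # a codon with no synonymous mutants at all still yields the NA status
  expect_equal(computeKaKs(cbind("ATG", "ATG"))$status, "na_no_syn_info")

  # one synonymous third-position change only: ratio 0, Ks hand-computed
  set.seed(20)
  q <- c("TTT", rep("GGA", 19))
  s <- c("TTC", rep("GGA", 19))
  r2 <- computeKaKs(cbind(q, s))
  S_hand <- (sum(oracle_ng_sites("TTT")["s"],
                 19 * oracle_ng_sites("GGA")["s"]) +
             sum(oracle_ng_sites("TTC")["s"],
                 19 * oracle_ng_sites("GGA")["s"])) / 2
  expect_equal(r2$Sd, 1)
  expect_equal(r2$Nd, 0)
  expect_equal(r2$Ks, -0.75 * log(1 - 4 * (1 / S_hand) / 3),
               tolerance = 1e-12)
  expect_equal(r2$ratio, 0)
  expect_equal(r2$status, "ok")

  # empty input
  r3 <- computeKaKs(cbind(character(), character()))
  expect_equal(r3$status, "na_empty")
  expect_true(is.na(r3$ratio))

  # saturation: wildly different codons drive pS/pN past the JC domain
  r4 <- computeKaKs(cbind(rep(c("TTA", "CTA"), 10), rep(c("CTG", "TTG"), 10)))
  expect_true(r4$status %in% c("ok", "na_saturated"))
})

test_that("Ka/Ks is symmetric and zero under synonymous-only evolution", {
  set.seed(21)
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  q <- sample(sense, 30, replace = TRUE)
  s <- sample(sense, 30, replace = TRUE)
  a <- computeKaKs(cbind(q, s))
  b <- computeKaKs(cbind(s, q))
  expect_equal(a$Ka, b$Ka, tolerance = 1e-12)
  expect_equal(a$Ks, b$Ks, tolerance = 1e-12)
  expect_equal(a$ratio, b$ratio, tolerance = 1e-12)

  # purely synonymous single-step divergence: Ka = 0 always. (At most one
  # substitution per codon: with multiple hits in one codon, pathway
  # averaging legitimately attributes weight to nonsynonymous routes.)
  set.seed(121)
  for (i in 1:10) {
    cod1 <- character(0); cod2 <- character(0)
    while (length(cod1) < 30) {
      c1 <- sample(sense, 1)
      muts <- unlist(lapply(1:3, function(p)
        vapply(setdiff(c("A", "C", "G", "T"), substr(c1, p, p)),
               function(b) { m <- c1; substr(m, p, p) <- b; m },
               character(1))))
      syn <- muts[GC_ORACLE[muts] == GC_ORACLE[[c1]]]
      if (!length(syn)) next
      cod1 <- c(cod1, c1)
      cod2 <- c(cod2, if (runif(1) < 0.5) c1 else sample(syn, 1))
    }
    r <- computeKaKs(cbind(cod1, cod2))
    expect_equal(r$Nd, 0)
    expect_equal(r$Ka, 0)
  }
})

test_that("ratios fall in exactly one reporting bin", {
  x <- c(NA, 0, 0.05, 0.099999, 0.1, 0.5, 1, 3)
  b <- kaksBin(x)
  expect_equal(as.character(b),
               c("NA", "0", "(0,0.1)", "(0,0.1)", "[0.1,1)", "[0.1,1)",
                 ">=1", ">=1"))
  expect_false(anyNA(b))
})
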