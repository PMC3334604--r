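tiny_cfg <- function(...) {
  base <- list(nChrom = 2L, chromLength = 40000L, nAnchors = 6L,
               nPlanted = 8L, nTranslocated = 1L, nQueryOnly = 1L,
               transposonCopies = 2L, nDecoyContigs = 20L,
               nDecoyTransfrags = 15L, seed = 5L)
  do.call(syntheticConfig, utils::modifyList(base, list(...)))
}

test_that("neutral evolution follows Jukes-Cantor expectations", {
  set.seed(31)
  s <- random_dna_chr(6000)
  expect_identical(evolveNeutral(s, 0), s)
  # realized difference fraction matches p = 3/4 (1 - exp(-4d/3))
  for (d in c(0.2, 0.5, 1.0)) {
    s2 <- evolveNeutral(s, d, seed = d * 100)
    pdiff <- mean(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
    pexp <- 0.75 * (1 - exp(-4 * d / 3))
    expect_lt(abs(pdiff - pexp), 3 * sqrt(pexp * (1 - pexp) / 6000))
  }
  # saturation limit: ~25% identity
  s3 <- evolveNeutral(s, 50, seed = 9)
  expect_lt(abs(mean(strsplit(s, "")[[1]] == strsplit(s3, "")[[1]]) - 0.25),
            0.03)
  # indels change length
  s4 <- evolveNeutral(s, 0.1, seed = 10, indelRate = 0.02)
  expect_false(nchar(s4) == nchar(s))
})

test_that("coding evolution respects omega and the ORF architecture", {
  set.seed(32)
  for (i in 1:10) {
    orf <- random_orf_chr(40)
    # ksTarget 0: identity
    expect_identical(as.character(evolveCoding(orf, 0, 0.3, seed = i)), orf)
    # omega 0: protein unchanged, sequence diverged
    e0 <- as.character(evolveCoding(orf, 0.5, 0, seed = i))
    expect_equal(translateCodons(e0), translateCodons(orf))
    expect_false(e0 == orf)
    # start/stop preserved, no internal stops, under any omega
    e1 <- as.character(evolveCoding(orf, 0.6, 1, seed = i))
    expect_equal(substr(e1, 1, 3), "ATG")
    aa <- translateCodons(e1)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("the generator is deterministic and internally consistent", {
  cfg <- tiny_cfg()
  a <- generateGenomePair(cfg)
  b <- generateGenomePair(cfg)
  expect_identical(as.character(a$queryGenome), as.character(b$queryGenome))
  expect_identical(as.character(a$subjectGenome),
                   as.character(b$subjectGenome))
  expect_identical(a$truth, b$truth)

  # truth coordinates point at real ORFs in both genomes
  for (i in seq_len(nrow(a$truth))) {
    tr <- a$truth[i, ]
    qorf <- substr(as.character(a$queryGenome[[tr$qchrom]]), tr$qstart,
                   tr$qend)
    if (tr$strand == "-") qorf <- rc_chr(qorf)
    expect_equal(substr(qorf, 1, 3), "ATG")
    expect_true(substr(qorf, nchar(qorf) - 2, nchar(qorf)) %in%
                  c("TAA", "TAG", "TGA"))
    if (tr$category != "query_only") {
      sorf <- substr(as.character(a$subjectGenome[[tr$schrom]]), tr$sstart,
                     tr$send)
      if (tr$strand == "-") sorf <- rc_chr(sorf)
      expect_equal(substr(sorf, 1, 3), "ATG")
      expect_equal(translateCodons(substr(qorf, 1, 3)),
                   translateCodons(substr(sorf, 1, 3)))
    }
  }
  # translocated plants sit on a different subject chromosome
  tl <- a$truth[a$truth$category == "translocated", ]
  expect_true(all(tl$schrom != tl$qchrom))
  # anchors colinear: subject starts increase with query starts per chrom
  for (ch in unique(a$anchors$qchrom)) {
    m <- a$anchors[a$anchors$qchrom == ch, ]
    expect_false(is.unsorted(m$sstart))
  }
  # capacity check
  expect_error(generateGenomePair(tiny_cfg(chromLength = 3000L)),
               "capacity")
})

test_that("identity-limit configuration reproduces the query genome", {
  cfg <- tiny_cfg(neutralDivergence = 0, indelRate = 0, ksTarget = 0,
                  anchorDivergence = 0, nTranslocated = 0L, nQueryOnly = 0L)
  sim <- generateGenomePair(cfg)
  expect_identical(as.character(sim$queryGenome),
                   as.character(sim$subjectGenome))
})

test_that("estimator recovers the generator's omega (consistency)", {
  set.seed(33)
  est <- replicate(150, {
    orf <- random_orf_chr(52)
    orf2 <- as.character(evolveCoding(orf, 0.5, 0.2))
    cod1 <- substring(orf, seq(1, nchar(orf) - 3, 3), seq(3, nchar(orf) - 3, 3))
    cod2 <- substring(orf2, seq(1, nchar(orf) - 3, 3), seq(3, nchar(orf) - 3, 3))
    computeKaKs(cbind(cod1, cod2))$ratio
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.2), 0.03)
})

test_that("evidence generation hits the configured sensitivities", {
  # sensitivity 0: no planted smORF passes multiple evidence
  sim0 <- generateGenomePair(tiny_cfg(pContig = 0, nDecoyContigs = 0L,
                                      nDecoyTransfrags = 0L))
  tr <- sim0$truth
  tgr <- gr1(tr$qchrom, tr$qstart, tr$qend, tr$strand)
  names(tgr) <- tr$id
  me0 <- multipleEvidence(buildEvidenceProfile(tgr, sim0$evidence))
  expect_false(any(me0$passes))
  # multi-substage fraction 1: every plant classifies as multi_substage
  sim1 <- generateGenomePair(tiny_cfg(pContig = 1, pMultiSubstage = 1,
                                      nDecoyContigs = 0L,
                                      nDecoyTransfrags = 0L))
  tr1 <- sim1$truth
  tgr1 <- gr1(tr1$qchrom, tr1$qstart, tr1$qend, tr1$strand)
  names(tgr1) <- tr1$id
  me1 <- multipleEvidence(buildEvidenceProfile(tgr1, sim1$evidence))
  expect_true(all(me1$case == "multi_substage"))
})

test_that("recovery scoring matches construction", {
  truth <- data.frame(id = c("p1", "p2"), category = "conserved",
                      qchrom = "chr1", qstart = c(100, 500),
                      qend = c(199, 599), strand = "+", codons = c(20, 20))
  perfect <- gr1("chr1", c(100, 500), c(199, 599), "+")
  sc <- scoreRecovery(perfect, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$fdr, 0)
  empty <- GenomicRanges::GRanges()
  sc0 <- scoreRecovery(empty, truth)
  expect_equal(sc0$sensitivity, 0)
  # a survivor overlapping no plant counts as a false positive
  mixed <- gr1("chr1", c(100, 9000), c(199, 9099), "+")
  scm <- scoreRecovery(mixed, truth)
  expect_equal(scm$fdr, 0.5)
  expect_equal(scm$sensitivity, 0.5)
})

test_that("synthetic data survives the round trip through disk formats", {
  sim <- generateGenomePair(tiny_cfg())
  dir <- tempfile()
  writeSyntheticData(sim, dir)
  q2 <- readGenomeFasta(file.path(dir, "query.fa"))
  expect_identical(as.character(q2), as.character(sim$queryGenome))
  ev2 <- readEvidenceBed(file.path(dir, "evidence.bed"))
  expect_equal(length(ev2), length(sim$evidence))
  expect_equal(sum(S4Vectors::mcols(ev2)$kind == "transfrag"),
               sum(S4Vectors::mcols(sim$evidence)$kind == "transfrag"))
  an2 <- readAnchorMap(file.path(dir, "anchors.tsv"))
  expect_equal(an2$sstart, sim$anchors$sstart)
  gff <- readFeatureAnnotation(file.path(dir, "annotation.gff3"), "gff3")
  expect_equal(sum(S4Vectors::mcols(gff)$featureClass == "transposon"),
               sum(S4Vectors::mcols(sim$annotation)$featureClass ==
                     "transposon"))
})
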