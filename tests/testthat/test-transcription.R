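ev_gr <- function(start, end, strand, kind, substage = NA_character_) {
  gr1("chr1", start, end, strand, kind = kind, substage = substage)
}

test_that("evidence profiles use same-strand >=1 bp overlap", {
  sm <- gr1("chr1", 1000, 1089, "+")
  names(sm) <- "s1"
  # antisense contig fully covering the smORF: excluded
  ev <- ev_gr(900, 1200, "-", "rnaseq_contig", "E0_4")
  p <- buildEvidenceProfile(sm, ev)
  expect_equal(p$nContigs, 0L)
  # abutting contig (no shared base): excluded
  ev2 <- ev_gr(900, 999, "+", "rnaseq_contig", "E0_4")
  expect_equal(buildEvidenceProfile(sm, ev2)$nContigs, 0L)
  # 1-base overlap: included
  ev3 <- ev_gr(900, 1000, "+", "rnaseq_contig", "E0_4")
  expect_equal(buildEvidenceProfile(sm, ev3)$nContigs, 1L)
  # unstranded-transfrag switch relaxes transfrags only
  ev4 <- c(ev_gr(950, 1050, "-", "transfrag"),
           ev_gr(950, 1050, "-", "rnaseq_contig", "E0_4"))
  p4 <- buildEvidenceProfile(sm, ev4, unstrandedTransfrags = TRUE)
  expect_equal(p4$nTransfrags, 1L)
  expect_equal(p4$nContigs, 0L)
  # random instances agree with a quadratic scan oracle
  set.seed(25)
  for (rep in 1:10) {
    ns <- 40; ne <- 60
    ss <- sample(1:5000, ns); sm2 <- gr1("chr1", ss, ss + 99,
                                         sample(c("+", "-"), ns, TRUE))
    names(sm2) <- paste0("m", 1:ns)
    es <- sample(1:5000, ne)
    ev5 <- gr1("chr1", es, es + sample(50:300, ne, TRUE),
               sample(c("+", "-"), ne, TRUE),
               kind = sample(c("rnaseq_contig", "transfrag"), ne, TRUE),
               substage = "E0_4")
    S4Vectors::mcols(ev5)$substage[S4Vectors::mcols(ev5)$kind ==
                                     "transfrag"] <- NA
    p5 <- buildEvidenceProfile(sm2, ev5)
    for (i in sample(ns, 10)) {
      keep <- oracle_overlap(BiocGenerics::start(sm2)[i],
                             BiocGenerics::end(sm2)[i],
                             BiocGenerics::start(ev5),
                             BiocGenerics::end(ev5))
      keep <- keep[as.character(BiocGenerics::strand(ev5))[keep] ==
                     as.character(BiocGenerics::strand(sm2))[i]]
      expect_equal(p5$nContigs[i],
                   sum(S4Vectors::mcols(ev5)$kind[keep] == "rnaseq_contig"))
      expect_equal(p5$nTransfrags[i],
                   sum(S4Vectors::mcols(ev5)$kind[keep] == "transfrag"))
    }
  }
})

test_that("the multiple-evidence cases are ordered and exhaustive", {
  prof <- data.frame(id = as.character(1:6),
                     nContigs = c(2L, 2L, 1L, 1L, 0L, 3L),
                     nSubstages = c(2L, 1L, 1L, 1L, 0L, 2L),
                     nTransfrags = c(0L, 0L, 1L, 0L, 5L, 1L))
  me <- multipleEvidence(prof)
  expect_equal(me$case, c("multi_substage", "multi_contig_one_substage",
                          "contig_plus_transfrag", "none", "none",
                          "multi_substage"))
  expect_equal(me$passes, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  # transfrags alone never pass
  expect_false(me$passes[5])
})

test_that("transcript clustering partitions by distinct smORF count", {
  sm <- gr1("chr1", c(100, 300, 500, 2000), c(189, 389, 589, 2089), "+")
  tx <- gr1("chr1", c(50, 1900, 3000), c(700, 2100, 3100), "+")
  cl <- clusterTranscripts(sm, tx)
  expect_equal(cl$counts$distinctTranscripts, 2)
  expect_equal(sort(cl$transcriptSizes), c(1, 3))
  expect_equal(cl$counts$more, 1)
  # disjoint sets: all singletons
  sm2 <- gr1("chr1", c(100, 300), c(150, 350), "+")
  tx2 <- gr1("chr1", c(100, 300), c(150, 350), "+")
  cl2 <- clusterTranscripts(sm2, tx2)
  expect_equal(cl2$counts$single, 2)
  expect_length(cl2$ambiguous, 0)
  # a smORF overlapping two transcripts is flagged ambiguous
  tx3 <- gr1("chr1", c(50, 120), c(130, 200), "+")
  cl3 <- clusterTranscripts(gr1("chr1", 100, 150, "+"), tx3)
  expect_equal(cl3$ambiguous, 1L)
})

test_that("evidence validation enforces strand and substage rules", {
  expect_error(validateEvidence(gr1("chr1", 1, 10, "*", kind = "transfrag",
                                    substage = NA)), "stranded")
  expect_error(validateEvidence(gr1("chr1", 1, 10, "+",
                                    kind = "rnaseq_contig",
                                    substage = NA)), "substage")
  expect_error(validateEvidence(gr1("chr1", 1, 10, "+", kind = "bogus",
                                    substage = NA)), "kind")
})
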