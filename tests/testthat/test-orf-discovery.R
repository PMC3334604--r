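test_that("translation follows the universal code, cross-checked", {
  expect_equal(translateCodons("ATG"), "M")
  expect_equal(translateCodons("ATGTAA"), "M*")
  expect_error(translateCodons("ATGT"), "divisible by 3")
  # random 300-mers agree with an independently coded codon table
  set.seed(2)
  for (i in 1:20) {
    s <- random_dna_chr(300)
    orc <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                              no.init.codon = TRUE))
    expect_equal(translateCodons(s), orc)
  }
})

test_that("scanSmorfs finds constructed ORFs with correct anatomy", {
  # 9-nt ORF is below the 30-nt bound
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("C", 50), "ATGAAATAG",
                                                strrep("C", 50))))
  expect_length(scanSmorfs(g), 0)

  # 36-nt ORF embedded in ATG/stop-free flanks: exactly one smORF, 11 aa
  set.seed(3)
  orf <- random_orf_chr(12)
  fwd <- paste0(strrep("C", 99), orf, strrep("C", 99))
  sm <- scanSmorfs(Biostrings::DNAStringSet(c(chr1 = fwd)))
  expect_equal(length(sm), 1)
  expect_equal(lengthNt(sm), 36L)
  expect_equal(lengthAa(sm), 11L)
  expect_equal(BiocGenerics::start(smorfRanges(sm)), 100)
  expect_true(validObject(sm))

  # reverse complement: strand -, identical peptide
  smr <- scanSmorfs(Biostrings::DNAStringSet(c(chr1 = rc_chr(fwd))))
  expect_equal(length(smr), 1)
  expect_equal(as.character(BiocGenerics::strand(smorfRanges(smr))), "-")
  expect_equal(unname(as.character(aaSeq(smr))),
               unname(as.character(aaSeq(sm))))
})

test_that("scanSmorfs equals the exhaustive enumeration oracle", {
  set.seed(11)
  for (rep in 1:25) {
    s <- random_dna_chr(2000, gc = runif(1, 0.3, 0.6))
    sm <- scanSmorfs(Biostrings::DNAStringSet(c(chr1 = s)))
    got <- as.data.frame(sm)[, c("start", "end", "strand")]
    rownames(got) <- NULL
    want <- oracle_orfs(s)
    rownames(want) <- NULL
    expect_equal(got, want)
    expect_true(validObject(sm))
  }
})

test_that("ORFs containing N are dropped", {
  set.seed(4)
  orf <- random_orf_chr(12)
  withN <- sub("ATG", "ATG", orf)
  substr(withN, 10, 10) <- "N"
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("C", 60), withN,
                                                strrep("C", 60))))
  expect_length(scanSmorfs(g), 0)
})

test_that("reverse controls run stop-to-ATG and exclude smORF overlaps", {
  # no ATG downstream of any stop: empty
  g0 <- Biostrings::DNAStringSet(c(chr1 = paste0("TAA", strrep("C", 60))))
  expect_length(scanReverseControls(g0), 0)

  # TAA + 10 codons + ATG: one control of 36 nt
  set.seed(5)
  mid <- paste0(sample(c("CCC", "CAC", "CCA", "ACC"), 10, TRUE),
                collapse = "")
  seg <- paste0("TAA", mid, "ATG")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("C", 99), seg,
                                                strrep("C", 99))))
  ctrl <- scanReverseControls(g)
  ctrl <- ctrl[as.character(BiocGenerics::strand(smorfRanges(ctrl))) == "+"]
  expect_equal(length(ctrl), 1)
  expect_equal(lengthNt(ctrl), 36L)
  expect_true(isControl(ctrl))
  expect_true(validObject(ctrl))

  # a control coinciding with a same-strand/frame smORF window is excluded
  fakegr <- smorfRanges(ctrl)
  fake <- SmORFSet(gr1("chr1", BiocGenerics::start(fakegr),
                       BiocGenerics::start(fakegr) + 35, "+",
                       frame = frameOf(ctrl)),
                   paste0("ATG", mid, "TAA"))
  ctrl2 <- scanReverseControls(g, smorfs = fake)
  ctrl2 <- ctrl2[as.character(BiocGenerics::strand(smorfRanges(ctrl2))) == "+"]
  expect_length(ctrl2, 0)
})

test_that("size-matched sampling follows largest-remainder quotas", {
  # reference all one length
  idx <- sizeMatchedSample(rep(30, 20), rep(30, 5), 10, seed = 1)
  expect_length(idx, 10)

  # n = pool size with matching reference returns the whole pool
  pool <- c(rep(30, 6), rep(60, 4))
  idx <- sizeMatchedSample(pool, pool, 10, seed = 1)
  expect_equal(sort(idx), 1:10)

  # 70/30 two-bin reference, n = 10: 7/3 split (hand-computed)
  pool <- c(rep(30, 50), rep(60, 50))
  ref <- c(rep(30, 70), rep(60, 30))
  idx <- sizeMatchedSample(pool, ref, 10, seed = 2)
  expect_equal(sum(pool[idx] == 30), 7)
  expect_equal(sum(pool[idx] == 60), 3)

  # determinism per seed
  expect_identical(sizeMatchedSample(pool, ref, 10, seed = 9),
                   sizeMatchedSample(pool, ref, 10, seed = 9))

  # per-bin count never deviates from the exact quota by more than 1
  set.seed(6)
  pool <- sample(seq(30, 90, 3), 400, replace = TRUE)
  ref <- sample(seq(30, 90, 3), 300, replace = TRUE)
  idx <- sizeMatchedSample(pool, ref, 100, seed = 3)
  for (b in unique(ref)) {
    expect_lte(abs(sum(pool[idx] == b) - 100 * mean(ref == b)), 1)
  }
})

test_that("SmORFSet validity rejects malformed candidates", {
  expect_error(SmORFSet(gr1("c", 1, 36, "+", frame = 0),
                        paste0("CTG", strrep("AAA", 10), "TAA")),
               "begin with ATG")
  expect_error(SmORFSet(gr1("c", 1, 36, "+", frame = 0),
                        paste0("ATG", strrep("AAA", 10), "AAA")),
               "stop codon")
  expect_error(SmORFSet(gr1("c", 1, 12, "+", frame = 0),
                        "ATGAAAAAATAA"), "30")
})
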