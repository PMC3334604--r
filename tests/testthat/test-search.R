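test_that("six-frame translation has the right frame anatomy and maps", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAG"))
  fr <- sixFrameTranslate(g)
  expect_equal(nrow(fr), 6)
  lens <- setNames(nchar(fr$aa), fr$frame)
  expect_equal(unname(lens[c("+0", "+1", "+2")]), c(3L, 2L, 2L))
  expect_equal(unname(lens[c("-0", "-1", "-2")]), c(3L, 2L, 2L))

  # mapping round-trip: residue i maps to a codon translating to it
  set.seed(10)
  s <- random_dna_chr(60)
  g <- Biostrings::DNAStringSet(c(chr1 = s))
  fr <- sixFrameTranslate(g)
  for (r in seq_len(nrow(fr))) {
    aa <- strsplit(fr$aa[r], "")[[1]]
    for (i in sample(seq_along(aa), min(4, length(aa)))) {
      sp <- frameResidueSpan(fr$chromLen[r], fr$strand[r], fr$offset[r], i)
      codon <- substr(s, sp$start, sp$end)
      if (fr$strand[r] == "-") codon <- rc_chr(codon)
      expect_equal(translateCodons(codon), aa[i])
    }
  }

  # frame translations agree with direct translation of framed substrings
  for (k in 0:2) {
    n <- nchar(s) - k
    n <- n - n %% 3
    expect_equal(fr$aa[fr$frame == paste0("+", k)],
                 translateCodons(substr(s, k + 1, k + n)))
  }
})

test_that("translated search finds planted queries on both strands", {
  set.seed(12)
  orf <- random_orf_chr(40)
  pep <- substr(translateCodons(orf), 1, 39)
  bg <- random_dna_chr(30000, 0.45)
  subj <- Biostrings::DNAStringSet(c(
    s1 = paste0(substr(bg, 1, 12000), substr(orf, 1, 117),
                substr(bg, 12001, 30000))))
  h <- translatedSearch(c(q = pep), subj)
  expect_gt(nrow(h), 0)
  expect_lt(h$evalue[1], 1e-6)
  expect_equal(h$start[1], 12001)
  expect_equal(h$end[1], 12117)
  expect_equal(h$strand[1], "+")
  expect_equal(h$qStart[1], 1)
  expect_equal(h$qEnd[1], 39)

  # strand symmetry: reverse-complemented subject gives the same raw score
  subj2 <- Biostrings::DNAStringSet(
    c(s1 = rc_chr(as.character(subj[[1]]))))
  h2 <- translatedSearch(c(q = pep), subj2)
  expect_equal(h2$raw[1], h$raw[1])
  expect_equal(h2$strand[1], "-")
  L <- Biostrings::width(subj2)[1]
  expect_equal(h2$start[1], L - 12117 + 1)
  expect_equal(h2$end[1], L - 12001 + 1)
})

test_that("seeded search never exceeds, and attains, the DP optimum", {
  sch <- blosum62Scheme()
  set.seed(13)
  for (rep in 1:5) {
    orf <- random_orf_chr(30)
    pep <- substr(translateCodons(orf), 1, 29)
    bg <- random_dna_chr(6000, 0.45)
    subj <- Biostrings::DNAStringSet(c(
      s1 = paste0(substr(bg, 1, 3000),
                  as.character(evolveCoding(orf, 0.4, 0.1, seed = rep)),
                  substr(bg, 3001, 6000))))
    h <- translatedSearch(c(q = pep), subj, neighborThresh = 11L)
    fr <- sixFrameTranslate(subj)
    dp <- max(vapply(fr$aa, function(aa)
      localAlign(pep, aa, sch, traceback = FALSE)$score, numeric(1)))
    expect_lte(max(h$raw), dp)
    expect_equal(max(h$raw), dp)  # planted homolog: optimum attained
  }
})

test_that("nucleotide exclusion removes exactly the database-derived set", {
  set.seed(14)
  orfs <- vapply(rep(40, 100), function(c) random_orf_chr(c), character(1))
  starts <- seq(1, by = 200, length.out = 100)
  gr <- gr1("chr1", starts, starts + 119, "+", frame = (starts - 1) %% 3)
  sm <- SmORFSet(gr, orfs)
  # db: 10 of the smORFs embedded verbatim inside transposon-like records
  planted <- sort(sample(100, 10))
  db <- Biostrings::DNAStringSet(setNames(vapply(planted, function(i)
    paste0(random_dna_chr(150), orfs[i], random_dna_chr(150)),
    character(1)), paste0("te", seq_along(planted))))
  res <- nucleotideExclusionFilter(sm, db)
  expect_equal(sort(match(smorfIds(res$removed), smorfIds(sm))), planted)
  expect_equal(length(res$retained), 90)

  # empty database: identity
  res0 <- nucleotideExclusionFilter(sm, Biostrings::DNAStringSet())
  expect_equal(length(res0$retained), 100)
  expect_length(res0$removed, 0)

  # reverse-complemented db record still excludes (both strands searched)
  dbrc <- Biostrings::DNAStringSet(c(te = rc_chr(paste0(
    random_dna_chr(100), orfs[1], random_dna_chr(100)))))
  res2 <- nucleotideExclusionFilter(sm, dbrc)
  expect_true(smorfIds(sm)[1] %in% smorfIds(res2$removed))
})
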