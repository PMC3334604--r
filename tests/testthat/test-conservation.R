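make_subject <- function(orf_subject, flankL = 1000, flankR = 2000,
                         seed = 1) {
  set.seed(seed)
  bg <- random_dna_chr(flankL + flankR, 0.45)
  Biostrings::DNAStringSet(c(s1 = paste0(substr(bg, 1, flankL), orf_subject,
                                         substr(bg, flankL + 1,
                                                flankL + flankR))))
}

query_smorf <- function(orf) {
  SmORFSet(gr1("q", 1, nchar(orf), "+", frame = 0), orf)
}

test_that("flank extraction clips, orients and maps coordinates", {
  set.seed(15)
  subj <- Biostrings::DNAStringSet(c(s1 = random_dna_chr(10000)))
  hit <- data.frame(chrom = "s1", start = 501, end = 560, strand = "+")
  fl <- extractFlanks(hit, subj, flank = 300)
  expect_equal(fl$wStart, 201)
  expect_equal(fl$wEnd, 860)
  expect_equal(nchar(fl$seq), 660)
  expect_equal(fl$toGenome(1), 201)

  # clipping near the sequence start
  hit2 <- data.frame(chrom = "s1", start = 101, end = 160, strand = "+")
  fl2 <- extractFlanks(hit2, subj, flank = 300)
  expect_equal(fl2$wStart, 1)
  expect_equal(nchar(fl2$seq), 460)

  # minus-strand window translates to contain the hit's protein segment
  orf <- random_orf_chr(20)
  subj3 <- Biostrings::DNAStringSet(c(s1 = rc_chr(paste0(
    random_dna_chr(400), orf, random_dna_chr(400)))))
  L <- Biostrings::width(subj3)[1]
  hit3 <- data.frame(chrom = "s1",
                     start = L - (400 + nchar(orf)) + 1,
                     end = L - 401 + 1, strand = "-")
  fl3 <- extractFlanks(hit3, subj3, flank = 300)
  pep <- translateCodons(substr(orf, 1, nchar(orf) - 3))
  expect_true(grepl(pep, translateCodons(substr(
    fl3$seq, 301, 300 + nchar(orf) - 3)), fixed = TRUE))
})

test_that("conserved-ORF calling classifies constructed cases", {
  set.seed(16)
  sense_noATG <- setdiff(names(GC_ORACLE)[GC_ORACLE != "*"], "ATG")
  orf <- paste0(c("ATG", sample(sense_noATG, 20, TRUE), "TAG"),
                collapse = "")
  qs <- query_smorf(orf)
  hit <- function(subj) data.frame(chrom = "s1", start = 1001,
                                   end = 1000 + nchar(orf), strand = "+")

  # identical subject: full_orf with identical boundaries
  subj <- make_subject(orf)
  call <- callConservedOrf(qs, extractFlanks(hit(subj), subj))
  expect_equal(call$category, "full_orf")
  expect_equal(BiocGenerics::start(call$subjectOrf), 1001)
  expect_equal(BiocGenerics::end(call$subjectOrf), 1000 + nchar(orf))
  expect_equal(call$subjectNt, orf)

  # full_orf subject sequence independently satisfies the ORF invariants
  expect_equal(substr(call$subjectNt, 1, 3), "ATG")
  expect_true(substr(call$subjectNt, nchar(call$subjectNt) - 2,
                     nchar(call$subjectNt)) %in% c("TAA", "TAG", "TGA"))
  aa <- translateCodons(call$subjectNt)
  expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))

  # start ATG mutated, no alternative ATG in reach: stop_only.
  # C-rich flanks guarantee no spurious in-frame ATG near the projection.
  orf_noStart <- orf
  substr(orf_noStart, 1, 3) <- "ATA"
  subjC <- Biostrings::DNAStringSet(c(s1 = paste0(strrep("C", 1000),
                                                  orf_noStart,
                                                  strrep("C", 1000))))
  call2 <- callConservedOrf(qs, extractFlanks(hit(subjC), subjC))
  expect_equal(call2$category, "stop_only")

  # stop mutated instead: start_only
  orf_noStop <- orf
  substr(orf_noStop, nchar(orf) - 2, nchar(orf)) <- "CAG"
  subjS <- Biostrings::DNAStringSet(c(s1 = paste0(strrep("C", 1000),
                                                  orf_noStop,
                                                  strrep("C", 1000))))
  call3 <- callConservedOrf(qs, extractFlanks(hit(subjS), subjS))
  expect_equal(call3$category, "start_only")

  # 1-nt deletion mid-ORF: frame disruption, similarity_only
  orf_fs <- paste0(substr(orf, 1, 30), substr(orf, 32, nchar(orf)))
  subjF <- Biostrings::DNAStringSet(c(s1 = paste0(strrep("C", 1000), orf_fs,
                                                  strrep("C", 1000))))
  call4 <- callConservedOrf(qs, extractFlanks(hit(subjF), subjF))
  expect_equal(call4$category, "similarity_only")
})

test_that("codon pairs come from ungapped codon columns only", {
  set.seed(17)
  orf <- random_orf_chr(12)          # 12 codons incl stop
  qs <- query_smorf(orf)
  subj <- make_subject(orf)
  hit <- data.frame(chrom = "s1", start = 1001, end = 1000 + nchar(orf),
                    strand = "+")
  call <- callConservedOrf(qs, extractFlanks(hit, subj))
  cp <- extractCodonPairs(call)
  expect_equal(nrow(cp), 11)         # stop excluded, start included
  expect_equal(cp[, 1], cp[, 2])
  expect_equal(cp[1, 1], "ATG")

  # one in-frame 3-nt deletion: pairs lose exactly the deleted codon
  orf_del <- paste0(substr(orf, 1, 12), substr(orf, 16, nchar(orf)))
  subj2 <- make_subject(orf_del)
  call2 <- callConservedOrf(qs, extractFlanks(hit, subj2))
  expect_equal(call2$category, "full_orf")
  cp2 <- extractCodonPairs(call2)
  expect_equal(nrow(cp2), 10)

  expect_error(extractCodonPairs(list(category = "stop_only")),
               "full_orf")
})

test_that("planted intact subjects are called full_orf, frameshifts never", {
  set.seed(18)
  n_full <- 0; n <- 30
  for (i in 1:n) {
    orf <- random_orf_chr(sample(12:60, 1))
    qs <- query_smorf(orf)
    orf2 <- as.character(evolveCoding(orf, 0.5, 0.05))
    subj <- make_subject(orf2, seed = i)
    hit <- data.frame(chrom = "s1", start = 1001,
                      end = 1000 + nchar(orf2), strand = "+")
    call <- callConservedOrf(qs, extractFlanks(hit, subj))
    if (call$category == "full_orf") n_full <- n_full + 1
    # planted frameshift must never be full_orf
    third <- nchar(orf2) %/% 3
    cut <- sample(third:(2 * third), 1)   # mid-ORF frameshift
    orf_fs <- paste0(substr(orf2, 1, cut - 1), substr(orf2, cut + 1,
                                                      nchar(orf2)))
    subj_fs <- make_subject(orf_fs, seed = i + 1000)
    hit_fs <- data.frame(chrom = "s1", start = 1001,
                         end = 1000 + nchar(orf_fs), strand = "-")
    hit_fs$strand <- "+"
    call_fs <- callConservedOrf(qs, extractFlanks(hit_fs, subj_fs))
    expect_false(call_fs$category == "full_orf")
  }
  expect_gte(n_full / n, 0.99)
})
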