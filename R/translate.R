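# Universal genetic code, coded here independently of any external codon
# table so that translation can be cross-checked against a second
# implementation in the tests.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]

#' Translate nucleotide sequences with the universal genetic code
#'
#' Length must be divisible by 3. Internal (and terminal) stop codons are
#' rendered as \code{*}; codons containing characters outside ACGT (for
#' example N) are rendered as \code{X}.
#'
#' @param nt character vector of DNA sequences (upper case ACGTN)
#' @return character vector of translations.
#' @examples
#' translateCodons("ATGTAA")  # "M*"
#' @export
translateCodons <- function(nt) {
  nt <- as.character(nt)
  if (any(nchar(nt) %% 3L != 0L))
    stop("sequence length must be divisible by 3")
  vapply(nt, function(s) {
    if (!nzchar(s)) return("")
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aa <- unname(CODON_TABLE[cod])
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run expr under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  expr
}

# integer-encode residues against a scheme alphabet (0-based codes for C++)
seq_to_codes <- function(x, scheme) {
  ab <- scheme@alphabet
  lapply(strsplit(as.character(x), ""), function(ch) {
    code <- match(ch, ab)
    if (anyNA(code)) {
      bad <- unique(ch[is.na(code)])
      # unknown residues: map to X for protein schemes, N for DNA
      fallback <- if ("X" %in% ab) "X" else if ("N" %in% ab) "N" else
        stop("illegal residues for scheme: ", paste(bad, collapse = ", "))
      code[is.na(code)] <- match(fallback, ab)
    }
    as.integer(code - 1L)
  })
}

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
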