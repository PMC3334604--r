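#' Configuration for the synthetic genome-pair generator
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's end-to-end tests: two 500-kb chromosomes per genome, 40
#' colinear ortholog anchor genes, 60 planted smORFs (50 conserved in
#' syntenic position, 5 translocated, 5 query-only) evolving under strong
#' purifying selection (omega 0.05) at a synonymous divergence of 0.5
#' substitutions per synonymous site, intergenic background at 1.0
#' substitutions/site (near saturation) with 2% indels, and 3 transposon
#' families of 10 copies to exercise the exclusion filter.
#'
#' @param nChrom chromosomes per genome
#' @param chromLength query chromosome length (bp)
#' @param gc background GC fraction
#' @param nAnchors total anchor genes (colinear in both genomes)
#' @param anchorLength anchor gene length (bp)
#' @param nPlanted total planted smORFs
#' @param nTranslocated planted smORFs moved to a different subject
#'   chromosome
#' @param nQueryOnly planted smORFs with no subject counterpart
#' @param plantLenRange planted ORF length range in nt (multiples of 3,
#'   within 30-300)
#' @param omega Ka/Ks of planted smORFs
#' @param ksTarget synonymous divergence of planted smORFs
#' @param neutralDivergence background substitutions/site
#' @param indelRate background indel events per site
#' @param anchorDivergence divergence of anchor genes (kept well below
#'   saturation so anchors stay recognisable orthologs)
#' @param transposonFamilies,transposonCopies,transposonLength,transposonDivergence
#'   transposon family count, copies per family, consensus length, and
#'   copy divergence from consensus
#' @param pContig fraction of planted smORFs covered by RNA-seq contigs
#' @param pMultiSubstage fraction of covered plants with contigs in two or
#'   more embryonic substages
#' @param pTransfrag fraction of plants additionally covered by a transfrag
#' @param nDecoyContigs,nDecoyTransfrags decoy evidence items at random
#'   positions
#' @param substages embryonic substage labels
#' @param seed RNG seed; every output is deterministic given the seed
#' @return list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nChrom = 2L, chromLength = 500000L, gc = 0.42,
                            nAnchors = 40L, anchorLength = 1500L,
                            nPlanted = 60L, nTranslocated = 5L,
                            nQueryOnly = 5L, plantLenRange = c(30L, 300L),
                            omega = 0.05, ksTarget = 0.5,
                            neutralDivergence = 1.0, indelRate = 0.02,
                            anchorDivergence = 0.15,
                            transposonFamilies = 3L, transposonCopies = 10L,
                            transposonLength = 600L,
                            transposonDivergence = 0.1,
                            pContig = 1.0, pMultiSubstage = 0.95,
                            pTransfrag = 0.7, nDecoyContigs = 300L,
                            nDecoyTransfrags = 200L,
                            substages = c("E0_4", "E4_8", "E8_12", "E12_16",
                                          "E16_20", "E20_24"),
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(gc >= 0, gc <= 1, omega >= 0, ksTarget >= 0,
            pContig >= 0, pContig <= 1, pMultiSubstage >= 0,
            pMultiSubstage <= 1, pTransfrag >= 0, pTransfrag <= 1,
            plantLenRange[1] >= 30L, plantLenRange[2] <= 300L,
            nTranslocated + nQueryOnly <= nPlanted)
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

sround <- function(x) floor(x) + (runif(length(x)) < x - floor(x))

#' Neutral (Jukes-Cantor) sequence evolution
#'
#' Per-site substitution with probability \eqn{p = 3/4 (1 - e^{-4d/3})}
#' at divergence d expected substitutions/site, substituting to a uniform
#' other base; optional small indels (geometric lengths, capped at 10 bp)
#' at \code{indelRate} events per site.
#'
#' @param nt DNA string
#' @param divergence expected substitutions per site (>= 0)
#' @param seed optional RNG seed
#' @param indelRate indel events per site (default 0)
#' @return the diverged sequence (character).
#' @export
evolveNeutral <- function(nt, divergence, seed = NULL, indelRate = 0) {
  stopifnot(divergence >= 0)
  with_seed(seed, {
    ch <- strsplit(nt, "")[[1]]
    L <- length(ch)
    if (L == 0L) return(nt)
    p <- 0.75 * (1 - exp(-4 * divergence / 3))
    hit <- which(runif(L) < p & ch %in% BASES)
    if (length(hit)) {
      off <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- BASES[(match(ch[hit], BASES) - 1L + off) %% 4L + 1L]
    }
    if (indelRate > 0) {
      nind <- rpois(1, indelRate * L)
      for (k in seq_len(nind)) {
        pos <- sample.int(length(ch), 1L)
        len <- min(rgeom(1, 0.5) + 1L, 10L)
        if (runif(1) < 0.5) {
          ch <- ch[-(pos:min(pos + len - 1L, length(ch)))]
          if (!length(ch)) ch <- sample(BASES, 1L)
        } else {
          ch <- append(ch, sample(BASES, len, replace = TRUE), after = pos)
        }
      }
    }
    paste0(ch, collapse = "")
  })
}

#' Evolve a coding ORF at a target synonymous divergence and omega
#'
#' Applies a conditioned substitution process to an ORF (ATG...stop): the
#' number of synonymous events is the stochastic rounding of
#' \code{ksTarget * S} and the number of nonsynonymous events the
#' stochastic rounding of \code{omega * ksTarget * N} (S, N = Nei-Gojobori
#' site counts over the mutable codons), so planted sequences realize the
#' nominal divergence up to rounding. Proposals are random single-nucleotide
#' changes; proposals creating internal stops or touching the start/stop
#' codons are rejected. With \code{omega = 0} the protein is unchanged;
#' with \code{ksTarget = 0} the sequence is returned as is.
#'
#' @param ntOrf ORF sequence (begins ATG, ends in a stop codon)
#' @param ksTarget target synonymous substitutions per synonymous site
#' @param omega target Ka/Ks
#' @param seed optional RNG seed
#' @return diverged ORF (character) with attributes \code{nSyn},
#'   \code{nNonsyn}, \code{S}, \code{N}, \code{realizedKs}.
#' @export
evolveCoding <- function(ntOrf, ksTarget, omega, seed = NULL) {
  stopifnot(nchar(ntOrf) %% 3 == 0, omega >= 0, ksTarget >= 0)
  with_seed(seed, {
    L <- nchar(ntOrf)
    cod <- substring(ntOrf, seq(1, L, 3), seq(3, L, 3))
    ncod <- length(cod)
    mutable <- setdiff(seq_len(ncod), c(1L, ncod))
    tab <- ng_sites_table()
    S <- sum(tab[cod[mutable], "s"])
    N <- sum(tab[cod[mutable], "n"])
    ns <- sround(ksTarget * S)
    nn <- sround(omega * ksTarget * N)
    events <- sample(c(rep(TRUE, ns), rep(FALSE, nn)))  # TRUE = synonymous
    for (syn in events) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) break
        i <- mutable[sample.int(length(mutable), 1L)]
        p <- sample.int(3L, 1L)
        b <- sample(setdiff(BASES, substr(cod[i], p, p)), 1L)
        m <- cod[i]
        substr(m, p, p) <- b
        if (CODON_TABLE[[m]] == "*") next
        if ((CODON_TABLE[[m]] == CODON_TABLE[[cod[i]]]) == syn) {
          cod[i] <- m
          break
        }
      }
    }
    out <- paste0(cod, collapse = "")
    attr(out, "nSyn") <- ns
    attr(out, "nNonsyn") <- nn
    attr(out, "S") <- S
    attr(out, "N") <- N
    attr(out, "realizedKs") <- if (S > 0) ns / S else 0
    out
  })
}

random_orf <- function(lenNt) {
  ncod <- lenNt %/% 3L
  paste0(c("ATG", sample(SENSE_CODONS, ncod - 2L, replace = TRUE),
           sample(STOP_CODONS, 1L)), collapse = "")
}

#' Generate a synthetic genome pair with planted ground truth
#'
#' Builds a query genome (background + colinear anchor genes + transposon
#' copies + planted smORF cassettes) and a subject genome in which the
#' background has diverged neutrally, anchors are conserved, planted
#' smORFs evolved under [evolveCoding()] at homologous (or translocated)
#' positions, and query-only plants are replaced by fresh background.
#' Planted cassettes carry an in-frame stop immediately upstream of the
#' ATG so that the planted start codon is the ORF's 5'-most start, in both
#' genomes. All outputs are deterministic given the configuration seed.
#'
#' @param config a [syntheticConfig()] list
#' @return list: queryGenome, subjectGenome (DNAStringSets), annotation
#'   (GRanges: exon/CDS/gene for anchors, transposon copies), anchors
#'   (data.frame), exclusionDb (DNAStringSet: transposon consensi + anchor
#'   CDS), evidence (GRanges), truth (data.frame of planted smORFs), and
#'   the config.
#' @export
generateGenomePair <- function(config = syntheticConfig()) {
  with_seed(config$seed, generate_pair_impl(config))
}

generate_pair_impl <- function(cfg) {
  nC <- cfg$nChrom
  chroms <- paste0("chr", seq_len(nC))
  # transposon families and copies
  fams <- vapply(seq_len(cfg$transposonFamilies), function(i)
    random_dna(cfg$transposonLength, cfg$gc), character(1))
  names(fams) <- paste0("TEfam", seq_len(cfg$transposonFamilies))
  # planted smORFs
  lens <- sample(seq(cfg$plantLenRange[1], cfg$plantLenRange[2], by = 3L),
                 cfg$nPlanted, replace = TRUE)
  cat_pool <- c(rep("translocated", cfg$nTranslocated),
                rep("query_only", cfg$nQueryOnly),
                rep("conserved", cfg$nPlanted - cfg$nTranslocated -
                      cfg$nQueryOnly))
  plant_cat <- sample(cat_pool)
  plant_strand <- sample(c("+", "-"), cfg$nPlanted, replace = TRUE)
  plant_orf <- vapply(lens, random_orf, character(1))

  # assign elements to chromosomes
  anchor_chrom <- rep(chroms, length.out = cfg$nAnchors)
  te_n <- cfg$transposonFamilies * cfg$transposonCopies
  te_chrom <- sample(chroms, te_n, replace = TRUE)
  te_fam <- rep(seq_len(cfg$transposonFamilies), each = cfg$transposonCopies)
  plant_chrom <- sample(chroms, cfg$nPlanted, replace = TRUE)

  plans <- list()
  for (ci in seq_len(nC)) {
    elems <- list()
    for (ai in which(anchor_chrom == chroms[ci]))
      elems[[length(elems) + 1L]] <- list(type = "anchor", id = ai,
        seq = random_dna(cfg$anchorLength, cfg$gc))
    for (ti in which(te_chrom == chroms[ci]))
      elems[[length(elems) + 1L]] <- list(type = "transposon", id = ti,
        seq = evolveNeutral(fams[te_fam[ti]], cfg$transposonDivergence))
    for (pi in which(plant_chrom == chroms[ci])) {
      cassette <- paste0("TAA", plant_orf[pi])
      if (plant_strand[pi] == "-") cassette <- revcomp_chr(cassette)
      elems[[length(elems) + 1L]] <- list(type = "plant", id = pi,
        seq = cassette)
    }
    # anchors stay colinear and ordered; other elements shuffle between them
    is_anchor <- vapply(elems, function(e) e$type == "anchor", logical(1))
    others <- sample(which(!is_anchor))
    # interleave: keep anchor order, scatter the rest uniformly
    ord <- integer(0)
    anchor_idx <- which(is_anchor)
    n_slots <- length(elems)
    take_other <- sort(sample(seq_len(n_slots), length(others)))
    k_a <- 1L; k_o <- 1L
    for (s in seq_len(n_slots)) {
      if (s %in% take_other && k_o <= length(others)) {
        ord <- c(ord, others[k_o]); k_o <- k_o + 1L
      } else if (k_a <= length(anchor_idx)) {
        ord <- c(ord, anchor_idx[k_a]); k_a <- k_a + 1L
      } else {
        ord <- c(ord, others[k_o]); k_o <- k_o + 1L
      }
    }
    elems <- elems[ord]
    elen <- sum(vapply(elems, function(e) nchar(e$seq), numeric(1)))
    bgTotal <- cfg$chromLength - elen
    if (bgTotal < 100L * (length(elems) + 1L))
      stop("requested insertions exceed genome capacity")
    w <- runif(length(elems) + 1L) + 0.1
    bglen <- floor(bgTotal * w / sum(w))
    bglen[1] <- bglen[1] + (bgTotal - sum(bglen))
    bg <- lapply(bglen, random_dna, gc = cfg$gc)
    plans[[ci]] <- list(elems = elems, bglen = bglen, bg = bg)
  }

  # build query genome, record query coordinates
  qseq <- character(nC)
  anchors_q <- data.frame(); truth <- data.frame(); te_q <- data.frame()
  anchor_seq_q <- list()
  for (ci in seq_len(nC)) {
    pl <- plans[[ci]]
    parts <- character(0); pos <- 0L
    for (k in seq_along(pl$elems)) {
      parts <- c(parts, pl$bg[[k]]); pos <- pos + pl$bglen[k]
      e <- pl$elems[[k]]
      parts <- c(parts, e$seq)
      st <- pos + 1L; en <- pos + nchar(e$seq)
      pl$elems[[k]]$qstart <- st; pl$elems[[k]]$qend <- en
      pos <- en
      if (e$type == "anchor") {
        anchors_q <- rbind(anchors_q, data.frame(id = e$id,
          qchrom = chroms[ci], qstart = st, qend = en))
        anchor_seq_q[[as.character(e$id)]] <- e$seq
      } else if (e$type == "transposon") {
        te_q <- rbind(te_q, data.frame(chrom = chroms[ci], start = st,
                                       end = en))
      } else {
        pi <- e$id
        if (plant_strand[pi] == "+") { os <- st + 3L; oe <- en }
        else { os <- st; oe <- en - 3L }
        truth <- rbind(truth, data.frame(id = paste0("plant", pi),
          category = plant_cat[pi], qchrom = chroms[ci], qstart = os,
          qend = oe, strand = plant_strand[pi], lengthNt = lens[pi],
          codons = lens[pi] / 3, omega = cfg$omega,
          ksTarget = cfg$ksTarget, schrom = NA_character_,
          sstart = NA_integer_, send = NA_integer_,
          stringsAsFactors = FALSE))
      }
    }
    parts <- c(parts, pl$bg[[length(pl$bg)]])
    qseq[ci] <- paste0(parts, collapse = "")
    plans[[ci]] <- pl
  }
  names(qseq) <- chroms

  # subject genome: walk the same plans
  sseq <- character(nC)
  anchors_s <- data.frame()
  transloc <- list()
  subj_orf <- setNames(vector("list", cfg$nPlanted), paste0("plant",
                       seq_len(cfg$nPlanted)))
  for (ci in seq_len(nC)) {
    pl <- plans[[ci]]
    parts <- character(0); pos <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    for (k in seq_along(pl$elems)) {
      add(evolveNeutral(pl$bg[[k]], cfg$neutralDivergence,
                        indelRate = cfg$indelRate))
      e <- pl$elems[[k]]
      if (e$type == "anchor") {
        s2 <- evolveNeutral(e$seq, cfg$anchorDivergence)
        anchors_s <- rbind(anchors_s, data.frame(id = e$id,
          schrom = chroms[ci], sstart = pos + 1L, send = pos + nchar(s2)))
        add(s2)
      } else if (e$type == "transposon") {
        add(evolveNeutral(e$seq, cfg$neutralDivergence,
                          indelRate = cfg$indelRate))
      } else {
        pi <- e$id
        if (plant_cat[pi] == "query_only") {
          add(random_dna(nchar(e$seq), cfg$gc))
        } else {
          orf2 <- as.character(evolveCoding(plant_orf[pi], cfg$ksTarget,
                                            cfg$omega))
          cassette <- paste0("TAA", orf2)
          if (plant_strand[pi] == "-") cassette <- revcomp_chr(cassette)
          if (plant_cat[pi] == "translocated") {
            transloc[[length(transloc) + 1L]] <- list(pi = pi,
              cassette = cassette, from = ci)
          } else {
            st <- pos + 1L; en <- pos + nchar(cassette)
            if (plant_strand[pi] == "+") { os <- st + 3L; oe <- en }
            else { os <- st; oe <- en - 3L }
            subj_orf[[paste0("plant", pi)]] <- list(chrom = chroms[ci],
              start = os, end = oe)
            add(cassette)
          }
        }
      }
    }
    add(evolveNeutral(pl$bg[[length(pl$bg)]], cfg$neutralDivergence,
                      indelRate = cfg$indelRate))
    sseq[ci] <- paste0(unlist(parts), collapse = "")
  }
  names(sseq) <- chroms
  # translocated plants: append on a different subject chromosome
  for (tr in transloc) {
    dest <- if (nC > 1L) chroms[(tr$from %% nC) + 1L] else chroms[1]
    spacer <- random_dna(500L, cfg$gc)
    base <- nchar(sseq[dest]) + nchar(spacer)
    st <- base + 1L; en <- base + nchar(tr$cassette)
    if (plant_strand[tr$pi] == "+") { os <- st + 3L; oe <- en }
    else { os <- st; oe <- en - 3L }
    subj_orf[[paste0("plant", tr$pi)]] <- list(chrom = dest, start = os,
                                               end = oe)
    sseq[dest] <- paste0(sseq[dest], spacer, tr$cassette)
  }
  for (i in seq_len(nrow(truth))) {
    so <- subj_orf[[truth$id[i]]]
    if (!is.null(so)) {
      truth$schrom[i] <- so$chrom
      truth$sstart[i] <- so$start
      truth$send[i] <- so$end
    }
  }

  anchors <- merge(anchors_q, anchors_s, by = "id")
  anchors$gene <- paste0("anchor", anchors$id)
  anchors <- anchors[order(anchors$qchrom, anchors$qstart),
                     c("qchrom", "qstart", "qend", "schrom", "sstart",
                       "send", "gene")]
  rownames(anchors) <- NULL

  ann <- c(
    GRanges(anchors$qchrom, IRanges(anchors$qstart, anchors$qend),
            strand = "+", featureClass = "exon"),
    GRanges(anchors$qchrom, IRanges(anchors$qstart, anchors$qend),
            strand = "+", featureClass = "CDS"),
    GRanges(anchors$qchrom, IRanges(anchors$qstart, anchors$qend),
            strand = "+", featureClass = "gene"),
    if (nrow(te_q)) GRanges(te_q$chrom, IRanges(te_q$start, te_q$end),
                            strand = "+", featureClass = "transposon")
    else GRanges())

  qgenome <- DNAStringSet(qseq)
  sgenome <- DNAStringSet(sseq)
  seqlengths(ann) <- Biostrings::width(qgenome)[match(seqlevels(ann),
                                                      names(qgenome))]
  db <- DNAStringSet(c(fams, setNames(unlist(anchor_seq_q),
                                      paste0("anchorCDS",
                                             names(anchor_seq_q)))))
  evidence <- generate_evidence_impl(truth, cfg,
                                     setNames(Biostrings::width(qgenome),
                                              names(qgenome)))
  list(queryGenome = qgenome, subjectGenome = sgenome, annotation = ann,
       anchors = anchors, exclusionDb = db, evidence = evidence,
       truth = truth, config = cfg)
}

#' Generate transcription evidence for planted smORFs plus decoys
#'
#' For the configured fractions of planted smORFs, emits same-strand
#' RNA-seq contigs labeled with embryonic substages (two substages with
#' probability \code{pMultiSubstage}, otherwise one) and ~200 bp
#' transfrags; decoy contigs and transfrags are placed at random positions
#' and never provide more than single-contig support by construction.
#'
#' @param truth truth data.frame from [generateGenomePair()]
#' @param config the [syntheticConfig()]
#' @param chromLengths named lengths of the query chromosomes
#' @param seed optional seed (the generator already seeds this internally)
#' @return stranded GRanges with mcols \code{kind} and \code{substage}.
#' @export
generateEvidence <- function(truth, config, chromLengths, seed = NULL) {
  with_seed(seed, generate_evidence_impl(truth, config, chromLengths))
}

generate_evidence_impl <- function(truth, cfg, chromLengths) {
  chrom <- character(); st <- integer(); en <- integer()
  strand <- character(); kind <- character(); substage <- character()
  emit <- function(ch, s, e, str, kd, sb) {
    L <- chromLengths[[ch]]
    chrom <<- c(chrom, ch); st <<- c(st, max(1L, s))
    en <<- c(en, min(L, e)); strand <<- c(strand, str)
    kind <<- c(kind, kd); substage <<- c(substage, sb)
  }
  for (i in seq_len(nrow(truth))) {
    if (runif(1) > cfg$pContig) next
    ch <- truth$qchrom[i]; str <- truth$strand[i]
    qs <- truth$qstart[i]; qe <- truth$qend[i]
    nsub <- if (runif(1) < cfg$pMultiSubstage) 2L else 1L
    subs <- sample(cfg$substages, nsub)
    for (sb in subs)
      emit(ch, qs - sample.int(100L, 1L), qe + sample.int(100L, 1L), str,
           "rnaseq_contig", sb)
    if (runif(1) < cfg$pTransfrag) {
      c0 <- qs + sample.int(max(1L, qe - qs), 1L) - 1L
      emit(ch, c0 - 100L, c0 + 100L, str, "transfrag", ".")
    }
  }
  for (k in seq_len(cfg$nDecoyContigs)) {
    ch <- sample(names(chromLengths), 1L)
    s0 <- sample.int(chromLengths[[ch]] - 400L, 1L)
    emit(ch, s0, s0 + sample(150:400, 1L), sample(c("+", "-"), 1L),
         "rnaseq_contig", sample(cfg$substages, 1L))
  }
  for (k in seq_len(cfg$nDecoyTransfrags)) {
    ch <- sample(names(chromLengths), 1L)
    s0 <- sample.int(chromLengths[[ch]] - 250L, 1L)
    emit(ch, s0, s0 + 200L, sample(c("+", "-"), 1L), "transfrag", ".")
  }
  gr <- GRanges(chrom, IRanges(st, en), strand = strand, kind = kind,
                substage = substage)
  mcols(gr)$substage[mcols(gr)$kind == "transfrag"] <- NA_character_
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Construct the worked multiple-evidence example instance
#'
#' Builds one synthetic smORF per qualifying transcription-evidence case at
#' the requested multiplicities (contigs in two substages; two contigs in
#' one substage; one contig plus a transfrag), plus distractor smORFs each
#' overlapping at most one contig and no transfrag, and returns the smORFs
#' with their evidence so the multiple-evidence rule can be tallied.
#'
#' @param nMultiSubstage,nMultiContigOneSubstage,nContigPlusTransfrag
#'   multiplicities of the three qualifying cases
#' @param nDistractors smORFs with at most single-contig support
#' @param seed RNG seed
#' @return list: \code{smorfs} (stranded GRanges), \code{evidence}
#'   (GRanges with kind/substage), \code{expected} (per-smORF expected
#'   case).
#' @export
simulateEvidenceCases <- function(nMultiSubstage, nMultiContigOneSubstage,
                                  nContigPlusTransfrag, nDistractors,
                                  seed = 1L) {
  n <- nMultiSubstage + nMultiContigOneSubstage + nContigPlusTransfrag +
    nDistractors
  with_seed(seed, {
    starts <- 1000L + (seq_len(n) - 1L) * 1000L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    smorfs <- GRanges("chrE", IRanges(starts, starts + 89L),
                      strand = strands)
    names(smorfs) <- paste0("s", seq_len(n))
    expected <- rep(c("multi_substage", "multi_contig_one_substage",
                      "contig_plus_transfrag", "none"),
                    c(nMultiSubstage, nMultiContigOneSubstage,
                      nContigPlusTransfrag, nDistractors))
    ch <- character(); st <- integer(); en <- integer()
    strv <- character(); kind <- character(); sub <- character()
    emit <- function(s, e, str, kd, sb) {
      ch <<- c(ch, "chrE"); st <<- c(st, s); en <<- c(en, e)
      strv <<- c(strv, str); kind <<- c(kind, kd); sub <<- c(sub, sb)
    }
    for (i in seq_len(n)) {
      s <- starts[i]; e <- s + 89L; str <- strands[i]
      case <- expected[i]
      if (case == "multi_substage") {
        emit(s - 20L, e + 10L, str, "rnaseq_contig", "E0_4")
        emit(s - 5L, e + 30L, str, "rnaseq_contig", "E8_12")
      } else if (case == "multi_contig_one_substage") {
        emit(s - 20L, s + 40L, str, "rnaseq_contig", "E4_8")
        emit(s + 30L, e + 20L, str, "rnaseq_contig", "E4_8")
      } else if (case == "contig_plus_transfrag") {
        emit(s - 10L, e + 10L, str, "rnaseq_contig", "E12_16")
        emit(s - 50L, s + 150L, str, "transfrag", NA_character_)
      } else {
        # distractor: at most one same-strand contig, no transfrag;
        # some get only an antisense contig, some nothing
        u <- runif(1)
        if (u < 0.4) emit(s - 10L, e + 10L, str, "rnaseq_contig", "E16_20")
        else if (u < 0.7) emit(s - 10L, e + 10L,
                               if (str == "+") "-" else "+",
                               "rnaseq_contig", "E16_20")
      }
    }
    evidence <- GRanges(ch, IRanges(st, en), strand = strv, kind = kind,
                        substage = sub)
    list(smorfs = smorfs, evidence = evidence, expected = expected)
  })
}

#' Score pipeline output against planted ground truth
#'
#' Sensitivity is the fraction of planted conserved smORFs (optionally
#' restricted by category and minimum codon count) recovered among the
#' surviving records; the empirical FDR is the fraction of survivors not
#' matching any planted smORF. Matching is same-strand coordinate overlap
#' on the query genome.
#'
#' @param result a [runPipeline()] result (or a GRanges of survivors)
#' @param truth truth data.frame from [generateGenomePair()]
#' @param finalClass records class counted as survivors (default the
#'   conservative set)
#' @param categories planted categories counted in the denominator
#' @param minCodons restrict the denominator to plants with at least this
#'   many codons
#' @return list: sensitivity, fdr, nSurvivors, nPlanted, recovered (ids),
#'   attrition (per-stage table when available).
#' @export
scoreRecovery <- function(result, truth, finalClass = "conservative_set",
                          categories = "conserved", minCodons = NULL) {
  if (is(result, "GRanges")) {
    surv <- result
    attrition <- NULL
  } else {
    rec <- result$records
    keep <- rec$finalClass %in% finalClass
    surv <- GRanges(rec$chrom[keep], IRanges(rec$start[keep],
                                             rec$end[keep]),
                    strand = rec$strand[keep])
    names(surv) <- rec$id[keep]
    attrition <- result$report
  }
  tr <- truth[truth$category %in% categories, , drop = FALSE]
  if (!is.null(minCodons)) tr <- tr[tr$codons >= minCodons, , drop = FALSE]
  tgr <- GRanges(tr$qchrom, IRanges(tr$qstart, tr$qend), strand = tr$strand)
  allgr <- GRanges(truth$qchrom, IRanges(truth$qstart, truth$qend),
                   strand = truth$strand)
  recov <- overlapsAny_strand(tgr, surv)
  fp <- !overlapsAny_strand(surv, allgr)
  list(sensitivity = if (nrow(tr)) mean(recov) else NA_real_,
       fdr = if (length(surv)) mean(fp) else 0,
       nSurvivors = length(surv), nPlanted = nrow(tr),
       recovered = tr$id[recov], attrition = attrition)
}

overlapsAny_strand <- function(a, b) {
  if (!length(a)) return(logical(0))
  if (!length(b)) return(rep(FALSE, length(a)))
  ov <- findOverlaps(a, b, ignore.strand = FALSE)
  seq_along(a) %in% queryHits(ov)
}

#' Write the synthetic dataset in standard on-disk formats
#'
#' FASTA genomes, GFF3 annotation, BED evidence, TSV anchors and truth.
#'
#' @param sim result of [generateGenomePair()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(sim$queryGenome, file.path(dir, "query.fa"))
  writeXStringSet(sim$subjectGenome, file.path(dir, "subject.fa"))
  writeXStringSet(sim$exclusionDb, file.path(dir, "exclusion_db.fa"))
  ann <- sim$annotation
  mcols(ann)$type <- mcols(ann)$featureClass
  mcols(ann)$phase <- ifelse(mcols(ann)$featureClass == "CDS", 0L,
                             NA_integer_)
  rtracklayer::export(ann, file.path(dir, "annotation.gff3"),
                      format = "gff3")
  ev <- sim$evidence
  df <- data.frame(chrom = as.character(seqnames(ev)),
                   start = start(ev) - 1L, end = end(ev),
                   name = paste0("ev", seq_along(ev)), score = 0L,
                   strand = as.character(strand(ev)),
                   kind = mcols(ev)$kind,
                   substage = ifelse(is.na(mcols(ev)$substage), ".",
                                     mcols(ev)$substage))
  write.table(df, file.path(dir, "evidence.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$anchors, file.path(dir, "anchors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
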