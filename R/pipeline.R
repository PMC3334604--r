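#' Pipeline configuration
#'
#' Inputs may be in-memory objects (DNAStringSet, GRanges, data.frame) or
#' file paths (FASTA / GFF3 / BED / TSV), which are read on demand. All
#' thresholds are recorded in the run report.
#'
#' @param queryGenome named DNAStringSet or FASTA path
#' @param annotation GRanges with featureClass mcol, or GFF3 path
#' @param subjectGenome named DNAStringSet or FASTA path
#' @param anchors anchor map data.frame or TSV path (see [readAnchorMap()])
#' @param evidence evidence GRanges or extended-BED path
#'   (see [readEvidenceBed()]); may be NULL (no transcription filter input)
#' @param exclusionDb DNAStringSet or FASTA path; may be NULL
#' @param eCut E-value threshold of the translated-search filter
#'   (default 1e-3; the relaxed analysis uses 0.05)
#' @param eMax E-value ceiling of the search itself (default 30)
#' @param exclusionECut E-value threshold of the nucleotide exclusion
#'   filter (default 1e-3)
#' @param kaksThreshold Ka/Ks acceptance threshold (default 0.1, the
#'   empirically calibrated 10% FDR value)
#' @param flank subject flank for conserved-ORF calling (default 300 bp)
#' @param searchWindow start/stop relocation window (default 30 nt)
#' @param slackBp synteny slack (default 50 kb)
#' @param minNt,maxNt smORF length bounds
#' @param seed seed recorded for sampling operations
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(queryGenome, annotation, subjectGenome, anchors,
                           evidence = NULL, exclusionDb = NULL,
                           eCut = 1e-3, eMax = 30, exclusionECut = 1e-3,
                           kaksThreshold = 0.1, flank = 300L,
                           searchWindow = 30L, slackBp = 50000L,
                           minNt = 30L, maxNt = 300L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(eCut > 0, eMax > 0, exclusionECut > 0, kaksThreshold > 0,
            flank > 0, slackBp >= 0)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

resolve_inputs <- function(cfg) {
  if (is.character(cfg$queryGenome))
    cfg$queryGenome <- readGenomeFasta(cfg$queryGenome)
  if (is.character(cfg$subjectGenome))
    cfg$subjectGenome <- readGenomeFasta(cfg$subjectGenome)
  if (is.character(cfg$annotation))
    cfg$annotation <- readFeatureAnnotation(cfg$annotation, "gff3")
  if (is.character(cfg$anchors)) cfg$anchors <- readAnchorMap(cfg$anchors)
  if (is.character(cfg$evidence)) cfg$evidence <- readEvidenceBed(cfg$evidence)
  if (is.character(cfg$exclusionDb))
    cfg$exclusionDb <- readGenomeFasta(cfg$exclusionDb)
  cfg
}

#' Run the full comparative smORF pipeline
#'
#' Stages: six-frame scan of non-exonic DNA; nucleotide exclusion filter;
#' seeded translated search against the subject genome; conserved-ORF
#' calling on the best hit; synteny; Ka/Ks; multiple evidence of
#' transcription. The conservative set is the conjunction full conserved
#' ORF AND syntenic AND Ka/Ks below threshold AND transcription pass; the
#' upper estimate is the full_orf pool.
#'
#' @param config a [pipelineConfig()]
#' @param cache optionally, the \code{cache} element of a previous run on
#'   the same inputs (reuses the scan and search, e.g. to re-filter at a
#'   different \code{eCut})
#' @param smorfs optionally, a pre-scanned [SmORFSet-class] to use instead
#'   of scanning (e.g. a subsample)
#' @return list: \code{records} (one row per candidate with every filter
#'   outcome), \code{report} (per-stage survivor counts and percentages),
#'   \code{venn} (8-cell partition of the conserved pool), \code{sizes}
#'   (codon-size summaries per pool), \code{cache}, \code{config}.
#' @export
runPipeline <- function(config, cache = NULL, smorfs = NULL) {
  cfg <- resolve_inputs(config)
  chromLen <- setNames(Biostrings::width(cfg$queryGenome),
                       names(cfg$queryGenome))

  if (!is.null(cache)) {
    smorfs <- cache$smorfs
    exclEv <- cache$exclEvalue
    hits <- cache$hits
  } else {
    if (is.null(smorfs)) {
      regions <- complementIntervals(cfg$annotation, chromLen)
      smorfs <- scanSmorfs(cfg$queryGenome, regions, cfg$minNt, cfg$maxNt)
    }
    excl <- nucleotideExclusionFilter(
      smorfs, if (is.null(cfg$exclusionDb)) DNAStringSet() else cfg$exclusionDb,
      eCut = cfg$exclusionECut)
    exclEv <- excl$evalue
    retained <- which(is.na(exclEv) | exclEv > cfg$exclusionECut)
    hits <- if (length(retained))
      translatedSearch(setNames(as.character(aaSeq(smorfs[retained])),
                                smorfIds(smorfs)[retained]),
                       cfg$subjectGenome, eMax = cfg$eMax)
    else empty_hits()
  }

  n <- length(smorfs)
  ids <- smorfIds(smorfs)
  gr <- smorfRanges(smorfs)
  rec <- data.frame(
    id = ids, chrom = as.character(seqnames(gr)), start = start(gr),
    end = end(gr), strand = as.character(strand(gr)),
    lengthNt = lengthNt(smorfs), codons = lengthNt(smorfs) / 3,
    excluded = !is.na(exclEv) & exclEv <= cfg$exclusionECut,
    bestEvalue = NA_real_, evaluePass = FALSE,
    orfCategory = NA_character_, subjChrom = NA_character_,
    subjStart = NA_integer_, subjEnd = NA_integer_, syntenic = FALSE,
    ka = NA_real_, ks = NA_real_, ratio = NA_real_,
    kaksStatus = NA_character_, kaksPass = FALSE,
    evidenceCase = NA_character_, transcriptionPass = FALSE,
    finalClass = NA_character_, stringsAsFactors = FALSE)

  if (nrow(hits)) {
    besthit <- hits[!duplicated(hits$query), , drop = FALSE]  # sorted by E
    m <- match(besthit$query, rec$id)
    rec$bestEvalue[m] <- besthit$evalue
  }
  rec$evaluePass <- !rec$excluded & !is.na(rec$bestEvalue) &
    rec$bestEvalue <= cfg$eCut

  # conserved-ORF call, synteny, Ka/Ks on E-value survivors
  idx_pass <- which(rec$evaluePass)
  if (length(idx_pass) && nrow(hits)) {
    besthit <- hits[!duplicated(hits$query), , drop = FALSE]
    rownames(besthit) <- besthit$query
    for (i in idx_pass) {
      hit <- besthit[rec$id[i], ]
      fl <- extractFlanks(hit, cfg$subjectGenome, cfg$flank)
      call <- callConservedOrf(smorfs[i], fl, cfg$searchWindow)
      rec$orfCategory[i] <- call$category
      rec$subjChrom[i] <- as.character(hit$chrom)
      rec$subjStart[i] <- hit$start
      rec$subjEnd[i] <- hit$end
      if (call$category == "full_orf") {
        so <- call$subjectOrf
        rec$subjStart[i] <- start(so)
        rec$subjEnd[i] <- end(so)
        rec$syntenic[i] <- isSyntenic(gr[i],
          list(chrom = as.character(seqnames(so)), start = start(so),
               end = end(so)), cfg$anchors, cfg$slackBp)
        kk <- computeKaKs(extractCodonPairs(call))
        rec$ka[i] <- kk$Ka; rec$ks[i] <- kk$Ks
        rec$ratio[i] <- kk$ratio; rec$kaksStatus[i] <- kk$status
        rec$kaksPass[i] <- !is.na(kk$ratio) && kk$ratio < cfg$kaksThreshold
      }
    }
  }

  # transcription evidence for the conserved pool
  conserved <- which(!is.na(rec$orfCategory) & rec$orfCategory == "full_orf")
  if (length(conserved) && !is.null(cfg$evidence) && length(cfg$evidence)) {
    prof <- buildEvidenceProfile(smorfs[conserved], cfg$evidence)
    me <- multipleEvidence(prof)
    rec$evidenceCase[conserved] <- me$case
    rec$transcriptionPass[conserved] <- me$passes
  } else if (length(conserved)) {
    rec$evidenceCase[conserved] <- "none"
  }

  conservative <- rec$orfCategory %in% "full_orf" & rec$syntenic &
    rec$kaksPass & rec$transcriptionPass
  rec$finalClass <- ifelse(rec$excluded, "rejected_exclusion",
    ifelse(!rec$evaluePass, "rejected_evalue",
    ifelse(!(rec$orfCategory %in% "full_orf"), "rejected_orf_structure",
    ifelse(conservative, "conservative_set", "conserved_only"))))

  venn <- vennPartition(rec)
  # internal cross-check: the conservative set is the all-true venn cell
  stopifnot(sum(conservative) ==
              venn[["syntenic+kaks+transcribed"]])

  stages <- c(scanned = n,
              post_exclusion = sum(!rec$excluded),
              evalue_pass = sum(rec$evaluePass),
              conserved_orf = sum(rec$orfCategory %in% "full_orf"),
              syntenic = sum(rec$orfCategory %in% "full_orf" & rec$syntenic),
              kaks_pass = sum(rec$orfCategory %in% "full_orf" &
                                rec$syntenic & rec$kaksPass),
              conservative = sum(conservative))
  report <- data.frame(stage = names(stages), survivors = as.integer(stages),
                       pct_of_previous = round(100 * as.integer(stages) /
                         c(NA, utils::head(as.integer(stages), -1)), 2),
                       row.names = NULL)

  sizes <- list(
    scanned = if (n) summarizeSizes(rec$codons) else NULL,
    evalue_pass = if (any(rec$evaluePass))
      summarizeSizes(rec$codons[rec$evaluePass]) else NULL,
    conserved = if (length(conserved))
      summarizeSizes(rec$codons[conserved]) else NULL,
    conservative = if (any(conservative))
      summarizeSizes(rec$codons[conservative]) else NULL)

  list(records = rec, report = report, venn = venn, sizes = sizes,
       cache = list(smorfs = smorfs, exclEvalue = exclEv, hits = hits),
       config = cfg)
}

#' Venn partition of the conserved-ORF pool
#'
#' Among records called full conserved ORFs, counts the 8 cells of the
#' (syntenic, Ka/Ks pass, transcription pass) partition; the cells sum to
#' the conserved total.
#'
#' @param records records data.frame from [runPipeline()]
#' @return named integer vector of 8 cell counts.
#' @export
vennPartition <- function(records) {
  r <- records[records$orfCategory %in% "full_orf", , drop = FALSE]
  cell <- function(s, k, t) sum(r$syntenic == s & r$kaksPass == k &
                                  r$transcriptionPass == t)
  c("none" = cell(FALSE, FALSE, FALSE),
    "syntenic" = cell(TRUE, FALSE, FALSE),
    "kaks" = cell(FALSE, TRUE, FALSE),
    "transcribed" = cell(FALSE, FALSE, TRUE),
    "syntenic+kaks" = cell(TRUE, TRUE, FALSE),
    "syntenic+transcribed" = cell(TRUE, FALSE, TRUE),
    "kaks+transcribed" = cell(FALSE, TRUE, TRUE),
    "syntenic+kaks+transcribed" = cell(TRUE, TRUE, TRUE))
}

#' Tabulate per-filter passes for an annotated validation set
#'
#' Applies the pipeline's pass rules to a table of per-smORF metrics:
#' translated-search E-value < 1e-3, Ka/Ks < 0.1, syntenic TRUE, RNA-seq
#' overlaps > 1; NA always fails. Returns the per-filter pass counts and
#' the count passing all four filters.
#'
#' @param table data.frame (or TSV path) with columns gene, codons,
#'   evalue, kaks, syntenic, overlaps (extra columns ignored; NA for
#'   missing values)
#' @return list: \code{counts} (evalue, kaks, synteny, overlaps),
#'   \code{passAll}, \code{table} (with per-filter logicals).
#' @export
validateAnnotatedSet <- function(table) {
  if (is.character(table))
    table <- read.delim(table, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "evalue", "kaks", "syntenic", "overlaps")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(table$gene) | !nzchar(table$gene))
  if (length(bad)) stop("malformed row(s): ", paste(bad, collapse = ", "))
  syn <- table$syntenic
  if (!is.logical(syn)) syn <- toupper(as.character(syn)) == "TRUE"
  table$pass_evalue <- !is.na(table$evalue) & table$evalue < 1e-3
  table$pass_kaks <- !is.na(table$kaks) & table$kaks < 0.1
  table$pass_synteny <- !is.na(syn) & syn
  table$pass_overlaps <- !is.na(table$overlaps) & table$overlaps > 1
  passAll <- table$pass_evalue & table$pass_kaks & table$pass_synteny &
    table$pass_overlaps
  list(counts = c(evalue = sum(table$pass_evalue),
                  kaks = sum(table$pass_kaks),
                  synteny = sum(table$pass_synteny),
                  overlaps = sum(table$pass_overlaps)),
       passAll = sum(passAll), table = table)
}

#' Run the pipeline on a stratified random subsample and extrapolate
#'
#' Selects a per-chromosome quota (or a fraction) of the scanned smORFs,
#' runs the remaining pipeline stages on the subsample, and extrapolates a
#' genome-wide estimate as survivors / fraction, rounded.
#'
#' @param config a [pipelineConfig()]
#' @param fraction fraction of the scanned pool to keep (ignored when
#'   \code{perChromQuota} is given)
#' @param perChromQuota named integer vector of per-chromosome sample sizes
#' @param seed sampling seed
#' @return list: survivors, fractionUsed, estimate, result (the subsample
#'   run).
#' @export
relaxedSubsampleRun <- function(config, fraction = NULL,
                                perChromQuota = NULL, seed = 1L) {
  cfg <- resolve_inputs(config)
  chromLen <- setNames(Biostrings::width(cfg$queryGenome),
                       names(cfg$queryGenome))
  regions <- complementIntervals(cfg$annotation, chromLen)
  smorfs <- scanSmorfs(cfg$queryGenome, regions, cfg$minNt, cfg$maxNt)
  chrom <- as.character(seqnames(smorfRanges(smorfs)))
  idx <- with_seed(seed, {
    if (!is.null(perChromQuota)) {
      unlist(lapply(names(perChromQuota), function(ch) {
        cand <- which(chrom == ch)
        sample(cand, min(perChromQuota[[ch]], length(cand)))
      }))
    } else {
      stopifnot(fraction > 0, fraction <= 1)
      unlist(lapply(unique(chrom), function(ch) {
        cand <- which(chrom == ch)
        sample(cand, round(fraction * length(cand)))
      }))
    }
  })
  idx <- sort(idx)
  fracUsed <- length(idx) / length(smorfs)
  res <- runPipeline(cfg, smorfs = smorfs[idx])
  surv <- sum(res$records$finalClass == "conservative_set")
  list(survivors = surv, fractionUsed = fracUsed,
       estimate = extrapolateCount(surv, fracUsed), result = res)
}

#' Extrapolate a genome-wide count from a sampled fraction
#'
#' @param survivors count observed in the sample
#' @param fraction sampled fraction of the pool
#' @return \code{round(survivors / fraction)}.
#' @export
extrapolateCount <- function(survivors, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  round(survivors / fraction)
}

#' Average euchromatic spacing of smORFs
#'
#' Base pairs of double-stranded euchromatin per smORF: both strands are
#' scanned, so the spacing is 2 x euchromatin length / count.
#'
#' @param euchromatinBp single-strand euchromatin length in bp
#' @param nSmorfs number of smORFs
#' @return bp per smORF.
#' @export
smorfDensity <- function(euchromatinBp, nSmorfs) {
  2 * euchromatinBp / nSmorfs
}
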