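---
title: "Comparative smORF discovery: models, parameters and design choices"
author: "smORFpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative smORF discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smORFpipe)
```

## The problem

Small open reading frames (smORFs; here, single-exon ORFs of 30-300 nt,
encoding at most 99 amino acids) are systematically under-annotated: at
these lengths, chance ORFs in non-coding DNA vastly outnumber functional
ones, so length- and homology-based gene finders discard them wholesale.
The strategy implemented by this package rescues the functional minority
through converging, independently calibrated filters applied to a pair of
related genomes (a *query*, in which candidates are scanned, and a
*subject*, against which conservation is assessed):

1. **Scan** all six frames of the query's non-exonic DNA for ATG-to-stop
   ORFs within the length bounds.
2. **Exclude** candidates with significant nucleotide similarity to
   annotated coding sequences or transposons.
3. **Translated search**: compare each candidate peptide against the
   six-frame translation of the subject genome; at near-saturated
   synonymous divergence, amino-acid-level similarity is evidence of
   selection, not common descent of neutral sequence.
4. **Conserved ORF structure**: require an in-frame start and stop in the
   subject around the hit — similarity alone could reflect pseudogenes or
   other conserved elements.
5. **Synteny**: require the subject hit to lie between the subject
   orthologs of the query's flanking anchor genes.
6. **Ka/Ks**: require a nonsynonymous/synonymous rate ratio below a
   threshold calibrated by an empirical FDR procedure.
7. **Transcription**: require multiple, strand-consistent overlap with
   transcription evidence.

The intersection of filters 4-7 defines the *conservative set*; the pool
passing filter 4 alone is the *upper estimate*.

## Statistical machinery

### Seeded translated search and E-values

The search is a seed-and-extend local aligner over the six-frame
translation of the subject: query 3-mers are expanded to all words scoring
at least `neighborThresh` (default 12) under BLOSUM62; word matches are
extended ungapped under an X-drop rule; extensions reaching the gapped
trigger undergo an exact local DP over a query-sized window. Raw scores S
convert to E-values by the Karlin-Altschul formula
\(E = K m n e^{-\lambda S}\), with \(m\) the query length and \(n\) the
total residue count across all six frames. \(\lambda\) and \(K\) are
fixed, documented constants per scoring configuration (BLOSUM62 with gap
open 11 / extend 1: \(\lambda = 0.267\), \(K = 0.041\); nucleotide
+2/-3 with gap 5/2: \(\lambda = 0.634\), \(K = 0.408\)); no on-the-fly
estimation is attempted. The gapped trigger defaults to the raw score at
which a hit would reach `eMax` minus a safety margin, so chance seeds far
below reportability are never gap-extended; like all seeded heuristics
this can miss hits whose E-value lies far above `eMax`, but hits near the
decision thresholds (1e-3, 0.05) have ungapped cores well above the
trigger. The search itself runs at the permissive ceiling `eMax = 30`;
decisions are taken downstream at the configured cutoff, so the same
search supports both the strict (1e-3) and relaxed (0.05) analyses.

### Conserved-ORF calling

Because a local aligner reports only the most similar segment, the
subject hit is extended by 300 bp on each side, the query ORF is
re-aligned globally (affine gaps, free end gaps on the window only), and
the query's start and stop codon positions are projected through the
alignment. An ATG and an in-frame stop are sought within 30 nt (in-frame
steps, nearest projection first) of the projected positions; a valid pair
must have no internal in-frame stop between them. The 30-nt relocation
window tolerates small terminal indels without accepting arbitrary ORFs —
the 300-bp flank bounds the search regardless. A net indel not divisible
by 3 inside the ORF span is a frame disruption and the call falls back to
`similarity_only`. The nearest in-frame ATG is accepted even if it is not
the alignment-projected one (the projected codon may have drifted by a
codon or two); consequently a subject whose original start decayed but
which retains another nearby in-frame ATG is still a full ORF, which we
consider biologically correct. The subject ORF's length is deliberately
not re-capped at 300 nt.

### Ka/Ks

The estimator is Nei-Gojobori: per-codon synonymous site counts
\(s = \sum_{p=1}^{3} (\text{synonymous mutants}/\text{viable mutants})\)
with mutations to stop codons excluded from the viable count; differences
between aligned codons averaged over all minimal mutational pathways,
excluding pathways through stops (falling back to all pathways when none
is stop-free); Jukes-Cantor correction
\(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\). Codon pairs come only from
alignment columns where both sequences carry an ungapped codon; the start
codon is included and the stop codon excluded. NA semantics are explicit:
`na_empty` (no pairs), `na_no_syn_info` (Ks = 0 — including the identical
case, where a ratio would be 0/0), `na_saturated` (p at or beyond 3/4).
A ratio of 0 (Ka = 0 with Ks > 0) *passes* a `< 0.1` threshold; the `0`
reporting bin is kept distinct from `(0, 0.1)`. This pathway-averaged
counting estimator was chosen over maximum-likelihood codon models
because it is deterministic, fully specified, oracle-checkable by direct
enumeration, and adequate for sequences of tens of codons where codon
models are themselves unstable.

### Empirical FDR

Both the E-value and the Ka/Ks thresholds are calibrated by the same
mechanism: positives are length-matched segments of translated annotated
exons, negatives are *reverse control ORFs* — stop-codon-to-ATG segments
drawn from the same non-exonic DNA with the same length distribution
(largest-remainder stratified sampling), non-overlapping with candidates
on the same strand and frame. For a threshold t, TP and FP are the
fractions of positives and negatives passing, and FDR = FP/(TP+FP)
(0 when nothing passes; NA never passes). Threshold selection scans
loosest-first and returns the first threshold with FDR at or below the
target; no isotonic smoothing is applied, matching the direct empirical
usage. The default pipeline cutoffs — E < 1e-3 and Ka/Ks < 0.1 — are the
calibrated operating points of this procedure.

### Size-distribution statistics

Pools are compared by Mann-Whitney U (rank sums, midrank ties, normal
approximation with tie-corrected variance and continuity correction) and
two-sample Kolmogorov-Smirnov (asymptotic p with effective size
\(n_1 n_2/(n_1+n_2)\)); exact enumeration is used only as a test oracle at
tiny n. Sizes are reported in codons = length_nt/3, i.e. *including* the
stop codon, so the 30-300 nt bounds read as 10-100 codons and at most
99 amino acids; this convention is applied uniformly since mixing the two
off-by-one conventions is the classic error in this literature.

## The synthetic genome pair

`generateGenomePair()` builds the study conditions end to end: two 500-kb
chromosomes; i.i.d. background at GC 0.42 (fly-like euchromatin); 40
colinear anchor genes (annotated exon/CDS, divergence 0.15 — conserved
orthologs); 3 transposon families with 10 diverged copies each in the
query (exercising the exclusion filter, whose database holds the family
consensi plus the anchor CDS); and 60 planted smORFs, uniform 30-300 nt —
50 conserved at homologous positions, 5 translocated to a different
subject chromosome (conserved but non-syntenic by construction), 5 with
no subject counterpart. Subject background evolves by a Jukes-Cantor
process at 1.0 substitutions/site — near saturation, so chance
amino-acid-level conservation of neutral sequence is rare, the premise of
the whole approach — with 2% small indels.

Planted ORFs evolve under `evolveCoding()` with omega 0.05 and a target
synonymous divergence of 0.5. Substitution counts are *conditioned*:
the number of synonymous events is the stochastic rounding of
\(K_s \cdot S\) and the nonsynonymous count of
\(\omega K_s \cdot N\), with proposals applied at random positions and
rejected if they create internal stops or touch the terminal codons.
Conditioning means each plant realizes the nominal divergence up to
rounding, so recovery experiments measure the pipeline's and estimator's
behaviour rather than the mutation-count lottery; the stochastic rounding
keeps the realized counts unbiased, and the estimator-consistency tests
confirm that mean recovered Ka/Ks tracks the generator's omega across
\(\omega \in \{0, 0.05, 0.2, 1\}\) (with the small upward ratio bias
inherent to ratio estimators at finite length).

Each planted cassette carries an in-frame stop codon immediately upstream
of its ATG, in both genomes, so the planted start is the ORF's 5'-most
qualifying start under the scanner's maximal-ORF policy — mirroring real
smORFs, whose annotated start is the 5'-most in-frame ATG after the
upstream stop.

Transcription evidence emulates embryonic tiling-array transfrags
(~200 bp, stranded in this artifact's format) and per-substage RNA-seq
contigs over six embryonic substage labels. Defaults: every plant is
covered by contigs, 95% in two or more substages, and 70% additionally by
a transfrag — the regime of deeply covered embryonic transcription for
genuinely transcribed loci; decoy contigs and transfrags at random
positions provide at most single-contig support and so never satisfy the
multiple-evidence rule on their own.

What the generator does *not* emulate: isochore/GC structure, codon-usage
bias, recombination, splicing, and genuinely transcribed-but-nonfunctional
background. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is correct and calibrated under the stated
divergence regime, not that its genome-scale counts on real data would be
reproduced.

## Numerical and convention choices

* Coordinates are 1-based closed (`GRanges`) throughout; conversion
  happens only at BED boundaries on import/export. One convention
  everywhere prevents off-by-one drift between modules.
* Alignment tracebacks break ties deterministically (diagonal, then up,
  then left); equal-scoring search hits order by lowest subject start,
  then + before -. Re-running any stage on the same inputs is
  byte-identical; every sampling function takes an explicit seed.
* The scanner drops any ORF containing N. "Non-exonic" masking uses the
  exon and CDS feature classes only; transposons are handled by the
  similarity exclusion filter instead, mirroring the two-step removal.
* One smORF per (stop, frame, strand), anchored at the 5'-most ATG that
  satisfies the length bounds; `allStarts = TRUE` reports every in-frame
  ATG variant. Reverse controls take the *nearest* next in-frame ATG
  after each stop and are excluded if they overlap a candidate on the
  same strand and frame (the in-frame pairing of stop and ATG is an
  assumption, documented here, since a stop-to-start control has no
  intrinsic frame).
* The exclusion filter's E-value cutoff (1e-3) is a documented default
  guess exposed in the configuration, as is the 50-kb synteny slack; the
  synteny test itself — hit within the min/max subject span of the two
  flanking anchors, extended by the slack, with local inversions counting
  as syntenic — is this package's own operational definition of "syntenic
  position", the simplest test that regional homology guarantees.
* Problem sizes in the shipped tests: oracle equivalence uses 1,000
  random 2-kb sequences for the scanner and 200 30-aa queries against
  100 kb for the search; estimator consistency uses 1,000 pairs of 50
  codons per omega; the end-to-end recovery run uses the default two
  500-kb chromosome configuration. These sizes give stable fractions in
  minutes on one CPU.

## Known limitations

* Karlin-Altschul parameters are treated as constants; compositionally
  extreme genomes would need re-tabulated values.
* No low-complexity masking, two-hit seeding or composition-based score
  adjustment: on repetitive real genomes the search would be noisier than
  the original tooling it mirrors.
* The conserved-ORF caller considers only the best-E-value hit per
  candidate; a conserved ORF reachable only through a secondary hit is
  missed (rare under the synthetic conditions; counted against
  sensitivity when it happens).
* Ka/Ks on very short ORFs is noisy regardless of estimator: at 20-40
  codons a true omega of 0.05 is estimated above 0.1 a few percent of the
  time. This false-negative rate is inherent to the yardstick at these
  lengths and is visible in the end-to-end recovery runs.
* Multi-exon (spliced) smORFs are out of scope by design, as is read
  mapping/assembly for the transcription evidence: only interval evidence
  is consumed.
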