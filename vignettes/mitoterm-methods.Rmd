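---
title: "Detecting mitochondrial nonstop mRNAs from 3'-end sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mitochondrial nonstop mRNAs from 3'-end sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoterm)
```

## The biological problem

Human mitochondrial DNA encodes 13 mRNAs inside two long polycistronic
transcripts. Under the tRNA punctuation model, RNase P and RNase Z cleave at
the tRNAs interleaved between genes, releasing the individual mRNAs. The
consequence for translation is unusual: 8 of the 13 mRNAs do not encode a
standard stop codon (UAA/UAG) within the CDS, and 6 of those (ND1, ND2, CO3,
ND3, ND4, CYB) end flush against a downstream tRNA. These six depend on
post-transcriptional polyadenylation of a terminal U or UA to complete the
UAA stop. The remaining two, CO1 and ND6, end in AGA and AGG — codons with no
cognate mitochondrial tRNA and no release-factor recognition.

Any failure in this chain — missed tRNA cleavage, missing poly(A), internal
truncation — produces a *nonstop mRNA*: a message on which the ribosome
reaches the 3' end with no stop codon in the A site. 3'-end deep sequencing
with a template-switching reverse transcriptase (TGIRT + R2R adapter)
captures the exact final nucleotide of each transcript, so the abundance of
every nonstop class can be measured directly. This package implements the
full computation: read trimming, exact 3'-CDS anchoring, five-way category
classification, genome-aware termination logic, summaries and 3'-position
histograms, plus the terminal-codon / −1-frameshift census used to test
whether a frameshift-termination mechanism on AGA/AGG is evolutionarily
plausible.

## The read model

A library read is modelled as

```
[ mRNA-sense templated fragment | non-templated A-tail | variable nt | adapter ]
```

where the last templated base is the RNA 3' terminus. Processing inverts
this construction:

1. **Trimming** (`trim_reads`): 3' bases below Phred 20 are removed, then
   the adapter plus its one variable 5' nucleotide; fragments shorter than
   10 nt are rejected (counted, never silently dropped). The thresholds are
   the standard `trimq = 20` / `minlen = 10` trimming parameters for this
   library chemistry.
2. **Anchoring** (`anchor_reads`): the fragment's leading 24-mer is matched
   *exactly* against each transcript's 3' context (CDS + encoded UTR + flank
   in mRNA sense). Requiring exactness replaces a general-purpose aligner:
   only the 3'-CDS context matters and fragments are short. A hit in more
   than one transcript (or twice in one) is reported `ambiguous`, never
   guessed. The anchor length is configurable; 24 nt makes random matches
   (p about 4^-24 per position) negligible even genome-wide.
3. **Maximal templated extension**: the match is extended 3'-wards as far as
   the genome explains the read. Genomic A's are therefore absorbed before a
   poly(A) tail is called — a deterministic convention that is conservative
   about tail length. When the boundary falls inside an A-run shared by
   genome and tail the split is unobservable in principle; such calls are
   flagged `junction_ambiguous` and counted. One mismatch per 20 nt of
   extension is tolerated as sequencing error, but never against an A-only
   read suffix (that would silently eat a tail boundary).

## Classification rules

Each anchored read has a signed offset (last templated base relative to the
CDS 3' end) and a tail. The category rules, in order:

| category | rule |
|---|---|
| `CDS` | offset 0, no tail |
| `CDS_POLYA` | offset 0, homopolymeric A tail (>= 1 nt) |
| `CDS_UTR(_POLYA)` | templated extension within the encoded 3'UTR |
| `CDS_TRNA` | extension >= 3 nt into a flanking tRNA (tail, if any, recorded) |
| `SHORT_EXTENSION` | 1-2 nt into the flank — below the tRNA rule, error-prone, reported separately and excluded from nonstop totals |
| `TRUNC_POLYA` | offset <= -3 with an A tail |
| `UNCLASSIFIED` | everything else, with a reason (`mixed_tail`, `truncated_no_tail`, `shallow_truncation`, `non_trna_flank`) |

Oligo- and polyadenylation are pooled (minimum tail 1 nt). Truncated reads
without a tail are counted but deliberately not interpreted: their fate is
not identifiable from 3'-end data alone.

**Termination.** A read terminates if (i) the CDS encodes a standard stop
and the read retains it (all categories except deep truncation — including
`CDS_TRNA`, since an encoded stop precedes any downstream extension); (ii)
the CDS ends in U/UA and the read is polyadenylated at the exact CDS end
(UAA completed); or (iii) the read carries flanking sequence whose in-frame
reading yields UAA/UAG within the captured extension. The junction case —
stop completed at codon index 0, i.e. with no polypeptide extension — is
what distinguishes ND1 (TRNI donates the final A of UAA) and ND2 (TRNW
donates AG of UAG) from ND3, ND4, CO3: their tRNAs complete no junction
stop. An in-frame stop deeper in the flank (CYB's TRNT at codon index 6)
still terminates, at the cost of a translated fusion peptide. Reads ending
in AGA/AGG-terminal CDSs are `arg_codon_resistant` regardless of category;
those with a captured UTR of at most 9 nt and no poly(A) are additionally
flagged `rescue_substrate` — short enough to fit the ribosomal mRNA channel
and be a candidate for ArfB-type rescue termination.

The three nonstop sources that emerge for a punctuated no-stop transcript
are exactly: correctly processed CDS lacking poly(A); CDS with >= 3 nt of
flanking tRNA (when no junction stop exists); and truncated polyadenylated
transcripts.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `q_threshold` | 20 | Phred | standard quality floor for 3' trimming |
| `min_len` | 10 | nt | shortest anchorable-in-principle fragment kept |
| `anchor_len` | 24 | nt | exact-match anchor; uniqueness on a 16.6-kb genome |
| `mismatch_per` | 20 | nt/mismatch | sequencing-error tolerance in extension |
| `trna_min` | 3 | nt | minimum tRNA extension for `CDS_TRNA` |
| `trunc_min` | 3 | nt | minimum truncation depth for `TRUNC_POLYA` |
| `polya_min` | 1 | nt | oligo- and polyadenylation pooled |
| `rescue_utr_max` | 9 | nt | UTR length fitting the mRNA channel |
| histogram window | [-30, +75] | nt | covers truncations and full tRNA flanks |

Raising `trna_min` can only move reads out of `CDS_TRNA`; raising
`rescue_utr_max` can only add rescue substrates — both monotonicities are
enforced by tests.

## The bundled reference

`human_mtdna()` loads a packaged copy of the complete human mitochondrial
genome (GenBank NC_001807.4, 16,571 nt) with a curated feature table (13
mRNAs, 22 tRNAs, 2 rRNAs) in 0-based half-open heavy-strand coordinates.
The curation is validated by the test suite rather than taken on faith: all
13 CDS start codons must be valid mitochondrial initiators, terminal codons
and remainders must reproduce the known 3' biology (CO1 AGA, ND6 AGG,
CO2/ATP8 TAG, ATP6/ND4L/ND5 TAA, six T/TA remainders), ND1/ND2 junctions
must complete stops at index 0 and CO3/ND3/ND4 must not, and CO1 must carry
its 72-nt encoded 3'UTR. ND6 is the one light-strand mRNA and exercises the
reverse-complement path.

Design choices where the annotation is genuinely open:

* **Bicistronic overlaps.** ATP8/ATP6 and ND4L/ND4 overlap on one
  transcript (and ATP6/CO3 share one base). The model keeps 13 per-gene
  units, each with its own 3' context; only duplicate or fully-contained
  mRNA annotations are rejected as errors. The overlapping downstream CDS
  simply acts as a (non-tRNA) flank.
* **Encoded UTR span.** The UTR is the intergenic gap to the next
  *same-strand* feature (light-strand tRNAs do not punctuate heavy-strand
  transcripts — that is how CO1's 72-nt UTR arises upstream of TRND),
  stored up to a 300-nt cap; read-level classification only ever probes the
  first ~75 nt.
* **ATP6/CO3 junction.** Cleaved by an unknown, non-RNase-P/Z activity; the
  model simply uses the annotated boundary.

## The synthetic library

`make_toy_genome()` builds a deterministic ~1.2-kb circular genome with five
mRNA archetypes — ND3-like (T remainder, junction-stop-free tRNA), ND1-like
(TA remainder, tRNA donating a TAG junction stop), CO2-like (encoded TAA,
5-nt UTR), CO1-like (AGA with upstream T and a 30-nt UTR) and ND6-like
(light-strand AGG) — so every classifier branch is reachable.
`simulate_reads()` draws per-read categories from a configurable mixture
(renormalised per transcript to the feasible categories), poly(A) lengths as
1 + geometric with mean 8 (the data report no tail-length distribution; a
geometric is the simplest memoryless stand-in with an oligo(A) mode), tRNA
extensions uniform on [3, 20] nt, truncations uniform on [-15, -3] nt,
fragments of 60 nt (auto-lengthened so at least anchor + 6 nt of CDS remain),
constant Q37 qualities, and optional uniform substitution errors.

Two deliberate idealisations define what round-trip tests do and do not
show. First, junction bases 3' of each toy CDS end are non-A, and tailed
truncation/UTR sites are drawn at positions whose next genomic base is not A
— so the templated/tail boundary is always observable and truth recovery can
be required to be exactly 100%. Real data contain unavoidable boundary
ambiguity; the pipeline reports it (`junction_ambiguous`) rather than
resolving it, and the ambiguous-junction toy variant
(`make_toy_genome(ambiguous_junction = TRUE)`) tests that recovered tails
shrink by at most the genomic A-run length. The human ND1 junction (TRNI
starts with A) shows the same effect with real sequence. Second, the
generator does not model PCR duplicates, GC or priming bias, quality decay,
RNA structure, or paired-end bookkeeping (reads arrive merged, in mRNA
sense). Passing tests therefore demonstrate correctness of the sorting
logic, not robustness to every library artefact.

## Numerical and degenerate-input choices

Proportions are exact ratios of integer counts (no pseudocounts); empty
summaries are zero-count rows, and an empty nonstop pool yields `NA`
proportions flagged `empty` rather than 0/0. The census excludes species
whose 3' sequence carries ambiguity codes (logged), deduplicates exact
sequences keeping first-by-input-order, and reports both raw and
deduplicated n. Because the "total abundance" of nonstop mRNAs can be
referred to either denominator, summaries emit both the per-transcript
share and the share of all anchored reads, and the nonstop-type
distribution is available per transcript and pooled.

Problem sizes in the test suite and acceptance script — grids of ~1,600
classifier cases, libraries of 10,000-20,000 reads, cohorts of 20-40
species — were chosen so every binomial comparison has 3-sigma resolution
below 2 percentage points while the whole suite runs in well under a
minute of simulation time.

## Known limitations

* Anchoring is exact-match; heavily divergent mitochondrial genomes need
  their own reference, not a tolerance increase.
* The termination calls are sequence logic, not kinetics: a read "terminates"
  if a stop codon is reachable in frame, with no model of readthrough,
  ribosome drop-off or rescue-factor competition.
* Truncated non-adenylated 3' ends are counted but not interpreted.
* The census consumes pre-extracted CDS 3' sequences; alignment, outlier
  removal and taxonomy filtering are upstream of this package.
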