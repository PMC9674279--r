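# Transcript models: one mRNA unit with its 3' context (terminal codon,
# codon remainder, encoded 3'UTR, directly flanking feature), plus the
# termination-logic primitives of the vertebrate mitochondrial genetic code.

#' Build transcript models from a genome and its features
#'
#' One model per mRNA feature. Light-strand units are reverse-complemented
#' into mRNA sense. The 3' context of each unit is taken from the next
#' feature downstream *on the same strand* in mRNA sense: any intergenic gap
#' becomes the encoded 3'UTR and the feature itself the flank (typically a
#' tRNA under the punctuation model). Partially overlapping mRNAs (bicistronic
#' units) are permitted: the overlapping downstream CDS then acts as the
#' flank with an empty UTR.
#'
#' @param genome Genome list as returned by [load_genome()].
#' @param features Feature data.frame as returned by [load_genome()].
#' @param utr_max Maximum encoded-UTR length stored per model (nt). Spans to
#'   the next same-strand feature longer than this are truncated; 300 nt by
#'   default, comfortably beyond any captured read extension.
#' @param flank_max Maximum flank sequence stored per model (nt); default 120.
#' @return Named list of transcript models. Each model is a list with fields
#'   `name`, `strand`, `cds_seq`, `terminal_codon`, `remainder` (one of "",
#'   "T", "TA", ... after the last complete codon), `encoded_utr_seq`,
#'   `flank_name`, `flank_kind`, `flank_seq`, and `anchor_ref` (the mRNA-sense
#'   concatenation CDS + UTR + flank used for read anchoring, with `cds_end`
#'   marking the CDS 3' terminus within it).
#' @export
build_transcript_models <- function(genome, features, utr_max = 300L,
                                    flank_max = 120L) {
  stopifnot(is.list(genome), nzchar(genome$sequence))
  validate_features(features, nchar(genome$sequence))
  mrna <- features[features$kind == "mRNA", , drop = FALSE]
  if (!nrow(mrna)) stop("no mRNA features to model")
  dup <- duplicated(mrna[, c("start", "end", "strand")])
  if (any(dup))
    stop("duplicate mRNA annotations: ", paste(mrna$name[dup], collapse = ", "))
  # fully-contained mRNA pairs are annotation errors; partial overlap is not
  for (i in seq_len(nrow(mrna))) for (j in seq_len(nrow(mrna))) {
    if (i != j && mrna$strand[i] == mrna$strand[j] &&
        mrna$start[j] >= mrna$start[i] && mrna$end[j] <= mrna$end[i])
      stop("mRNA annotation ", mrna$name[j], " is contained in ", mrna$name[i])
  }
  models <- lapply(seq_len(nrow(mrna)), function(i)
    one_model(genome, features, mrna[i, ], utr_max, flank_max))
  stats::setNames(models, mrna$name)
}

one_model <- function(genome, features, row, utr_max, flank_max) {
  gseq <- genome$sequence
  glen <- nchar(gseq)
  cds_seq <- slice_sense(gseq, row$start, row$end, row$strand)
  if (!nzchar(cds_seq)) stop("mRNA ", row$name, " has no sequence")
  L <- nchar(cds_seq)
  if (L < 3L) stop("mRNA ", row$name, " shorter than one codon")
  rem_len <- L %% 3L
  remainder <- if (rem_len) substr(cds_seq, L - rem_len + 1L, L) else ""
  k <- (L - rem_len) %/% 3L
  terminal_codon <- substr(cds_seq, 3L * (k - 1L) + 1L, 3L * k)

  # mRNA-sense 3' end position on the genome, and the downstream direction
  down <- downstream_feature(features, row)
  if (row$strand == "heavy") {
    cds_end <- row$end                       # 0-based pos just past the CDS
    if (is.null(down)) {
      gap_seq <- substr(gseq, cds_end + 1L, min(glen, cds_end + utr_max))
      flank <- NULL
    } else {
      gap <- max(0L, down$start - cds_end)
      gap_seq <- if (gap) substr(gseq, cds_end + 1L, cds_end + min(gap, utr_max)) else ""
      fstart <- max(down$start, cds_end)
      flank <- list(name = down$name, kind = down$kind,
                    seq = substr(gseq, fstart + 1L,
                                 min(glen, fstart + flank_max)))
    }
  } else {
    # light strand: mRNA 3' end at genomic `start`; downstream = lower coords
    cds_end <- row$start
    if (is.null(down)) {
      lo <- max(0L, cds_end - utr_max)
      gap_seq <- revcomp(substr(gseq, lo + 1L, cds_end))
      flank <- NULL
    } else {
      gap <- max(0L, cds_end - down$end)
      gap_seq <- if (gap)
        revcomp(substr(gseq, cds_end - min(gap, utr_max) + 1L, cds_end)) else ""
      fend <- min(down$end, cds_end)
      flank <- list(name = down$name, kind = down$kind,
                    seq = revcomp(substr(gseq, max(1L, fend - flank_max + 1L), fend)))
    }
  }

  flank_seq <- if (is.null(flank)) "" else flank$seq
  anchor_ref <- paste0(cds_seq, gap_seq, flank_seq)
  list(name = row$name, strand = row$strand,
       cds_seq = cds_seq, terminal_codon = terminal_codon, remainder = remainder,
       encoded_utr_seq = gap_seq,
       flank_name = if (is.null(flank)) NA_character_ else flank$name,
       flank_kind = if (is.null(flank)) NA_character_ else flank$kind,
       flank_seq = flank_seq,
       anchor_ref = anchor_ref, cds_end = nchar(cds_seq))
}

# Next feature downstream of `row` in mRNA sense on the same strand
# (the feature covering or starting at/after the CDS 3' end).
downstream_feature <- function(features, row) {
  same <- features[features$strand == row$strand &
                   !(features$start == row$start & features$end == row$end), ,
                   drop = FALSE]
  if (!nrow(same)) return(NULL)
  if (row$strand == "heavy") {
    cand <- same[same$end > row$end, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[which.min(cand$start), ]
  } else {
    cand <- same[same$start < row$start, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[which.max(cand$end), ]
  }
}

slice_sense <- function(gseq, start0, end0, strand) {
  s <- substr(gseq, start0 + 1L, end0)
  if (strand == "light") revcomp(s) else s
}

revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Classify a terminal codon under the vertebrate mitochondrial code
#'
#' TAA and TAG are standard stop codons recognised by the mitochondrial
#' release factors. AGA and AGG, found at the 3' ends of human *MT-CO1* and
#' *MT-ND6*, have no cognate mitochondrial tRNA and are not recognised by a
#' release factor; they are classed separately. Everything else is a sense
#' codon. (AGA/AGG are arginine in the standard code, hence the class name.)
#'
#' @param codon A 3-nt string over {A,C,G,T}; U is mapped to T on input.
#' @return One of `"standard_stop"`, `"mito_arg_nonstop"`, `"sense"`.
#' @examples
#' terminal_codon_class("TAA")  # standard_stop
#' terminal_codon_class("AGA")  # mito_arg_nonstop
#' @export
terminal_codon_class <- function(codon) {
  codon <- chartr("Uu", "Tt", toupper(codon))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 nt over {A,C,G,T}: got '", codon, "'")
  if (codon %in% c("TAA", "TAG")) "standard_stop"
  else if (codon %in% c("AGA", "AGG")) "mito_arg_nonstop"
  else "sense"
}

#' Does polyadenylation complete a stop codon?
#'
#' Mitochondrial CDSs ending in a partial codon T or TA gain the UAA stop by
#' post-transcriptional adenylation. An empty remainder followed by poly(A)
#' reads AAA (lysine), not a stop.
#'
#' @param remainder The trailing nucleotides after the last complete codon:
#'   "", a 1-nt, or a 2-nt DNA string.
#' @return `TRUE` iff `remainder` is `"T"` or `"TA"`.
#' @export
polya_completes_stop <- function(remainder) {
  remainder <- chartr("Uu", "Tt", toupper(remainder))
  if (nchar(remainder) > 2L)
    stop("remainder longer than 2 nt: '", remainder, "'")
  remainder %in% c("T", "TA")
}

#' Scan for an in-frame stop codon in the downstream flank
#'
#' Concatenates the CDS codon remainder with the downstream (mRNA-sense)
#' flanking sequence and reads successive codons in the CDS frame. Returns
#' the codon index of the first TAA/TAG, with index 0 meaning the stop is
#' completed at the junction by the first flank nucleotides — i.e. without
#' extending the nascent polypeptide. Returns `NA` when no stop lies within
#' the window.
#'
#' @param remainder Codon remainder ("", 1 or 2 nt).
#' @param flank_seq mRNA-sense downstream sequence (may be empty).
#' @param window Number of nucleotides of `remainder + flank_seq` to scan;
#'   default 30 for model-level scans. The classifier passes the captured
#'   flank length instead.
#' @return Integer codon index (0-based) of the first in-frame stop, or `NA`.
#' @examples
#' inframe_stop_scan("TA", "AGGGC")   # 0: TA|A -> TAA at the junction
#' inframe_stop_scan("", "CATCAT")    # NA
#' @export
inframe_stop_scan <- function(remainder, flank_seq, window = 30L) {
  seq <- chartr("Uu", "Tt", toupper(paste0(remainder, flank_seq)))
  window <- min(window + nchar(remainder), nchar(seq))
  seq <- substr(seq, 1L, window)
  n_codons <- nchar(seq) %/% 3L
  if (n_codons < 1L) return(NA_integer_)
  for (i in seq_len(n_codons)) {
    codon <- substr(seq, 3L * (i - 1L) + 1L, 3L * i)
    if (codon %in% c("TAA", "TAG")) return(i - 1L)
  }
  NA_integer_
}
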