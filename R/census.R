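# Terminal-codon and -1 ribosomal frameshift codon census over a set of
# CDS 3'-end sequences (one per species). On ...U-AGA, a one-nucleotide
# backward slip of the ribosome would place UAG in the A site; the census
# tabulates, per species, the terminal codon and the codon a -1 frameshift
# would produce, to test whether such a mechanism is conserved.

#' Remove exact-duplicate CDS 3' sequences
#'
#' @param records data.frame with columns `species` and `seq3` (mRNA-sense
#'   3'-terminal CDS sequence), e.g. from [read_cds_ends()].
#' @return The records with exact-duplicate `seq3` removed (first by input
#'   order kept); the number removed is in attribute `"n_removed"`.
#' @export
dedupe_cds_ends <- function(records) {
  keep <- !duplicated(records$seq3)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Terminal codon of a CDS 3'-end sequence
#'
#' @param seq3 mRNA-sense 3'-terminal CDS sequence (>= 3 nt). Vectorised.
#' @return The last 3 nt.
#' @export
terminal_codon <- function(seq3) {
  seq3 <- chartr("Uu", "Tt", toupper(seq3))
  if (any(nchar(seq3) < 3L)) stop("seq3 shorter than 3 nt")
  substr(seq3, nchar(seq3) - 2L, nchar(seq3))
}

#' Codon produced by a -1 ribosomal frameshift on the terminal codon
#'
#' The terminal codon shifted back one nucleotide: positions L-3..L-1 of the
#' sequence. On a human-type ...TAGA 3' end this is TAG, a standard stop.
#'
#' @param seq3 mRNA-sense 3'-terminal CDS sequence (>= 4 nt). Vectorised.
#' @return The 3-nt codon one base upstream of the terminal codon.
#' @export
minus1_codon <- function(seq3) {
  seq3 <- chartr("Uu", "Tt", toupper(seq3))
  if (any(nchar(seq3) < 4L)) stop("seq3 shorter than 4 nt")
  substr(seq3, nchar(seq3) - 3L, nchar(seq3) - 1L)
}

#' Terminal and -1 frameshift codon census over species
#'
#' @param records data.frame with columns `species`, `seq3`.
#' @param dedupe Remove exact-duplicate sequences first? Default `TRUE`.
#' @return List with:
#'   `terminal`, `minus1`: codon -> species-count tables (named integer
#'   vectors) with attributes `n_species`;
#'   `per_species`: data.frame `species`, `terminal_codon`, `minus1_codon`,
#'   `terminal_is_stop`, `minus1_is_stop`;
#'   `n_raw`, `n_used`, `n_excluded_ambiguous` bookkeeping counts.
#'   Species whose `seq3` contains ambiguity codes are excluded (logged in
#'   `excluded`).
#' @examples
#' recs <- data.frame(species = c("a", "b"), seq3 = c("CCTAGA", "CCCTAA"))
#' codon_census(recs)$minus1
#' @export
codon_census <- function(records, dedupe = TRUE) {
  stopifnot(all(c("species", "seq3") %in% names(records)))
  n_raw <- nrow(records)
  records$seq3 <- chartr("Uu", "Tt", toupper(records$seq3))
  amb <- grepl("[^ACGT]", records$seq3) | nchar(records$seq3) < 4L
  excluded <- records$species[amb]
  records <- records[!amb, , drop = FALSE]
  n_removed <- 0L
  if (dedupe) {
    records <- dedupe_cds_ends(records)
    n_removed <- attr(records, "n_removed")
  }
  n <- nrow(records)
  if (n == 0L) {
    empty <- stats::setNames(integer(0), character(0))
    attr(empty, "n_species") <- 0L
    return(list(terminal = empty, minus1 = empty,
                per_species = data.frame(species = character(),
                                         terminal_codon = character(),
                                         minus1_codon = character(),
                                         terminal_is_stop = logical(),
                                         minus1_is_stop = logical()),
                n_raw = n_raw, n_used = 0L, n_deduped = n_removed,
                n_excluded_ambiguous = length(excluded), excluded = excluded))
  }
  tc <- terminal_codon(records$seq3)
  m1 <- minus1_codon(records$seq3)
  is_stop <- function(x) x %in% c("TAA", "TAG")
  per <- data.frame(species = records$species, terminal_codon = tc,
                    minus1_codon = m1, terminal_is_stop = is_stop(tc),
                    minus1_is_stop = is_stop(m1), stringsAsFactors = FALSE)
  census_tab <- function(x) {
    tab <- table(x)
    out <- stats::setNames(as.integer(tab), names(tab))
    attr(out, "n_species") <- n
    out
  }
  list(terminal = census_tab(tc), minus1 = census_tab(m1), per_species = per,
       n_raw = n_raw, n_used = n, n_deduped = n_removed,
       n_excluded_ambiguous = length(excluded), excluded = excluded)
}

#' Read CDS 3'-end sequences from a multi-FASTA
#'
#' @param path Multi-FASTA, one record per species.
#' @param tail_len Keep only the last `tail_len` nt of each record
#'   (`Inf` keeps the whole record).
#' @return data.frame `species`, `seq3`.
#' @export
read_cds_ends <- function(path, tail_len = Inf) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  if (is.finite(tail_len))
    seqs <- substr(seqs, pmax(1L, nchar(seqs) - as.integer(tail_len) + 1L),
                   nchar(seqs))
  data.frame(species = sub("\\s.*$", "", names(set)), seq3 = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Slice the CDS 3'-end sequence from a transcript model
#'
#' Convenience for feeding annotated genomes into the census.
#'
#' @param model A transcript model.
#' @param n Number of 3'-terminal CDS nt to keep; default 30.
#' @return Character: the last `n` nt of the CDS in mRNA sense.
#' @export
cds_end_seq <- function(model, n = 30L) {
  L <- nchar(model$cds_seq)
  substr(model$cds_seq, max(1L, L - n + 1L), L)
}
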