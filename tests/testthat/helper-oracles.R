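# Shared fixtures and independent oracle implementations used across tests.

# toy genome shared by many tests (built once per run)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_genome(seed = 1L)
    cache
  }
})

human_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- human_mtdna()
    cache
  }
})

# --- Independent brute-force rule table -------------------------------------
# A literal transcription of the sorting rules, written without reference to
# the classifier's code path: decides the category from (offset, tail) plus
# the transcript facts (encoded UTR length, flank kind).
oracle_category <- function(offset, tail, utr_len, flank_is_trna,
                            trna_min = 3, trunc_min = 3, polya_min = 1) {
  n_nonA <- nchar(gsub("A", "", tail))
  tail_is_polya <- nchar(tail) >= polya_min && nchar(tail) > 0 &&
    n_nonA <= nchar(tail) %/% 20
  if (nchar(tail) > 0 && !tail_is_polya) return("UNCLASSIFIED")
  if (offset == 0) {
    if (nchar(tail) == 0) return("CDS")
    return("CDS_POLYA")
  }
  if (offset < 0) {
    if (offset <= -trunc_min && tail_is_polya) return("TRUNC_POLYA")
    return("UNCLASSIFIED")
  }
  # offset > 0: templated extension past the CDS 3' end
  if (offset <= utr_len) {
    if (tail_is_polya) return("CDS_UTR_POLYA")
    return("CDS_UTR")
  }
  into_flank <- offset - utr_len
  if (into_flank <= 2) return("SHORT_EXTENSION")
  if (into_flank >= trna_min && flank_is_trna) return("CDS_TRNA")
  "UNCLASSIFIED"
}

# Independent anchoring oracle for error-free fragments: enumerate every
# split of the fragment into (templated prefix, tail suffix) and take the
# longest templated prefix that occurs as a substring of the reference
# ending at a consistent position.
oracle_anchor <- function(fragment, ref, cds_end) {
  best <- NULL
  for (k in seq(nchar(fragment), 1)) {
    prefix <- substr(fragment, 1, k)
    hit <- gregexpr(prefix, ref, fixed = TRUE)[[1]]
    if (hit[1] != -1) {
      end_pos <- hit[1] + k - 1
      best <- list(offset = end_pos - cds_end,
                   tail = substr(fragment, k + 1, nchar(fragment)))
      break
    }
  }
  best
}

# quick constructor for a raw-read table from bare fragments (+ adapter)
raw_reads <- function(fragments, adapter = "AGATCGGAAGAGCACACGTCT",
                      var_nt = "T", qual_char = "F") {
  seqs <- paste0(fragments, var_nt, adapter)
  data.frame(id = paste0("r", seq_along(fragments)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), stringsAsFactors = FALSE)
}

# minimal single-transcript model for table-driven classifier tests
stub_model <- function(terminal_codon = "CAC", remainder = "T",
                       utr = "", flank_kind = "tRNA",
                       flank_seq = "CGCCGGCGGCGAAGGCGGCGGCG", name = "STUB") {
  # fixed non-repetitive A-free CDS body: anchors are unique and truncation
  # boundaries unambiguous
  body <- paste0("CGGCTGGGGCTCGGGCGGCTGTGGCTGGCGGTCGTGTGTTCTTCTGCCCC",
                 "TCTTGTTTTGTGCTTTCTTGTGTTGGCCTCTTCTTCCGTC")
  cds <- paste0("ATG", body, terminal_codon, remainder)
  list(name = name, strand = "heavy", cds_seq = cds,
       terminal_codon = terminal_codon, remainder = remainder,
       encoded_utr_seq = utr,
       flank_name = if (nzchar(flank_seq)) "FLK" else NA_character_,
       flank_kind = if (nzchar(flank_seq)) flank_kind else NA_character_,
       flank_seq = flank_seq,
       anchor_ref = paste0(cds, utr, flank_seq), cds_end = nchar(cds))
}
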