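# Read processing: quality/adapter trimming of 3'-end library reads and
# exact k-mer anchoring of each fragment's 3' terminus onto a transcript.
#
# Library layout (template-switching TGIRT chemistry): the read is the
# mRNA-sense fragment whose last templated base is the RNA 3' terminus,
# optionally followed by a non-templated tail, then one variable nucleotide
# (the R2R adapter's variable 5' position) and the R2R adapter itself.

DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCT"

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (gzip-transparent).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(set)),
             seq = as.character(set),
             qual = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality- and adapter-trim 3'-end library reads
#'
#' Trims low-quality 3' bases (Phred below `q_threshold`), then removes the
#' R2R adapter together with the one variable nucleotide that precedes it.
#' Reads shorter than `min_len` after trimming are rejected (counted, not
#' raised).
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (Phred+33 strings), e.g. from [read_fastq()].
#' @param adapter R2R adapter sequence searched for in the read.
#' @param q_threshold Phred threshold for 3' quality trimming; default 20.
#' @param min_len Minimum fragment length after trimming; default 10.
#' @param adapter_policy `"require"` rejects reads without the adapter;
#'   `"allow"` keeps them (with `adapter_found = FALSE`).
#' @param variable_nt Does the adapter carry one variable 5' nucleotide to be
#'   removed along with it (the R2R primer layout)? Default `TRUE`.
#' @return List with `reads` (data.frame: `id`, `fragment`, `adapter_found`)
#'   and `rejected` (data.frame: `reason`, `count`).
#' @export
trim_reads <- function(reads, adapter = DEFAULT_ADAPTER, q_threshold = 20L,
                       min_len = 10L, adapter_policy = c("require", "allow"),
                       variable_nt = TRUE) {
  adapter_policy <- match.arg(adapter_policy)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  frag <- character(n); found <- logical(n); reason <- character(n)
  has_qual <- "qual" %in% names(reads) && !all(is.na(reads$qual))
  for (i in seq_len(n)) {
    s <- toupper(reads$seq[i])
    if (has_qual && !is.na(reads$qual[i]) && nzchar(reads$qual[i])) {
      q <- utf8ToInt(reads$qual[i]) - 33L
      keep <- nchar(s)
      while (keep > 0L && q[keep] < q_threshold) keep <- keep - 1L
      s <- substr(s, 1L, keep)
    }
    hit <- regexpr(adapter, s, fixed = TRUE)[1L]
    if (hit > 0L) {
      s <- substr(s, 1L, max(0L, hit - 1L - as.integer(variable_nt)))
      found[i] <- TRUE
    } else if (adapter_policy == "require") {
      reason[i] <- "no_adapter"
      next
    }
    if (nchar(s) < min_len) { reason[i] <- "too_short"; next }
    frag[i] <- s
  }
  kept <- !nzchar(reason) & nzchar(frag)
  rej <- table(reason[nzchar(reason)])
  list(reads = data.frame(id = reads$id[kept], fragment = frag[kept],
                          adapter_found = found[kept],
                          stringsAsFactors = FALSE, row.names = NULL),
       rejected = data.frame(reason = names(rej), count = as.integer(rej),
                             stringsAsFactors = FALSE, row.names = NULL))
}

#' Anchor processed fragments onto transcript 3' ends
#'
#' Each fragment's leading `anchor_len`-mer is matched exactly against the
#' 3'-CDS context of every transcript (CDS, then encoded UTR, then flank in
#' mRNA sense). The unique hit is extended 3'-wards as far as the genome
#' explains the fragment — maximal templated extension, so genomic A's are
#' absorbed before a poly(A) tail is called — tolerating `mismatch_per` nt of
#' extension per mismatch (sequencing error). The unexplained suffix becomes
#' the non-templated tail.
#'
#' @param fragments data.frame from [trim_reads()] (`id`, `fragment`), or a
#'   character vector of fragments.
#' @param models Transcript models from [build_transcript_models()].
#' @param anchor_len Exact-match anchor length; default 24.
#' @param mismatch_per One mismatch tolerated per this many nt of templated
#'   extension beyond the anchor; default 20. `Inf` disables tolerance.
#' @return data.frame with one row per fragment: `id`, `transcript`,
#'   `offset` (signed nt of the last templated base relative to the CDS 3'
#'   end; 0 = exact CDS end, negative = inside CDS, positive = into
#'   UTR/flank), `tail` (non-templated 3' suffix), `anchored` (logical),
#'   `reason` (`"no_anchor"`, `"ambiguous"`, `"too_short"` or `""`), and
#'   `junction_ambiguous` (last templated base is A and the tail is A-only,
#'   so the templated/tail boundary within the A-run is not observable).
#' @export
anchor_reads <- function(fragments, models, anchor_len = 24L,
                         mismatch_per = 20L) {
  if (is.character(fragments))
    fragments <- data.frame(id = paste0("frag", seq_along(fragments)),
                            fragment = fragments, stringsAsFactors = FALSE)
  refs <- vapply(models, function(m) m$anchor_ref, character(1))
  cds_ends <- vapply(models, function(m) m$cds_end, integer(1))
  n <- nrow(fragments)
  out <- data.frame(id = fragments$id, transcript = NA_character_,
                    offset = NA_integer_, tail = NA_character_,
                    anchored = FALSE, reason = "",
                    junction_ambiguous = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(n)) {
    frag <- fragments$fragment[i]
    if (nchar(frag) < anchor_len) { out$reason[i] <- "too_short"; next }
    kmer <- substr(frag, 1L, anchor_len)
    hits <- lapply(refs, function(r) {
      g <- gregexpr(kmer, r, fixed = TRUE)[[1L]]
      if (g[1L] == -1L) integer(0) else as.integer(g)
    })
    nhit <- vapply(hits, length, integer(1))
    if (sum(nhit) == 0L) { out$reason[i] <- "no_anchor"; next }
    if (sum(nhit) > 1L) { out$reason[i] <- "ambiguous"; next }
    t_idx <- which(nhit == 1L)
    ref <- refs[[t_idx]]
    pos <- hits[[t_idx]][1L]              # 1-based start of anchor in ref
    ext <- extend_match(frag, ref, frag_at = anchor_len,
                        ref_at = pos + anchor_len - 1L,
                        mismatch_per = mismatch_per)
    tail <- substr(frag, ext$frag_end + 1L, nchar(frag))
    offset <- ext$ref_end - cds_ends[t_idx]
    last_base <- substr(ref, ext$ref_end, ext$ref_end)
    out$transcript[i] <- names(models)[t_idx]
    out$offset[i] <- offset
    out$tail[i] <- tail
    out$anchored[i] <- TRUE
    out$junction_ambiguous[i] <- last_base == "A" && nzchar(tail) &&
      !grepl("[^A]", tail)
  }
  out
}

# Greedy 3'-ward extension of an exact seed: walk fragment/reference in step,
# allowing one mismatch per `mismatch_per` nt of extension, and report the
# last position that matched exactly (the templated 3' end).
extend_match <- function(frag, ref, frag_at, ref_at, mismatch_per = 20L) {
  j <- frag_at; p <- ref_at          # last aligned positions (anchor end)
  last_j <- j; last_p <- p
  mism <- 0L
  nf <- nchar(frag); nr <- nchar(ref)
  while (j < nf && p < nr) {
    j <- j + 1L; p <- p + 1L
    if (substr(frag, j, j) == substr(ref, p, p)) {
      last_j <- j; last_p <- p
    } else {
      # never tolerate a mismatch against an A-only read suffix: that is a
      # poly(A) tail boundary, not a sequencing error
      rest_is_tail <- !grepl("[^A]", substr(frag, j, nf))
      ext_len <- j - frag_at
      if (!rest_is_tail && is.finite(mismatch_per) &&
          (mism + 1L) * mismatch_per <= ext_len) {
        mism <- mism + 1L              # tolerated; not a templated endpoint
      } else break
    }
  }
  list(frag_end = last_j, ref_end = last_p)
}
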