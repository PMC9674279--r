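# Five-way 3'-end category classification and translation-termination calls.
#
# Categories (closed vocabulary):
#   CDS              exact CDS 3' end, no extension, no tail
#   CDS_POLYA        exact CDS 3' end + non-templated oligo/poly(A)
#   CDS_UTR          templated extension into the encoded 3'UTR
#   CDS_UTR_POLYA    as CDS_UTR with a poly(A) tail after the UTR
#   CDS_TRNA         templated extension >= trna_min nt into a flanking tRNA
#   TRUNC_POLYA      3' end >= trunc_min nt inside the CDS, poly(A)-tailed
#   SHORT_EXTENSION  1-2 nt into the flank (below the tRNA rule; reported
#                    separately, excluded from nonstop totals)
#   UNCLASSIFIED     anything else (counted with a reason, never dropped)

#' Classification thresholds
#'
#' @param trna_min Minimum templated extension into a flanking tRNA to call
#'   CDS_TRNA (nt, default 3: "at least +3 nt").
#' @param trunc_min Minimum truncation depth for TRUNC_POLYA (nt, default 3:
#'   "missing -3 nt").
#' @param polya_min Minimum A-tail length counted as poly(A); default 1
#'   (oligo- and polyadenylation are pooled).
#' @param rescue_utr_max Maximum captured UTR length (nt) for an AGA/AGG
#'   transcript 3' end to fit the ribosomal mRNA channel and be flagged a
#'   rescue substrate; default 9.
#' @param tail_tol_per One non-A tolerated per this many tail nt when testing
#'   for a homopolymeric A tail; default 20.
#' @return A named list of thresholds.
#' @export
thresholds <- function(trna_min = 3L, trunc_min = 3L, polya_min = 1L,
                       rescue_utr_max = 9L, tail_tol_per = 20L) {
  th <- list(trna_min = as.integer(trna_min), trunc_min = as.integer(trunc_min),
             polya_min = as.integer(polya_min),
             rescue_utr_max = as.integer(rescue_utr_max),
             tail_tol_per = as.integer(tail_tol_per))
  if (any(unlist(th)[1:4] < 1L)) stop("all thresholds must be >= 1")
  th
}

is_polya <- function(tail, polya_min = 1L, tol_per = 20L) {
  n <- nchar(tail)
  if (n < polya_min || n == 0L) return(FALSE)
  non_a <- n - nchar(gsub("[^A]", "", tail))
  non_a <= n %/% tol_per
}

#' Classify one anchored read
#'
#' Applies the category rules to a single anchor (offset + tail) in the
#' context of its transcript model, then assigns the termination status.
#' Vectorised over anchors via [classify_anchors()].
#'
#' @param offset Signed nt offset of the last templated base relative to the
#'   CDS 3' end (see [anchor_reads()]).
#' @param tail Non-templated 3' suffix.
#' @param model Transcript model of the anchored transcript.
#' @param th Thresholds from [thresholds()].
#' @return One-row data.frame: `category`, `polya_len`, `flank_len`,
#'   `utr_len`, `termination`, `rescue_substrate`, `reason`.
#' @export
classify_read <- function(offset, tail, model, th = thresholds()) {
  u <- nchar(model$encoded_utr_seq)
  polya <- is_polya(tail, th$polya_min, th$tail_tol_per)
  mixed <- nzchar(tail) && !polya
  polya_len <- if (polya) nchar(tail) else 0L
  category <- "UNCLASSIFIED"; reason <- ""
  flank_len <- 0L; utr_len <- 0L

  if (mixed) {
    reason <- "mixed_tail"
  } else if (offset == 0L) {
    category <- if (polya) "CDS_POLYA" else "CDS"
  } else if (offset < 0L) {
    if (-offset >= th$trunc_min && polya) category <- "TRUNC_POLYA"
    else reason <- if (polya) "shallow_truncation" else "truncated_no_tail"
  } else {                                   # templated extension 3' of CDS
    utr_len <- min(offset, u)
    ext <- offset - u
    if (ext <= 0L) {
      category <- if (polya) "CDS_UTR_POLYA" else "CDS_UTR"
    } else if (ext < th$trna_min) {
      category <- "SHORT_EXTENSION"; flank_len <- ext
    } else if (identical(model$flank_kind, "tRNA")) {
      category <- "CDS_TRNA"; flank_len <- ext   # tail length still recorded
    } else {
      reason <- "non_trna_flank"; flank_len <- ext
    }
  }

  term <- termination_status(category, offset, polya_len, utr_len, flank_len,
                             model, th)
  data.frame(category = category, polya_len = polya_len,
             flank_len = flank_len, utr_len = utr_len,
             termination = term$termination,
             rescue_substrate = term$rescue_substrate,
             reason = reason, stringsAsFactors = FALSE)
}

# Termination decision for a classified read. Returns one of "terminates",
# "nonstop", "arg_codon_resistant", or NA for categories outside the
# termination accounting (SHORT_EXTENSION, UNCLASSIFIED).
termination_status <- function(category, offset, polya_len, utr_len, flank_len,
                               model, th = thresholds()) {
  tclass <- terminal_codon_class(model$terminal_codon)
  cds_like <- c("CDS", "CDS_POLYA", "CDS_UTR", "CDS_UTR_POLYA")
  if (tclass == "mito_arg_nonstop") {
    rescue <- polya_len == 0L && max(offset, 0L) <= th$rescue_utr_max &&
      category %in% c("CDS", "CDS_UTR", "UNCLASSIFIED")
    return(list(termination = "arg_codon_resistant", rescue_substrate = rescue))
  }
  if (category %in% c("SHORT_EXTENSION", "UNCLASSIFIED"))
    return(list(termination = NA_character_, rescue_substrate = FALSE))

  downstream <- paste0(model$encoded_utr_seq, model$flank_seq)
  captured_down <- substr(downstream, 1L, max(offset, 0L))
  term <- if (tclass == "standard_stop" &&
              category %in% c(cds_like, "CDS_TRNA")) {
    # an encoded stop precedes any 3' extension: the ribosome terminates
    # there no matter what follows (only truncation can remove it)
    "terminates"
  } else if (category == "CDS_POLYA" && polya_completes_stop(model$remainder)) {
    "terminates"
  } else if (category == "CDS_TRNA") {
    hit <- inframe_stop_scan(model$remainder, captured_down, window = offset)
    if (!is.na(hit)) "terminates" else "nonstop"
  } else if (category %in% c("CDS_UTR", "CDS_UTR_POLYA")) {
    hit <- inframe_stop_scan(model$remainder, captured_down, window = offset)
    if (!is.na(hit)) {
      "terminates"
    } else if (category == "CDS_UTR_POLYA") {
      # does the A tail complete a stop in frame after the captured UTR?
      frame_seq <- paste0(model$remainder, captured_down)
      rem2 <- substr(frame_seq, nchar(frame_seq) - (nchar(frame_seq) %% 3L) + 1L,
                     nchar(frame_seq))
      if (polya_completes_stop(rem2)) "terminates" else "nonstop"
    } else "nonstop"
  } else if (category == "TRUNC_POLYA") {
    "nonstop"
  } else if (category == "CDS") {
    "nonstop"
  } else if (category == "CDS_POLYA") {
    "nonstop"                           # no encoded stop, AAA is lysine
  } else NA_character_
  list(termination = term, rescue_substrate = FALSE)
}

#' Classify a table of anchored reads
#'
#' @param anchors data.frame from [anchor_reads()].
#' @param models Transcript models from [build_transcript_models()].
#' @param th Thresholds from [thresholds()].
#' @return data.frame of read calls: `read_id`, `transcript`, `category`,
#'   `offset`, `polya_len`, `flank_len`, `termination`, `rescue_substrate`,
#'   `junction_ambiguous`, `reason`. Unanchored reads are dropped (their
#'   reasons live in the anchor table).
#' @export
classify_anchors <- function(anchors, models, th = thresholds()) {
  anc <- anchors[anchors$anchored, , drop = FALSE]
  if (!nrow(anc))
    return(data.frame(read_id = character(), transcript = character(),
                      category = character(), offset = integer(),
                      polya_len = integer(), flank_len = integer(),
                      termination = character(), rescue_substrate = logical(),
                      junction_ambiguous = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  n <- nrow(anc)
  category <- character(n); polya_len <- integer(n); flank_len <- integer(n)
  termination <- character(n); rescue <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    m <- models[[anc$transcript[i]]]
    cl <- classify_read(anc$offset[i], anc$tail[i], m, th)
    category[i] <- cl$category; polya_len[i] <- cl$polya_len
    flank_len[i] <- cl$flank_len; termination[i] <- cl$termination
    rescue[i] <- cl$rescue_substrate; reason[i] <- cl$reason
  }
  data.frame(read_id = anc$id, transcript = anc$transcript,
             category = category, offset = anc$offset,
             polya_len = polya_len, flank_len = flank_len,
             termination = termination, rescue_substrate = rescue,
             junction_ambiguous = anc$junction_ambiguous, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full pipeline on raw reads
#'
#' Convenience wrapper: [trim_reads()] then [anchor_reads()] then
#' [classify_anchors()].
#'
#' @param reads Raw read data.frame (`id`, `seq`, optionally `qual`).
#' @param models Transcript models.
#' @param th Thresholds from [thresholds()].
#' @param ... Passed to [trim_reads()] and [anchor_reads()]
#'   (`adapter`, `q_threshold`, `min_len`, `adapter_policy`, `anchor_len`,
#'   `mismatch_per`).
#' @return List: `calls` (read calls), `anchors`, `rejected`, and `counts`
#'   (named totals: input, trimmed, anchored, classified).
#' @export
classify_library <- function(reads, models, th = thresholds(), ...) {
  dots <- list(...)
  trim_args <- dots[names(dots) %in% c("adapter", "q_threshold", "min_len",
                                       "adapter_policy", "variable_nt")]
  anchor_args <- dots[names(dots) %in% c("anchor_len", "mismatch_per")]
  tr <- do.call(trim_reads, c(list(reads = reads), trim_args))
  anc <- do.call(anchor_reads, c(list(fragments = tr$reads, models = models),
                                 anchor_args))
  calls <- classify_anchors(anc, models, th)
  list(calls = calls, anchors = anc, rejected = tr$rejected,
       counts = c(input = nrow(reads), trimmed = nrow(tr$reads),
                  anchored = sum(anc$anchored), classified = nrow(calls)))
}
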