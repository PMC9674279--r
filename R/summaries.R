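# Aggregation of read calls: per-transcript category counts/proportions,
# nonstop totals, nonstop-type distributions, and 3'-position histograms.

#' Per-transcript category summaries and nonstop totals
#'
#' Counts and proportions per 3'-end category for every transcript in
#' `models`, plus nonstop totals. Because the field's "total abundance" axis
#' is reported in arbitrary units, the nonstop total is emitted two ways:
#' as a share of the transcript's own anchored reads
#' (`nonstop_proportion`) and as a share of all anchored reads in the
#' library (`nonstop_share_overall`). A pooled row (`transcript =
#' "PUNCTUATED_POOL"`) aggregates the tRNA-punctuated transcripts — those
#' whose model lacks an encoded standard stop and has a tRNA directly at the
#' 3' end (in the human annotation: ND1, ND2, CO3, ND3, ND4, CYB).
#'
#' @param calls Read calls from [classify_anchors()].
#' @param models Transcript models (defines the rows; transcripts with no
#'   reads get zero-count summaries).
#' @return data.frame with one row per transcript (+ the pooled row):
#'   `transcript`, `n_reads`, one `n_<CATEGORY>` and `p_<CATEGORY>` column
#'   per category, `nonstop_count`, `nonstop_proportion`,
#'   `nonstop_share_overall`.
#' @export
summarize_categories <- function(calls, models) {
  total_all <- nrow(calls)
  tr_names <- names(models)
  punct <- vapply(models, is_punctuated, logical(1))
  groups <- c(as.list(stats::setNames(tr_names, tr_names)),
              list(PUNCTUATED_POOL = tr_names[punct]))
  rows <- lapply(names(groups), function(g) {
    sub <- calls[calls$transcript %in% groups[[g]], , drop = FALSE]
    n <- nrow(sub)
    cnt <- vapply(CATEGORIES, function(cat) sum(sub$category == cat), integer(1))
    prop <- if (n > 0L) cnt / n else stats::setNames(rep(0, length(cnt)),
                                                     names(cnt))
    ns <- sum(sub$termination == "nonstop", na.rm = TRUE)
    df <- data.frame(transcript = g, n_reads = n, stringsAsFactors = FALSE)
    for (cat in CATEGORIES) df[[paste0("n_", cat)]] <- cnt[[cat]]
    for (cat in CATEGORIES) df[[paste0("p_", cat)]] <- unname(prop[[cat]])
    df$nonstop_count <- ns
    df$nonstop_proportion <- if (n > 0L) ns / n else 0
    df$nonstop_share_overall <- if (total_all > 0L) ns / total_all else 0
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# A transcript is tRNA-punctuated when its CDS encodes no standard stop and a
# tRNA flanks the 3' end directly (no encoded UTR).
is_punctuated <- function(model) {
  terminal_codon_class(model$terminal_codon) != "standard_stop" &&
    identical(model$flank_kind, "tRNA") &&
    nchar(model$encoded_utr_seq) == 0L
}

#' 3'-position frequency histogram of non-polyadenylated reads
#'
#' Counts the mapped 3'-nt offsets (last templated base relative to the CDS
#' 3' end) over anchored reads without a poly(A) tail, including
#' SHORT_EXTENSION and UNCLASSIFIED anchored reads.
#'
#' @param calls Read calls from [classify_anchors()].
#' @param transcript Transcript name to histogram.
#' @param window Integer range of offsets kept; default `c(-30, 75)`.
#' @return List with `transcript`, `counts` (named integer vector, names =
#'   offsets as characters, one entry per offset in the window with nonzero
#'   count), and `total`.
#' @export
histogram_3prime <- function(calls, transcript, window = c(-30L, 75L)) {
  sub <- calls[calls$transcript == transcript & calls$polya_len == 0L, ,
               drop = FALSE]
  sub <- sub[sub$offset >= window[1L] & sub$offset <= window[2L], , drop = FALSE]
  tab <- table(sub$offset)
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(transcript = transcript, counts = counts, total = sum(counts),
       window = window)
}

#' Distribution of nonstop mRNA types
#'
#' Among reads with termination `"nonstop"`, the proportions of the three
#' nonstop sources: correctly processed CDS lacking poly(A)
#' (`CDS_no_polyA`), CDS with flanking tRNA sequence (`CDS_TRNA`), and
#' truncated polyadenylated transcripts (`TRUNC_POLYA`). For transcripts
#' whose flanking tRNA completes a junction in-frame stop (ND1/ND2-type) the
#' CDS_TRNA class contributes zero by construction.
#'
#' @param calls Read calls from [classify_anchors()].
#' @param transcripts Optional character vector restricting the pool;
#'   default all.
#' @return List with `n_nonstop`, `counts` and `proportions` (both named by
#'   `c("CDS_no_polyA", "CDS_TRNA", "TRUNC_POLYA")`), and `empty` (`TRUE`
#'   when no nonstop reads exist, in which case proportions are `NA`).
#' @export
nonstop_type_distribution <- function(calls, transcripts = NULL) {
  sub <- calls[!is.na(calls$termination) & calls$termination == "nonstop", ,
               drop = FALSE]
  if (!is.null(transcripts))
    sub <- sub[sub$transcript %in% transcripts, , drop = FALSE]
  n <- nrow(sub)
  cnt <- c(CDS_no_polyA = sum(sub$category == "CDS"),
           CDS_TRNA = sum(sub$category == "CDS_TRNA"),
           TRUNC_POLYA = sum(sub$category == "TRUNC_POLYA"))
  prop <- if (n > 0L) cnt / n else stats::setNames(rep(NA_real_, 3L), names(cnt))
  list(n_nonstop = n, counts = cnt, proportions = prop, empty = n == 0L)
}

#' Write read calls to TSV with a provenance header
#'
#' @param calls Read calls from [classify_anchors()].
#' @param path Output file.
#' @param th Thresholds echoed in header comments.
#' @export
write_calls_tsv <- function(calls, path, th = thresholds()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitoterm read calls; thresholds: %s",
                     paste(names(th), unlist(th), sep = "=", collapse = " ")),
             con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
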