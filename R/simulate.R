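# Synthetic data: a deterministic toy mitochondrial genome exercising every
# 3'-end archetype, and a ground-truth-labelled simulator of template-
# switching 3'-end library reads.

#' Simulation configuration
#'
#' Defaults describe a clean template-switching 3'-end library: every read is
#' an mRNA-sense fragment ending at the RNA 3' terminus, followed by an
#' optional non-templated A tail, one random variable nucleotide (the R2R
#' adapter's variable 5' position) and the adapter.
#'
#' @param n_reads Number of reads.
#' @param mixture Named numeric vector of category proportions over
#'   `c("CDS", "CDS_POLYA", "CDS_UTR", "CDS_UTR_POLYA", "CDS_TRNA",
#'   "TRUNC_POLYA", "SHORT_EXTENSION")`; must sum to 1. Categories
#'   infeasible for a transcript (e.g. CDS_UTR on a UTR-less unit) are
#'   renormalised away per transcript.
#' @param transcripts Transcript names to draw from (default: all models),
#'   with equal weight.
#' @param polya_mean Mean A-tail length; tails are 1 + geometric so the
#'   minimum is 1 nt (oligoadenylation) with mean `polya_mean` (default 8).
#' @param flank_range Range of templated extension into the flank for
#'   CDS_TRNA reads; default `c(3, 20)`.
#' @param trunc_range Range (negative offsets) for TRUNC_POLYA; default
#'   `c(-15, -3)`.
#' @param fragment_len Templated fragment length (nt) measured to the
#'   templated 3' end; reads with large positive offsets are lengthened so
#'   at least `anchor_len + 6` CDS nt remain for anchoring. Default 60.
#' @param error_rate Per-base substitution probability; default 0.
#' @param adapter Adapter sequence appended 3' of the variable nucleotide.
#' @param variable_nt Emit the one variable nucleotide before the adapter?
#'   Default `TRUE`.
#' @param anchor_len Anchor length assumed when padding fragments; default 24.
#' @param seed Integer seed; every simulation is reproducible given the
#'   config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 1000L,
                       mixture = c(CDS = 0.3, CDS_POLYA = 0.4, CDS_TRNA = 0.1,
                                   TRUNC_POLYA = 0.1, CDS_UTR = 0.1),
                       transcripts = NULL,
                       polya_mean = 8, flank_range = c(3L, 20L),
                       trunc_range = c(-15L, -3L), fragment_len = 60L,
                       error_rate = 0, adapter = DEFAULT_ADAPTER,
                       variable_nt = TRUE, anchor_len = 24L, seed = 1L) {
  allowed <- setdiff(CATEGORIES, c("UNCLASSIFIED"))
  if (!all(names(mixture) %in% allowed))
    stop("unknown mixture categories: ",
         paste(setdiff(names(mixture), allowed), collapse = ", "))
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(list(n_reads = as.integer(n_reads), mixture = mixture,
                 transcripts = transcripts, polya_mean = polya_mean,
                 flank_range = as.integer(flank_range),
                 trunc_range = as.integer(trunc_range),
                 fragment_len = as.integer(fragment_len),
                 error_rate = error_rate, adapter = adapter,
                 variable_nt = isTRUE(variable_nt),
                 anchor_len = as.integer(anchor_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Deterministic toy mitochondrial genome
#'
#' A small circular genome (~1.5 kb) whose five mRNA units cover the 3'-end
#' archetypes of the human mitochondrial transcriptome:
#'
#' * `ND3L`: no encoded stop, remainder "T", tRNA directly 3'; the tRNA does
#'   *not* complete a junction stop.
#' * `ND1L`: no encoded stop, remainder "TA", tRNA directly 3' whose first
#'   base (G) completes the TAG junction stop at codon index 0.
#' * `CO2L`: encoded TAA stop, short (5 nt) encoded UTR, then a tRNA.
#' * `CO1L`: AGA terminal codon (release-factor resistant) with upstream T
#'   (so a -1 frameshift would read TAG), a 30-nt UTR, then a tRNA.
#' * `ND6L`: light-strand unit, AGG terminal codon with upstream T, 40-nt
#'   UTR, then a light-strand tRNA.
#'
#' Junction bases are chosen so the genomic base 3' of each CDS end is not A
#' (unambiguous poly(A) tails), except with `ambiguous_junction = TRUE`,
#' which starts the ND3L tRNA with "AA" to exercise the junction-ambiguity
#' accounting.
#'
#' @param seed Integer seed for the random filler sequence; same seed, same
#'   genome.
#' @param ambiguous_junction Build the ambiguous-junction variant?
#' @return List with `genome`, `features`, `models` (as [load_genome()] plus
#'   models).
#' @export
make_toy_genome <- function(seed = 1L, ambiguous_junction = FALSE) {
  rng <- local_rng(seed)
  rand_dna <- function(n, avoid_stops = TRUE) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                        prob = c(0.22, 0.28, 0.28, 0.22)), collapse = "")
      if (!avoid_stops) return(s)
      # keep filler free of in-frame stops when read as codons from base 1
      codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
      if (!any(codons %in% c("TAA", "TAG"))) return(s)
    }
  }
  # CDS bodies: 40 complete codons ending in a chosen terminal codon,
  # plus the remainder.
  body <- function(terminal, remainder = "") {
    paste0("ATG", rand_dna(39L * 3L - 3L), terminal, remainder)
  }
  trna <- function(first) paste0(first, rand_dna(68L, avoid_stops = FALSE))

  nd3l_cds <- body("CAC", "T")                 # no stop; T remainder
  nd3l_trna <- trna(if (ambiguous_junction) "AA" else "CG") # T+CG no stop
  nd1l_cds <- body("ACC", "TA")                # no stop; TA remainder
  nd1l_trna <- trna("G")                       # TA+G = TAG junction stop
  co2l_cds <- body("TAA")                      # encoded stop
  co2l_utr <- "CCTGC"                          # short UTR (5 nt)
  co2l_trna <- trna("C")
  co1l_cds <- body("AGA")                      # arg-terminal; body ends T-AGA
  co1l_cds <- paste0(substr(co1l_cds, 1L, nchar(co1l_cds) - 4L), "TAGA")
  co1l_utr <- paste0("C", rand_dna(29L, avoid_stops = FALSE))  # 30-nt UTR
  co1l_trna <- trna("G")
  nd6l_cds <- body("AGG")
  nd6l_cds <- paste0(substr(nd6l_cds, 1L, nchar(nd6l_cds) - 4L), "TAGG")
  nd6l_utr <- paste0("C", rand_dna(39L, avoid_stops = FALSE))  # 40-nt UTR
  nd6l_trna <- trna("C")
  spacer <- function(n) rand_dna(n, avoid_stops = FALSE)

  # assemble heavy-strand sequence; the ND6L block is reverse-complemented
  # (CDS is downstream-to-upstream on the heavy strand)
  blocks <- list(
    list(seq = spacer(30L)),
    list(name = "ND3L", kind = "mRNA", strand = "heavy", seq = nd3l_cds),
    list(name = "TRN3", kind = "tRNA", strand = "heavy", seq = nd3l_trna),
    list(seq = spacer(20L)),
    list(name = "ND1L", kind = "mRNA", strand = "heavy", seq = nd1l_cds),
    list(name = "TRN1", kind = "tRNA", strand = "heavy", seq = nd1l_trna),
    list(seq = spacer(20L)),
    list(name = "CO2L", kind = "mRNA", strand = "heavy", seq = co2l_cds),
    list(seq = co2l_utr),
    list(name = "TRN2", kind = "tRNA", strand = "heavy", seq = co2l_trna),
    list(seq = spacer(20L)),
    list(name = "CO1L", kind = "mRNA", strand = "heavy", seq = co1l_cds),
    list(seq = co1l_utr),
    list(name = "TRN4", kind = "tRNA", strand = "heavy", seq = co1l_trna),
    list(seq = spacer(20L)),
    # light-strand block in mRNA-sense order tRNA / UTR / CDS so that the
    # CDS's mRNA 3' end points at lower genome coordinates
    list(name = "TRN6", kind = "tRNA", strand = "light",
         seq = revcomp(nd6l_trna)),
    list(seq = revcomp(nd6l_utr)),
    list(name = "ND6L", kind = "mRNA", strand = "light",
         seq = revcomp(nd6l_cds)),
    list(seq = spacer(30L)))

  seqs <- vapply(blocks, `[[`, character(1), "seq")
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs)
  named <- !vapply(blocks, function(b) is.null(b$name), logical(1))
  features <- data.frame(
    name = vapply(blocks[named], `[[`, character(1), "name"),
    kind = vapply(blocks[named], `[[`, character(1), "kind"),
    strand = vapply(blocks[named], `[[`, character(1), "strand"),
    start = starts[named], end = ends[named], stringsAsFactors = FALSE)
  genome <- list(id = sprintf("toy_mito_seed%d", seed),
                 sequence = paste(seqs, collapse = ""), circular = TRUE)
  models <- build_transcript_models(genome, features)
  list(genome = genome, features = features, models = models)
}

# Seed the RNG for a simulation (simulations own the RNG stream; callers
# wanting isolation can wrap in withr::with_seed).
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Simulate ground-truth-labelled 3'-end library reads
#'
#' Each read is built from its transcript's anchoring reference (CDS + UTR +
#' flank in mRNA sense): a templated fragment ending at the drawn 3' offset,
#' a category-appropriate A tail, one random variable nucleotide and the
#' adapter, with substitution errors applied at `error_rate`. The generating
#' truth is recorded per read.
#'
#' @param config A [sim_config()].
#' @param models Transcript models (e.g. from [make_toy_genome()]).
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `id`, `transcript`, `category`, `offset`, `polya_len`,
#'   `flank_len`).
#' @export
simulate_reads <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  local_rng(config$seed)
  trs <- config$transcripts %||% names(models)
  n <- config$n_reads
  ids <- sprintf("read%06d", seq_len(n))
  seqs <- character(n); cats <- character(n); trn <- character(n)
  offs <- integer(n); pal <- integer(n); fln <- integer(n)
  for (i in seq_len(n)) {
    tr <- if (length(trs) == 1L) trs else sample(trs, 1L)
    m <- models[[tr]]
    mix <- feasible_mixture(config$mixture, m, config)
    cat <- sample(names(mix), 1L, prob = mix)
    draw <- draw_offset(cat, m, config)
    tmpl_len <- max(config$fragment_len,
                    draw$offset + config$anchor_len + 6L)
    end_in_ref <- m$cds_end + draw$offset
    start_in_ref <- max(1L, end_in_ref - tmpl_len + 1L)
    fragment <- substr(m$anchor_ref, start_in_ref, end_in_ref)
    tail <- strrep("A", draw$polya_len)
    var_nt <- if (config$variable_nt) sample(c("A", "C", "G", "T"), 1L) else ""
    read <- paste0(fragment, tail, var_nt, config$adapter)
    if (config$error_rate > 0) read <- mutate_seq(read, config$error_rate)
    seqs[i] <- read; cats[i] <- cat; trn[i] <- tr
    offs[i] <- draw$offset; pal[i] <- draw$polya_len; fln[i] <- draw$flank_len
  }
  list(reads = data.frame(id = ids, seq = seqs,
                          qual = strrep("F", nchar(seqs)),  # Phred 37
                          stringsAsFactors = FALSE),
       truth = data.frame(id = ids, transcript = trn, category = cats,
                          offset = offs, polya_len = pal, flank_len = fln,
                          stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restrict the mixture to categories this transcript can generate
feasible_mixture <- function(mixture, model, config) {
  u <- nchar(model$encoded_utr_seq)
  has_trna <- identical(model$flank_kind, "tRNA")
  ok <- vapply(names(mixture), function(cat) switch(cat,
    CDS = TRUE, CDS_POLYA = TRUE,
    CDS_UTR = u >= 1L, CDS_UTR_POLYA = u >= 1L,
    CDS_TRNA = has_trna && nchar(model$flank_seq) >= config$flank_range[1L],
    TRUNC_POLYA = nchar(model$cds_seq) + config$trunc_range[1L] >
      config$anchor_len,
    SHORT_EXTENSION = nchar(model$flank_seq) >= 2L,
    FALSE), logical(1))
  mix <- mixture[ok]
  if (!length(mix)) stop("no feasible category for transcript ", model$name)
  mix / sum(mix)
}

draw_offset <- function(cat, model, config) {
  u <- nchar(model$encoded_utr_seq)
  polya_len <- 0L; flank_len <- 0L; offset <- 0L
  rpolya <- function() 1L + stats::rgeom(1L, prob = 1 / config$polya_mean)
  runi <- function(lo, hi) if (lo >= hi) lo else sample(seq.int(lo, hi), 1L)
  # Offsets for poly(A)-tailed reads are drawn at positions where the next
  # templated base is not A, so the templated/tail boundary is observable
  # (the CDS-end junctions are unambiguous by toy-genome construction; this
  # extends the same property to internal truncation and UTR sites).
  runi_nonA <- function(lo, hi) {
    cand <- seq.int(lo, hi)
    nxt <- substring(model$anchor_ref, model$cds_end + cand + 1L,
                     model$cds_end + cand + 1L)
    cand <- cand[nxt != "A" & nzchar(nxt)]
    if (!length(cand)) stop("no unambiguous offset in [", lo, ",", hi,
                            "] for ", model$name)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  switch(cat,
    CDS = NULL,
    CDS_POLYA = { polya_len <- rpolya() },
    CDS_UTR = { offset <- runi(1L, u) },
    CDS_UTR_POLYA = { offset <- runi_nonA(1L, u); polya_len <- rpolya() },
    CDS_TRNA = {
      flank_len <- runi(config$flank_range[1L],
                        min(config$flank_range[2L], nchar(model$flank_seq)))
      offset <- u + flank_len
    },
    TRUNC_POLYA = {
      offset <- runi_nonA(config$trunc_range[1L], config$trunc_range[2L])
      polya_len <- rpolya()
    },
    SHORT_EXTENSION = { flank_len <- runi(1L, 2L); offset <- u + flank_len },
    stop("cannot draw offsets for category ", cat))
  list(offset = offset, polya_len = polya_len, flank_len = flank_len)
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (j in hit) chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
  paste(chars, collapse = "")
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame `id`, `seq`, `qual` from [simulate_reads()].
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
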