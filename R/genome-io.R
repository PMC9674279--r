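# Genome and feature input: FASTA / GenBank flat file genomes, BED / GFF3 /
# TSV feature tables. Internally coordinates are 0-based half-open on the
# heavy-strand reference; strand is "heavy" or "light".

FEATURE_KINDS <- c("mRNA", "tRNA", "rRNA")

#' Load a mitochondrial genome and its gene features
#'
#' Reads a (circular) mitochondrial genome from FASTA or a GenBank flat file,
#' plus a gene feature table from BED, GFF3 or a plain TSV. When the genome
#' file is a GenBank record carrying a feature table, `feature_file` may be
#' omitted.
#'
#' @param genome_file Path to a FASTA or GenBank flat file.
#' @param feature_file Path to a BED (0-based half-open; optional 7th column
#'   giving the feature kind), GFF3 (1-based, converted on input), or TSV file
#'   with columns `name`, `kind`, `strand`, `start`, `end`. `NULL` when the
#'   genome file is a GenBank record with its own feature table.
#' @param circular Is the genome circular? Default `TRUE`.
#' @return A list with elements `genome` (list: `id`, `sequence`, `circular`)
#'   and `features` (data.frame: `name`, `kind`, `strand`, `start`, `end`,
#'   0-based half-open, sorted by `start`). Light-strand features are kept in
#'   heavy-strand coordinates with `strand = "light"`.
#' @examples
#' path <- system.file("extdata", "human_mtDNA_NC_001807.fasta",
#'                     package = "mitoterm")
#' feat <- system.file("extdata", "human_mtDNA_features.tsv",
#'                     package = "mitoterm")
#' ref <- load_genome(path, feat)
#' nrow(subset(ref$features, kind == "mRNA"))  # 13
#' @export
load_genome <- function(genome_file, feature_file = NULL, circular = TRUE) {
  stopifnot(is.character(genome_file), length(genome_file) == 1L)
  if (!file.exists(genome_file)) stop("genome file not found: ", genome_file)
  first <- readLines(genome_file, n = 1L)
  if (grepl("^LOCUS", first)) {
    gb <- read_genbank(genome_file)
    genome <- gb$genome
    features <- if (is.null(feature_file)) gb$features else NULL
  } else if (grepl("^>", first)) {
    genome <- read_genome_fasta(genome_file)
    features <- NULL
  } else {
    stop("malformed genome file (line 1): expected FASTA '>' or GenBank LOCUS")
  }
  genome$circular <- circular
  if (!is.null(feature_file)) features <- read_features(feature_file)
  if (is.null(features)) stop("no feature table: supply 'feature_file' or a GenBank genome")
  validate_features(features, nchar(genome$sequence))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  list(genome = genome, features = features)
}

read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("malformed FASTA: no sequences in ", path)
  if (length(set) > 1L)
    warning("multiple FASTA records; using the first: ", names(set)[1L])
  seq <- toupper(as.character(set[[1L]]))
  id <- sub("\\s.*$", "", names(set)[1L])
  check_dna(seq, what = paste0("genome ", id))
  list(id = id, sequence = seq, circular = TRUE)
}

# Minimal GenBank flat-file parser: LOCUS / FEATURES / ORIGIN sections, with
# CDS, tRNA and rRNA features and simple `a..b` / `complement(a..b)` locations.
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines)
  if (length(locus) != 1L)
    stop("malformed GenBank file: expected one LOCUS line, found ", length(locus))
  acc <- strsplit(trimws(sub("^LOCUS", "", lines[locus])), "\\s+")[[1L]][1L]

  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) != 1L) stop("malformed GenBank file: missing ORIGIN (line ",
                                 length(lines), ")")
  oend <- grep("^//", lines)
  oend <- oend[oend > ostart][1L]
  if (is.na(oend)) oend <- length(lines) + 1L
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[(ostart + 1L):(oend - 1L)], collapse = "")))
  check_dna(seq, what = paste0("GenBank record ", acc))

  fstart <- grep("^FEATURES", lines)
  features <- NULL
  if (length(fstart) == 1L) {
    block <- lines[(fstart + 1L):(ostart - 1L)]
    features <- parse_genbank_features(block)
  }
  list(genome = list(id = acc, sequence = seq, circular = TRUE), features = features)
}

parse_genbank_features <- function(block) {
  # Feature lines start at column 6; qualifiers are indented further.
  is_key <- grepl("^ {5}\\S", block)
  keys <- which(is_key)
  out <- list()
  for (i in seq_along(keys)) {
    ln <- block[keys[i]]
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- parts[1L]
    kind <- switch(key, CDS = "mRNA", tRNA = "tRNA", rRNA = "rRNA", NULL)
    if (is.null(kind)) next
    loc <- parts[2L]
    # location may continue on the next line(s); keep it simple: single span
    strand <- if (grepl("complement", loc)) "light" else "heavy"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) != 2L)
      stop("unsupported GenBank location '", loc, "' (feature line ", keys[i], ")")
    start1 <- as.integer(nums[1L]); end1 <- as.integer(nums[2L])
    # qualifiers up to next key
    qend <- if (i < length(keys)) keys[i + 1L] - 1L else length(block)
    quals <- block[(keys[i] + 1L):qend]
    gene <- qual_value(quals, "gene")
    if (is.na(gene)) gene <- qual_value(quals, "product")
    if (is.na(gene)) gene <- paste0(key, "_", start1)
    out[[length(out) + 1L]] <- data.frame(
      name = gene, kind = kind, strand = strand,
      start = start1 - 1L, end = end1, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

qual_value <- function(quals, key) {
  hit <- grep(paste0('^\\s*/', key, '='), quals, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^\\s*/[a-z_]+="?|"?\\s*$', "", hit[1L])
}

read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (!length(first)) stop("malformed feature file: ", path, " is empty")
  if (grepl("^##gff-version", readLines(path, n = 1L)) ||
      grepl("\t[^\t]*\t[^\t]*\t[0-9]+\t[0-9]+\t[^\t]*\t[+-.]\t", first[1L])) {
    return(read_features_gff3(path))
  }
  fields <- strsplit(first[1L], "\t")[[1L]]
  if (identical(fields[1:5], c("name", "kind", "strand", "start", "end")) ||
      grepl("^name\t", first[1L])) {
    return(read_features_tsv(path))
  }
  read_features_bed(path)
}

read_features_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("name", "kind", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("feature TSV must have columns: ", paste(need, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df[, need]
}

# BED: chrom start end name [score] [strand] [kind]; 0-based half-open.
read_features_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("malformed BED (", path, "): need at least 4 columns (line 1)")
  strand <- if (ncol(df) >= 6L) ifelse(df[[6L]] == "-", "light", "heavy") else "heavy"
  kind <- if (ncol(df) >= 7L) df[[7L]] else "mRNA"
  data.frame(name = df[[4L]], kind = kind, strand = strand,
             start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
             stringsAsFactors = FALSE)
}

# GFF3 via rtracklayer (1-based, converted to 0-based half-open here).
read_features_gff3 <- function(path) {
  df <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  type <- as.character(df$type)
  kind <- ifelse(type %in% c("CDS", "mRNA", "gene"), "mRNA",
          ifelse(type == "tRNA", "tRNA",
          ifelse(type == "rRNA", "rRNA", NA_character_)))
  keep <- !is.na(kind)
  df <- df[keep, , drop = FALSE]; kind <- kind[keep]
  nm <- if (!is.null(df$Name)) as.character(df$Name) else
        if (!is.null(df$ID)) as.character(df$ID) else
        paste0(kind, "_", df$start)
  data.frame(name = nm, kind = kind,
             strand = ifelse(as.character(df$strand) == "-", "light", "heavy"),
             start = as.integer(df$start) - 1L,
             end = as.integer(df$end), stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_len) {
  need <- c("name", "kind", "strand", "start", "end")
  if (!all(need %in% names(features)))
    stop("feature table lacks columns: ",
         paste(setdiff(need, names(features)), collapse = ", "))
  bad <- !features$kind %in% FEATURE_KINDS
  if (any(bad))
    stop("unknown feature kind(s): ", paste(unique(features$kind[bad]), collapse = ", "))
  bad <- !features$strand %in% c("heavy", "light")
  if (any(bad))
    stop("feature strand must be 'heavy' or 'light' (got: ",
         paste(unique(features$strand[bad]), collapse = ", "), ")")
  oob <- features$start < 0L | features$end > genome_len | features$start >= features$end
  if (any(oob))
    stop("feature(s) outside genome bounds [0, ", genome_len, "): ",
         paste(features$name[oob], collapse = ", "))
  invisible(features)
}

check_dna <- function(seq, what = "sequence") {
  if (!nzchar(seq)) stop(what, " is empty")
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

#' The bundled annotated human mitochondrial genome
#'
#' Loads the packaged copy of the human mitochondrial genome (GenBank
#' NC_001807.4, 16,571 nt) together with its curated gene feature table
#' (13 protein-coding mRNA units, 22 tRNAs, 2 rRNAs), and builds the
#' transcript models.
#'
#' @param models Also build and return transcript models? Default `TRUE`.
#' @return A list with `genome`, `features` and (when `models = TRUE`)
#'   `models` (see [build_transcript_models()]).
#' @examples
#' hs <- human_mtdna()
#' hs$models[["CO1"]]$terminal_codon  # "AGA"
#' @export
human_mtdna <- function(models = TRUE) {
  ref <- load_genome(
    system.file("extdata", "human_mtDNA_NC_001807.fasta", package = "mitoterm"),
    system.file("extdata", "human_mtDNA_features.tsv", package = "mitoterm"))
  if (models) ref$models <- build_transcript_models(ref$genome, ref$features)
  ref
}
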