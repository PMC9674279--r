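# Genome/feature loading and the termination-logic primitives.

write_toy_fasta_bed <- function(dir, genome, features) {
  fa <- file.path(dir, "toy.fasta")
  writeLines(c(paste0(">", genome$id), genome$sequence), fa)
  bed <- file.path(dir, "toy.bed")
  df <- features
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s", genome$id, df$start, df$end,
                     df$name, ifelse(df$strand == "light", "-", "+"), df$kind),
             bed)
  list(fasta = fa, bed = bed)
}

test_that("FASTA + BED loading round-trips the toy annotation", {
  toy <- toy_fixture()
  dir <- withr::local_tempdir()
  paths <- write_toy_fasta_bed(dir, toy$genome, toy$features)
  ref <- load_genome(paths$fasta, paths$bed)
  expect_identical(ref$genome$sequence, toy$genome$sequence)
  expect_setequal(ref$features$name, toy$features$name)
  got <- ref$features[match(toy$features$name, ref$features$name), ]
  expect_equal(got$start, toy$features$start)
  expect_equal(got$end, toy$features$end)
  expect_equal(got$strand, toy$features$strand)
  expect_true(all(got$kind %in% c("mRNA", "tRNA", "rRNA")))
})

test_that("a single toy mRNA parses from BED with its strand", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">g", strrep("ACGT", 25)), fa)
  bed <- file.path(dir, "f.bed")
  writeLines("g\t10\t40\tgene1\t0\t+\tmRNA", bed)
  ref <- load_genome(fa, bed)
  expect_equal(nrow(ref$features), 1L)
  expect_equal(ref$features$strand, "heavy")
  expect_equal(ref$features$start, 10L)
  expect_equal(ref$features$end, 40L)
})

test_that("out-of-bounds and malformed inputs are rejected with clear errors", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">g", strrep("ACGT", 25)), fa)  # 100 nt
  bed <- file.path(dir, "bad.bed")
  writeLines("g\t50\t101\tgene1\t0\t+\tmRNA", bed)
  expect_error(load_genome(fa, bed), "bounds")
  junk <- file.path(dir, "junk.txt")
  writeLines("this is not a genome", junk)
  expect_error(load_genome(junk, bed), "malformed")
})

test_that("GenBank flat files parse to the same genome and features", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "toy.gb")
  seq60 <- paste0(strrep("ACGTGA", 20))  # 120 nt
  body <- vapply(seq(1, 120, by = 60), function(i)
    sprintf("%9d %s", i, paste(substring(seq60, seq(i, i + 50, by = 10),
                                         seq(i + 9, i + 59, by = 10)),
                               collapse = " ")), character(1))
  writeLines(c(
    "LOCUS       TOYGB                120 bp    DNA     circular     01-JAN-2000",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..69",
    '                     /gene="geneA"',
    "     tRNA            complement(80..110)",
    '                     /product="tRNA-Xxx"',
    "ORIGIN",
    body,
    "//"), gb)
  ref <- load_genome(gb)
  expect_equal(ref$genome$id, "TOYGB")
  expect_equal(nchar(ref$genome$sequence), 120L)
  expect_equal(nrow(ref$features), 2L)
  cds <- ref$features[ref$features$kind == "mRNA", ]
  expect_equal(cds$name, "geneA")
  expect_equal(c(cds$start, cds$end), c(9L, 69L))
  trna <- ref$features[ref$features$kind == "tRNA", ]
  expect_equal(trna$strand, "light")
})

test_that("terminal codon classes partition the 64 codons correctly", {
  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")
  cls <- vapply(codons, terminal_codon_class, character(1))
  expect_setequal(codons[cls == "standard_stop"], c("TAA", "TAG"))
  expect_setequal(codons[cls == "mito_arg_nonstop"], c("AGA", "AGG"))
  expect_equal(sum(cls == "sense"), 60L)
  expect_equal(terminal_codon_class("UAA"), "standard_stop")  # RNA input
  expect_error(terminal_codon_class("AT"), "3 nt")
  expect_error(terminal_codon_class("ANT"), "3 nt")
})

test_that("poly(A) completes a stop exactly for T and TA remainders", {
  nts <- c("A", "C", "G", "T")
  rems <- c("", nts, apply(expand.grid(nts, nts), 1, paste, collapse = ""))
  ok <- vapply(rems, polya_completes_stop, logical(1))
  expect_setequal(rems[ok], c("T", "TA"))
  expect_error(polya_completes_stop("TAA"), "longer")
})

test_that("in-frame stop scan finds junction stops at the right codon index", {
  expect_equal(inframe_stop_scan("TA", "AGGGC", 5), 0L)
  expect_equal(inframe_stop_scan("T", "AGCCC", 5), 0L)    # T|AG
  expect_true(is.na(inframe_stop_scan("", "CATCAT", 6)))
  expect_equal(inframe_stop_scan("", "CCCTAAGG", 8), 1L)  # CCC TAA
  expect_true(is.na(inframe_stop_scan("T", "", 10)))       # empty flank
  # stop beyond the window is not reported
  expect_true(is.na(inframe_stop_scan("", "CCCTAA", 3)))
})

test_that("transcript models keep frame invariants on toy and human genomes", {
  for (models in list(toy_fixture()$models, human_fixture()$models)) {
    for (m in models) {
      expect_equal((nchar(m$cds_seq) - nchar(m$remainder)) %% 3, 0)
      expect_true(nchar(m$remainder) <= 2)
      expect_equal(nchar(m$terminal_codon), 3L)
      expect_identical(m$anchor_ref,
                       paste0(m$cds_seq, m$encoded_utr_seq, m$flank_seq))
    }
  }
})

test_that("light-strand models are reverse-complemented into mRNA sense", {
  toy <- toy_fixture()
  m <- toy$models$ND6L
  row <- toy$features[toy$features$name == "ND6L", ]
  genomic <- substr(toy$genome$sequence, row$start + 1, row$end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic)))
  expect_identical(m$cds_seq, rc)
  expect_equal(m$terminal_codon, "AGG")
})

test_that("models are invariant under genome strand flip", {
  toy <- toy_fixture()
  g <- toy$genome
  L <- nchar(g$sequence)
  flipped <- list(id = g$id, circular = g$circular,
                  sequence = as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(g$sequence))))
  f <- toy$features
  flipped_feats <- data.frame(
    name = f$name, kind = f$kind,
    strand = ifelse(f$strand == "heavy", "light", "heavy"),
    start = L - f$end, end = L - f$start, stringsAsFactors = FALSE)
  m1 <- build_transcript_models(g, f)
  m2 <- build_transcript_models(flipped, flipped_feats)
  for (nm in names(m1)) {
    expect_identical(m2[[nm]]$cds_seq, m1[[nm]]$cds_seq)
    expect_identical(m2[[nm]]$flank_seq, m1[[nm]]$flank_seq)
    expect_identical(m2[[nm]]$encoded_utr_seq, m1[[nm]]$encoded_utr_seq)
  }
})

test_that("duplicate or contained mRNA annotations are annotation errors", {
  toy <- toy_fixture()
  f <- toy$features
  dup <- rbind(f, f[f$name == "ND3L", ])
  expect_error(build_transcript_models(toy$genome, dup), "duplicate")
  inner <- f[f$name == "ND3L", ]
  inner$name <- "INNER"; inner$start <- inner$start + 6L
  inner$end <- inner$end - 6L
  expect_error(build_transcript_models(toy$genome, rbind(f, inner)),
               "contained")
})
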