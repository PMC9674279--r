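# Category classification and termination logic.

test_that("the category rule table matches its definitions case by case", {
  th <- thresholds()
  m <- stub_model()                           # T remainder, tRNA flank, no UTR
  cl <- function(off, tail, model = m) classify_read(off, tail, model, th)

  expect_equal(cl(0L, "")$category, "CDS")
  r <- cl(0L, "AAAAAAAA")
  expect_equal(r$category, "CDS_POLYA")
  expect_equal(r$polya_len, 8L)
  r <- cl(5L, "")
  expect_equal(r$category, "CDS_TRNA")        # 5 nt into the flanking tRNA
  expect_equal(r$flank_len, 5L)
  expect_equal(cl(-10L, "AAAA")$category, "TRUNC_POLYA")
  r <- cl(-10L, "")
  expect_equal(r$category, "UNCLASSIFIED")    # truncated but not adenylated
  expect_true(is.na(r$termination))
  expect_equal(cl(1L, "")$category, "SHORT_EXTENSION")
  expect_equal(cl(2L, "AAA")$category, "SHORT_EXTENSION")
  expect_equal(cl(0L, "ACAG")$reason, "mixed_tail")

  mu <- stub_model(utr = "CCTGCTTCC")         # 9-nt encoded UTR
  expect_equal(cl(4L, "", mu)$category, "CDS_UTR")
  expect_equal(cl(4L, "AAAAA", mu)$category, "CDS_UTR_POLYA")
  expect_equal(cl(9L + 4L, "", mu)$category, "CDS_TRNA")
  expect_equal(cl(9L + 1L, "", mu)$category, "SHORT_EXTENSION")
})

test_that("classifier agrees with the brute-force rule table exhaustively", {
  th <- thresholds()
  models <- list(
    no_utr = stub_model(),
    with_utr = stub_model(utr = "CCTGCTTCC"),
    mrna_flank = stub_model(flank_kind = "mRNA"))
  tails <- c("", vapply(1:12, function(n) strrep("A", n), character(1)),
             "AACAA", "CAAAA", "G")
  n_checked <- 0L
  for (nm in names(models)) {
    m <- models[[nm]]
    u <- nchar(m$encoded_utr_seq)
    for (off in -15:15) {
      if (off > u + nchar(m$flank_seq)) next
      for (tail in tails) {
        got <- classify_read(off, tail, m, th)$category
        want <- oracle_category(off, tail, u, identical(m$flank_kind, "tRNA"))
        expect_identical(got, want,
                         info = sprintf("%s off=%d tail=%s", nm, off, tail))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 1000L)
})

test_that("termination status reproduces the per-gene logic", {
  th <- thresholds()
  # ND3-type: no encoded stop, tRNA flank with no junction stop
  nd3 <- stub_model(terminal_codon = "GAA", remainder = "T",
                    flank_seq = "TGGTATATAGTTTAAACAAAAC")
  expect_equal(classify_read(0L, "", nd3, th)$termination, "nonstop")
  expect_equal(classify_read(0L, "AAAA", nd3, th)$termination, "terminates")
  expect_equal(classify_read(5L, "", nd3, th)$termination, "nonstop")
  expect_equal(classify_read(-5L, "AAA", nd3, th)$termination, "nonstop")

  # ND1-type: TA remainder, flank completes TAG at the junction
  nd1 <- stub_model(terminal_codon = "ACC", remainder = "TA",
                    flank_seq = "GAAAATATGTCTGATAAAAGAG")
  expect_equal(classify_read(4L, "", nd1, th)$termination, "terminates")
  expect_equal(classify_read(0L, "", nd1, th)$termination, "nonstop")
  expect_equal(classify_read(-6L, "AAAA", nd1, th)$termination, "nonstop")

  # CO2-type: encoded stop, short UTR
  co2 <- stub_model(terminal_codon = "TAG", remainder = "", utr = "CACCC")
  expect_equal(classify_read(0L, "", co2, th)$termination, "terminates")
  expect_equal(classify_read(3L, "AAAAA", co2, th)$termination, "terminates")
  expect_equal(classify_read(-8L, "AAA", co2, th)$termination, "nonstop")

  # CO1-type: AGA terminal codon, long UTR
  co1 <- stub_model(terminal_codon = "AGA", remainder = "",
                    utr = strrep("C", 72))
  r <- classify_read(5L, "", co1, th)
  expect_equal(r$termination, "arg_codon_resistant")
  expect_true(r$rescue_substrate)             # 5-nt UTR fits the channel
  r <- classify_read(30L, "", co1, th)
  expect_equal(r$termination, "arg_codon_resistant")
  expect_false(r$rescue_substrate)            # UTR too long
  r <- classify_read(5L, "AAAA", co1, th)
  expect_false(r$rescue_substrate)            # polyadenylated
})

test_that("a transcript with an encoded stop never yields nonstop CDS-like calls", {
  th <- thresholds()
  m <- stub_model(terminal_codon = "TAA", remainder = "", utr = "CCTGC")
  for (case in list(list(0L, ""), list(0L, "AAAA"), list(3L, ""),
                    list(3L, "AAAAAA"))) {
    r <- classify_read(case[[1]], case[[2]], m, th)
    expect_true(r$category %in% c("CDS", "CDS_POLYA", "CDS_UTR", "CDS_UTR_POLYA"))
    expect_equal(r$termination, "terminates")
  }
  # the encoded stop precedes any flanking-tRNA extension too
  r <- classify_read(5L + 4L, "", m, th)
  expect_equal(r$category, "CDS_TRNA")
  expect_equal(r$termination, "terminates")
  # only truncation deep enough to remove the stop makes a nonstop read
  expect_equal(classify_read(-6L, "AAAA", m, th)$termination, "nonstop")
})

test_that("exactly three categories map to nonstop for an ND3-type transcript", {
  th <- thresholds()
  nd3 <- stub_model(terminal_codon = "GAA", remainder = "T",
                    flank_seq = "TGGTATATAGTTTAAACAAAAC")
  cases <- list(
    CDS = list(0L, ""), CDS_POLYA = list(0L, "AAAAA"),
    CDS_TRNA = list(6L, ""), TRUNC_POLYA = list(-8L, "AAAA"),
    SHORT_EXTENSION = list(2L, ""), UNCLASSIFIED = list(-8L, ""))
  res <- lapply(cases, function(x) classify_read(x[[1]], x[[2]], nd3, th))
  nonstop_cats <- unique(vapply(res[vapply(res, function(r)
    identical(r$termination, "nonstop"), logical(1))],
    function(r) r$category, character(1)))
  expect_setequal(nonstop_cats, c("CDS", "CDS_TRNA", "TRUNC_POLYA"))
})

test_that("raising trna_min only moves reads out of CDS_TRNA", {
  m <- stub_model()
  offsets <- 1:12
  for (hi in c(4L, 6L, 9L)) {
    lo_calls <- vapply(offsets, function(o)
      classify_read(o, "", m, thresholds(trna_min = 3L))$category, character(1))
    hi_calls <- vapply(offsets, function(o)
      classify_read(o, "", m, thresholds(trna_min = hi))$category, character(1))
    moved_in <- hi_calls == "CDS_TRNA" & lo_calls != "CDS_TRNA"
    expect_false(any(moved_in))
    expect_lte(sum(hi_calls == "CDS_TRNA"), sum(lo_calls == "CDS_TRNA"))
  }
})

test_that("raising rescue_utr_max only increases rescue-substrate calls", {
  co1 <- stub_model(terminal_codon = "AGA", remainder = "",
                    utr = strrep("C", 40))
  offsets <- 0:30
  n_rescue <- vapply(c(3L, 9L, 15L, 25L), function(rmax) {
    sum(vapply(offsets, function(o)
      classify_read(o, "", co1, thresholds(rescue_utr_max = rmax))$rescue_substrate,
      logical(1)))
  }, integer(1))
  expect_true(all(diff(n_rescue) >= 0))
})

test_that("every anchored read gets exactly one category (partition)", {
  toy <- toy_fixture()
  sim <- simulate_reads(sim_config(n_reads = 400L, seed = 5L), toy$models)
  res <- classify_library(sim$reads, toy$models)
  expect_equal(nrow(res$calls), sum(res$anchors$anchored))
  expect_true(all(res$calls$category %in% mitoterm:::CATEGORIES))
  summ <- summarize_categories(res$calls, toy$models)
  per_tr <- summ[summ$transcript != "PUNCTUATED_POOL", ]
  count_cols <- grep("^n_", names(per_tr), value = TRUE)
  count_cols <- setdiff(count_cols, "n_reads")
  expect_equal(rowSums(per_tr[, count_cols]), per_tr$n_reads,
               ignore_attr = TRUE)
})
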