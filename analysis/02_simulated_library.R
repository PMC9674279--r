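#!/usr/bin/env Rscript
# Simulate a mixed 3'-end library on the toy genome, run the full pipeline
# (trim -> anchor -> classify), and aggregate the category summaries,
# nonstop-type distribution and 3'-position histograms.
# Writes results/sim_category_summary.tsv, results/sim_nonstop_types.tsv,
# results/sim_histogram_<transcript>.tsv, results/sim_read_calls.tsv.

suppressMessages(library(mitoterm))
dir.create("results", showWarnings = FALSE)

toy <- make_toy_genome(seed = 1L)
# a library with every aberration class represented (proportions chosen to
# mimic a mostly-processed, mostly-polyadenylated transcriptome with a
# low-level nonstop load)
cfg <- sim_config(
  n_reads = 20000L,
  mixture = c(CDS_POLYA = 0.55, CDS = 0.15, CDS_UTR = 0.1,
              CDS_UTR_POLYA = 0.05, CDS_TRNA = 0.08, TRUNC_POLYA = 0.05,
              SHORT_EXTENSION = 0.02),
  seed = 20L)
sim <- simulate_reads(cfg, toy$models)
res <- classify_library(sim$reads, toy$models)

cat("Pipeline counts:\n")
print(res$counts)
if (nrow(res$rejected)) print(res$rejected)

write_calls_tsv(res$calls, "results/sim_read_calls.tsv")

summ <- summarize_categories(res$calls, toy$models)
write.table(summ, "results/sim_category_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nPer-transcript nonstop proportions:\n")
print(summ[, c("transcript", "n_reads", "nonstop_count",
               "nonstop_proportion", "nonstop_share_overall")])

dist_all <- nonstop_type_distribution(res$calls)
punct <- c("ND3L", "ND1L")
dist_rows <- rbind(
  data.frame(pool = "all", t(dist_all$proportions),
             n_nonstop = dist_all$n_nonstop),
  do.call(rbind, lapply(punct, function(tr) {
    d <- nonstop_type_distribution(res$calls, transcripts = tr)
    data.frame(pool = tr, t(d$proportions), n_nonstop = d$n_nonstop)
  })))
write.table(dist_rows, "results/sim_nonstop_types.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nNonstop type distribution (pooled and per junction archetype):\n")
print(dist_rows)

for (tr in c("ND3L", "CO1L")) {
  h <- histogram_3prime(res$calls, tr)
  df <- data.frame(offset = as.integer(names(h$counts)), count = h$counts)
  write.table(df[order(df$offset), ],
              sprintf("results/sim_histogram_%s.tsv", tr), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

co1 <- res$calls[res$calls$transcript == "CO1L", ]
cat(sprintf("\nCO1L (AGA-terminal) reads: %d; rescue substrates (UTR <= 9 nt,\n",
            nrow(co1)))
cat(sprintf("no poly(A)): %d (%.1f%%)\n", sum(co1$rescue_substrate),
            100 * mean(co1$rescue_substrate)))

cat("\nFinding: with the ND1-type junction stop in force, nonstop reads on\n")
cat("the ND1-like unit come only from unadenylated CDS ends and truncated\n")
cat("poly(A) transcripts, while the ND3-like unit adds the CDS+tRNA class —\n")
cat("the three-source structure the classifier is built around.\n")
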