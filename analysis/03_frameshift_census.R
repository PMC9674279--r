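#!/usr/bin/env Rscript
# Terminal-codon and -1 frameshift codon census.
#
# Real haplorhine CDS 3'-end sets are a download away and not bundled; this
# driver (a) runs the census on the two human AGA/AGG-terminal genes taken
# from the bundled genome, and (b) builds a SYNTHETIC primate-like cohort
# that encodes the competing hypotheses — a clade where the upstream T of
# the terminal AGA is conserved (every -1 codon is TAG) and a clade where it
# is not — to show what the census reports in each regime.
# Writes results/census_human.tsv and results/census_synthetic_cohort.tsv.

suppressMessages(library(mitoterm))
dir.create("results", showWarnings = FALSE)

hs <- human_mtdna()
human <- data.frame(
  species = c("human_CO1", "human_ND6"),
  seq3 = c(cds_end_seq(hs$models$CO1, 15), cds_end_seq(hs$models$ND6, 15)),
  stringsAsFactors = FALSE)
cen_h <- codon_census(human, dedupe = FALSE)
write.table(cen_h$per_species, "results/census_human.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Human AGA/AGG-terminal genes:\n")
print(cen_h$per_species)

# synthetic cohort: 40 species, conserved-T clade vs degenerate clade
set.seed(7)
rand_ctx <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
conserved <- data.frame(
  species = sprintf("conservedT_sp%02d", 1:20),
  seq3 = vapply(1:20, function(i) paste0(rand_ctx(8), "TAGA"), character(1)),
  stringsAsFactors = FALSE)
degenerate <- data.frame(
  species = sprintf("degenerate_sp%02d", 1:20),
  seq3 = vapply(1:20, function(i)
    paste0(rand_ctx(8), sample(c("C", "G", "A"), 1), "AGA"), character(1)),
  stringsAsFactors = FALSE)
cohort <- rbind(conserved, degenerate)
cen <- codon_census(cohort, dedupe = TRUE)
write.table(cen$per_species, "results/census_synthetic_cohort.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tag_share <- function(sub) mean(sub$minus1_is_stop)
per <- cen$per_species
cat(sprintf("\nSynthetic cohort: %d raw, %d after deduplication (%d removed),\n",
            cen$n_raw, cen$n_used, cen$n_deduped))
cat(sprintf("ambiguous excluded: %d\n", cen$n_excluded_ambiguous))
cat(sprintf("-1 codon is a stop: %.0f%% in the conserved-T clade, %.0f%% in the degenerate clade\n",
            100 * tag_share(per[grepl("^conservedT", per$species), ]),
            100 * tag_share(per[grepl("^degenerate", per$species), ])))
cat("\nFinding: the census cleanly separates the two regimes; a strict -1\n")
cat("frameshift termination mechanism predicts the conserved pattern, so a\n")
cat("mixed census across a clade argues against it.\n")
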