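#!/usr/bin/env Rscript
# Stage 3: enrichment scoring.
#
# Computes per-replicate and mean log2 fold changes for the function
# contrast (glucose T0 -> T2) and the two kinase contrasts (T1 -> T3 in
# glucose and galactose), ranks variants by mean function score, and
# checks recovery of the generating fitness landscape.

library(cofilinscreen)

counts <- read_count_tsv("results/counts.tsv")
design <- screen_design(replicates = 3, depth = 1e6)
counts$samples <- design$samples
fitness <- read_fitness_tsv("results/fitness_truth.tsv")

records <- score_screen(counts, pseudocount = 0.5)
write_enrichment_tsv(records, "results/enrichment.tsv")

cat("variants enriched (mean function log2FC > 0):",
    length(select_enriched(records)), "of", nrow(records), "\n")
cat(sprintf("Spearman(true w_glu, mean function score): %.3f\n",
            cor(fitness$w_glu, records$func_mean, method = "spearman")))
for (v in c("RSGV", "ASGV", "ASGM")) {
  r <- records[records$variant == v, ]
  cat(sprintf("%s: mean function log2FC %+.2f, rank %d\n",
              v, r$func_mean, r$rank))
}
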