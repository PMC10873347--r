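#!/usr/bin/env Rscript
# Stage 5: positional statistics of the enriched set.
#
# Heat-map means and box statistics per residue-position, the exact
# binomial probability logo of the enriched set against the design
# background (Bonferroni threshold over the 62 tested cells), and pairwise
# residue covariation within the 400 most enriched sequences.

library(cofilinscreen)

records <- read.delim("results/enrichment.tsv", stringsAsFactors = FALSE)

hm <- residue_position_means(records)
write.table(hm, "results/heatmap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
dists <- do.call(rbind, lapply(2:5, function(p)
  score_distribution_summary(records, p)))
write.table(dists, "results/distributions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

enriched <- select_enriched(records)
logo <- binomial_logo(enriched)
write.table(logo, "results/logo.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("enriched foreground n =", length(enriched), "\n")
top5 <- head(logo[order(-logo$height), ], 5)
cat("strongest over-represented cells (position/residue/height):\n")
print(top5[, c("position", "residue", "k", "height", "significant")])

cov <- pairwise_covariation(top_enriched(records, 400))
write.table(cov, "results/covariation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gv <- cov[cov$pos_i == 4 & cov$pos_j == 5 &
            cov$res_i == "G" & cov$res_j == "V", ]
cat(sprintf("Gly4-Val5 in top 400: observed %d, expected %.1f, log2(obs/exp) %+.2f\n",
            gv$observed, gv$expected, gv$log2_obs_exp))

# mean-score gap between Thr3/Thr5 and Ser3/Thr5 combinations
p3 <- residue_at(records$variant, 3)
p5 <- residue_at(records$variant, 5)
m_tt <- mean(records$func_mean[p3 == "T" & p5 == "T"])
m_st <- mean(records$func_mean[p3 == "S" & p5 == "T"])
cat(sprintf("mean function score Thr3/Thr5 %.2f vs Ser3/Thr5 %.2f\n",
            m_tt, m_st))
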