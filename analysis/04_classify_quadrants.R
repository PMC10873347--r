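#!/usr/bin/env Rscript
# Stage 4: kinase-sensitivity quadrant classification.
#
# Places every variant in the glucose-vs-galactose enrichment plane:
# functional variants (enriched on the glucose axis) that are strictly
# depleted under kinase induction are called sensitive; the rest of the
# functional set is resistant.

library(cofilinscreen)

records <- read.delim("results/enrichment.tsv", stringsAsFactors = FALSE)
calls <- classify_quadrants(records)
write.table(calls, "results/quadrants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
overall <- sensitivity_summary(calls)
by_acceptor <- sensitivity_summary(calls, stratify_by = 3)
write.table(rbind(overall, by_acceptor), "results/sensitivity_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(table(calls$call))
cat(sprintf("fraction of functional variants sensitive to the kinase: %.2f\n",
            overall$fraction_sensitive))
cat(sprintf("  Ser3: %.2f   Thr3: %.3f\n",
            by_acceptor$fraction_sensitive[by_acceptor$stratum == "S"],
            by_acceptor$fraction_sensitive[by_acceptor$stratum == "T"]))
for (v in c("ASGV", "ATGV", "ASLV")) {
  cat(v, "->", calls$call[calls$variant == v], "\n")
}
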