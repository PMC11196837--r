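#!/usr/bin/env Rscript
# Step 4: region x management summaries comparing mitochondrial and nuclear
# ancestry proportions per lineage through 95% Wald intervals at the
# lineage-appropriate effective allele counts (n colonies for mtDNA,
# (2 + 12) x n alleles for nuclear).

library(apiadmix)

est <- read.csv("results/estimates.csv")
mito <- read.csv("results/mito_report.csv")
meta <- mito[, c("colony_id", "region", "management")]

groups <- summarize_groups(est, mito, meta,
                           group_by = c("region", "management"))
write.csv(groups, "results/group_summary.csv", row.names = FALSE)
verdicts <- groups[!is.na(groups$verdict),
                   c("region", "management", "lineage", "verdict")]
write.csv(verdicts, "results/verdicts.csv", row.names = FALSE)

message(sprintf("%d group x lineage rows across %d groups",
                nrow(groups), nrow(unique(groups[, c("region", "management")]))))
message("verdict table (mito vs nuclear ancestry per lineage):")
print(table(verdicts$lineage, verdicts$verdict))
message("rows where the two marker systems disagree detectably:")
print(verdicts[verdicts$verdict != "not_distinguishable", ], row.names = FALSE)
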