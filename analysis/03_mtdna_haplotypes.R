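#!/usr/bin/env Rscript
# Step 3: maternal ancestry from the COI-COII sequences — nearest-reference
# lineage classification, haplotype deduplication, parsimony-style network,
# and apiary-level mitochondrial Africanization.

library(apiadmix)

refs <- read_reference_fasta("results/data/references.fasta")
seqs <- apiadmix:::read_fasta("results/data/colony_seqs.fasta")
meta <- load_colonies("results/data/colonies.csv",
                      load_panel("results/data/panel.csv"))
meta <- do.call(rbind, lapply(meta, function(x) {
  data.frame(colony_id = x$colony_id, apiary_id = x$apiary_id,
             region = x$region, management = x$management)
}))

calls <- classify_colonies(seqs, refs)
write.csv(merge(calls, meta, by = "colony_id"), "results/mito_report.csv",
          row.names = FALSE)
message(sprintf("classified %d colonies; lineage counts: %s",
                nrow(calls),
                paste(names(table(calls$lineage)), table(calls$lineage),
                      sep = "=", collapse = ", ")))

haps <- dedupe_haplotypes(merge(
  data.frame(colony_id = names(seqs), sequence = unname(seqs)),
  calls[, c("colony_id", "lineage")], by = "colony_id"))
message(sprintf("%d distinct haplotypes among %d colonies",
                nrow(haps), sum(haps$count)))

net <- build_network(haps, max_steps = 10L)
write.csv(net$edges, "results/network_edges.csv", row.names = FALSE)
message(sprintf("haplotype network: %d components, spanning weight %d",
                net$n_components, net$spanning_weight))

afr <- mito_africanization(merge(calls[, c("colony_id", "lineage")],
                                 meta[, c("colony_id", "apiary_id")],
                                 by = "colony_id"))
write.csv(afr, "results/mito_africanization.csv", row.names = FALSE)
message("per-apiary mitochondrial Africanization (% A haplotypes):")
for (i in seq_len(nrow(afr))) {
  message(sprintf("  %s: %.1f%% (%d colonies)", afr$apiary_id[i],
                  afr$pct_african[i], afr$n_colonies[i]))
}
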