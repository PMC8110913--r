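#!/usr/bin/env Rscript
# Step 6: over-representation analysis of the miRNA-targeted dysregulated
# mRNAs against the simulated pathway collection (upper-tail
# hypergeometric test, BH within namespace, both raw and adjusted p
# below 0.05).

library(cernet)

mrna_f <- read.delim("results/mrna_edges_filtered.tsv")
measured <- read_expression("results/sim_inputs/mrna_matrix.tsv",
                            "results/sim_inputs/samples.tsv")
# background: genes present in both the annotation and the measured matrix
coll <- read_gmt("results/sim_inputs/gene_sets.gmt",
                 universe = sort(rownames(measured$mat)))

query <- sort(unique(mrna_f$target))
enr <- hypergeom_enrich(query, coll)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(top_terms(enr), "results/enrichment_top.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("query: %d mRNAs against %d terms; %d significant\n",
            length(query), nrow(enr), sum(enr$significant)))
print(enr[enr$significant,
          c("term", "k", "K", "p_value", "adjusted_p")],
      row.names = FALSE)
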