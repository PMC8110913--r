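#!/usr/bin/env Rscript
# Step 7: layer the key lncRNAs with enriched pathways, extract the
# lncRNA-miRNA-mRNA regulatory axes, and build the TF network over the
# axis mRNAs from the binding-site count table.

library(cernet)

triplets <- read.delim("results/triplets.tsv")
keys <- read.delim("results/key_lncrnas.tsv")
enr <- read.delim("results/enrichment.tsv")
coll <- read_gmt("results/sim_inputs/gene_sets.gmt")
bindings <- read.delim("results/sim_inputs/tf_bindings.tsv",
                       comment.char = "#")

pnet <- pathway_network(keys, triplets, enr, coll)
cat("pathways per key lncRNA:\n")
print(pnet$lncrna_pathway_counts, row.names = FALSE)

tfnet <- tf_network(bindings, unique(pnet$triplets$mrna))
axes <- extract_axes(pnet, tf_net = tfnet)
cat(sprintf("regulatory axes: %d; TF network: %d edges\n",
            nrow(axes), nrow(tfnet$edges)))
cat("top TFs by number of targets:\n")
print(head(tfnet$ranking, 3), row.names = FALSE)

write.table(axes, "results/axes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tfnet$edges, "results/tf_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tfnet$ranking, "results/tf_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("done; all tables under results/\n")
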