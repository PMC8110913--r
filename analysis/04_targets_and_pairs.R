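#!/usr/bin/env Rscript
# Step 4: filter the scored miRNA target predictions against the retained
# miRNA catalogue and the DE sets (mRNA edges: score > 80, strict; lncRNA
# edges: upper decile of the supplied score distribution), then compute
# correlated co-dysregulated lncRNA-mRNA pairs (Pearson r > 0.99,
# p < 0.05, both groups pooled).

library(cernet)

inp <- "results/sim_inputs"
lnc <- read_expression(file.path(inp, "lncrna_matrix.tsv"),
                       file.path(inp, "samples.tsv"))
mrna <- read_expression(file.path(inp, "mrna_matrix.tsv"),
                        file.path(inp, "samples.tsv"))
lnc_de <- read.delim("results/de_lncrna.tsv")
mrna_de <- read.delim("results/de_mrna.tsv")
cat_tab <- read.delim("results/sim_mirna_catalogue.tsv")
retained <- retained_mirnas(cat_tab)
lnc_edges <- read.delim(file.path(inp, "lncrna_edges.tsv"),
                        comment.char = "#")
mrna_edges <- read.delim(file.path(inp, "mrna_edges.tsv"),
                         comment.char = "#")

lnc_f <- filter_targets(lnc_edges, retained, lnc_de)
mrna_f <- filter_targets(mrna_edges, retained, mrna_de)
cat(sprintf("lncRNA edges: %d -> %d (score cutoff %.1f)\n",
            nrow(lnc_edges), nrow(lnc_f),
            attr(lnc_f, "thresholds")[["lncRNA"]]))
cat(sprintf("mRNA edges: %d -> %d (score cutoff %.1f)\n",
            nrow(mrna_edges), nrow(mrna_f),
            attr(mrna_f, "thresholds")[["mRNA"]]))

pairs <- coexpression_pairs(lnc$mat, mrna$mat, lnc_de, mrna_de)
cat(sprintf("co-dysregulated correlated pairs: %d\n", nrow(pairs)))

write.table(lnc_f, "results/lncrna_edges_filtered.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mrna_f, "results/mrna_edges_filtered.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pairs, "results/coexpression_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
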