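#!/usr/bin/env Rscript
# Step 2: two-class differential screening of the simulated lncRNA and
# mRNA matrices (|FC| > 1.5, Student's t on log2 values, p < 0.05).

library(cernet)

inp <- "results/sim_inputs"
lnc <- read_expression(file.path(inp, "lncrna_matrix.tsv"),
                       file.path(inp, "samples.tsv"))
mrna <- read_expression(file.path(inp, "mrna_matrix.tsv"),
                        file.path(inp, "samples.tsv"))

lnc_de <- de_screen(lnc$mat, lnc$groups, kind = "lncRNA")
mrna_de <- de_screen(mrna$mat, mrna$groups, kind = "mRNA")

dir.create("results", showWarnings = FALSE)
write.table(lnc_de, "results/de_lncrna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mrna_de, "results/de_mrna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (de in list(lncRNA = lnc_de, mRNA = mrna_de)) {
  up <- sum(de$direction == "up"); dn <- sum(de$direction == "down")
  cat(sprintf("%s screen: %d genes, %d up, %d down\n",
              de$kind[1], nrow(de), up, dn))
}
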