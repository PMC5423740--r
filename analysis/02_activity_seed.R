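#!/usr/bin/env Rscript
# Step 2: read the study back from disk, standardize and filter, score
# pathway activity (PC1 of each pathway's standardized member-gene
# submatrix) and pick the seed pathway (largest |t| of activity between
# groups). Writes the per-pathway statistic table.

suppressPackageStartupMessages(library(pinsel))

study <- read_expression_tsv("results/data/expression.tsv",
                             labels = "results/data/labels.tsv")
pathways <- read_gmt("results/data/pathways.gmt")
ppi <- read_ppi_tsv("results/data/ppi.tsv", score_scale = "unit")

inputs <- prepare_inputs(study, pathways, ppi)
cat(sprintf("standardized %d genes; %d informative pathways; %d PPI edges\n",
            nrow(inputs$study$standardized), length(inputs$pathways),
            nrow(inputs$ppi)))

activity <- compute_activity_matrix(inputs)
seed <- select_seed(activity, inputs$study$labels)
print(seed)

dir.create("results", showWarnings = FALSE)
write.table(seed$per_pathway_statistics, "results/activity_statistics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/activity_statistics.tsv\n")
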