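#!/usr/bin/env Rscript
# Step 3: per-gene differential expression (pooled t, raw p < 0.05),
# per-PPI-edge Pearson correlations within each condition, pathway
# interaction network construction (shared-DEG or co-expressed-PPI
# criteria, weights = sum of |PCC| over crossing PPI pairs) and reduction
# to the top 5% of edges. Writes the DEG table and both edge lists.

suppressPackageStartupMessages(library(pinsel))

study <- read_expression_tsv("results/data/expression.tsv",
                             labels = "results/data/labels.tsv")
pathways <- read_gmt("results/data/pathways.gmt")
ppi <- read_ppi_tsv("results/data/ppi.tsv", score_scale = "unit")
inputs <- prepare_inputs(study, pathways, ppi)

degs <- differential_expression(inputs$study, alpha = 0.05)
cat(sprintf("%d of %d genes differentially expressed at p < 0.05\n",
            sum(degs$is_deg), nrow(degs)))

corr <- pairwise_pcc(inputs$study, inputs$ppi)
pin <- build_pin(inputs, degs, corr)
reduced <- reduce_top_fraction(pin, fraction = 0.05)
cat(sprintf("PIN: %d qualified pathway pairs; top 5%% kept: %d edges\n",
            nrow(pin$edges), nrow(reduced$edges)))
if (nrow(reduced$edges)) {
  cat(sprintf("heaviest interaction: %s -- %s (weight %.4f)\n",
              pin$pathway_names[reduced$edges$id_a[
                which.max(reduced$edges$weight)] + 1L],
              pin$pathway_names[reduced$edges$id_b[
                which.max(reduced$edges$weight)] + 1L],
              max(reduced$edges$weight)))
}

dir.create("results", showWarnings = FALSE)
write.table(degs, "results/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_network_tsv(pin, "results/pin_full.tsv")
write_network_tsv(reduced, "results/pin_reduced.tsv")
cat("wrote results/deg_table.tsv, results/pin_full.tsv, results/pin_reduced.tsv\n")
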