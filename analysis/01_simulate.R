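#!/usr/bin/env Rscript
# Step 1: generate the synthetic case/control study used throughout the
# analysis (15 disease vs 8 control samples, 1000 genes, 50 pathways of
# which 5 consecutive ones are planted as dysregulated) and write the three
# standard inputs plus the ground truth under results/data/.

suppressPackageStartupMessages(library(pinsel))

cfg <- synthetic_config(seed = 3L)
paths <- run_synth(cfg, "results/data")

truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
cat(sprintf("wrote %d files under results/data\n", length(paths)))
cat(sprintf("planted pathway IDs: %s\n",
            paste(truth$planted_pathway_ids, collapse = ", ")))
cat(sprintf("affected genes: %d\n", length(truth$affected_genes)))
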