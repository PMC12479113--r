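#!/usr/bin/env Rscript
# Simulate the synthetic ChIP-seq world used by the downstream analyses:
# a 60-TF x 30-cell-line compendium (600 experiments, 2009-2023) with
# rich-get-richer attention skew, a bimodal expression structure, TSS-
# enriched peaks, GWAS SNPs, knockout DEG counts and two planted hidden
# gems. All downstream scripts read the files written here.

library(tfcoverage)

out <- file.path("results", "world")
cfg <- world_config(seed = 20240601)
world <- generate_world(cfg)
write_world(world, out)

cat(sprintf("world written to %s\n", out))
cat(sprintf("  %d experiments over %d TFs and %d cell types (%d classes)\n",
            nrow(world$metadata), cfg$n_tfs, cfg$n_cell_types,
            cfg$n_classes))
cat(sprintf("  %d truly expressed TF-cell-line pairs (pi = %.2f)\n",
            nrow(world$ground_truth$true_expressed), cfg$pi_expressed))
cat(sprintf("  %d planted hidden gems: %s\n",
            nrow(world$ground_truth$planted_gems),
            paste(world$ground_truth$planted_gems$tf,
                  world$ground_truth$planted_gems$cell_type_class,
                  sep = "-", collapse = ", ")))
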