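#!/usr/bin/env Rscript
# Could a different acquisition order have covered GWAS SNPs faster?
# Shuffle deposit dates over the experiments of the busiest class 100
# times, score each order's annual GWAS-SNP trajectory by span-normalized
# AUC, relate AUC to early TF diversity, and compare the top-3/bottom-3
# shuffled orders to the real one with subsampled Welch tests (90%/50%).

library(tfcoverage)

world <- read_world(file.path("results", "world"))
yrs <- as.integer(format(world$metadata$deposit_date, "%Y"))
years <- seq(min(yrs), max(yrs))
cls_of <- world$class_map$cell_type_class[
  match(world$metadata$cell_type, world$class_map$cell_type)]
busiest <- names(which.max(table(cls_of)))

sim <- run_order_simulation(world$metadata, world$snps, world$peaks,
                            busiest, level = "class",
                            mapping = world$class_map, years = years,
                            n_reps = 100, seed = world$seed)
write.table(sim$results, file.path("results", "order_simulation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

real_auc <- sim$results$auc[sim$results$order == "real"]
sh <- sim$results[sim$results$order != "real", ]
cat(sprintf("entity %s: real AUC %.4f; shuffled AUC %.4f-%.4f (median %.4f)\n",
            busiest, real_auc, min(sh$auc), max(sh$auc), median(sh$auc)))
cat(sprintf("%d of 100 shuffled orders beat the real acquisition order\n",
            sum(sh$auc > real_auc)))
rho <- cor(sh$auc, sh$early_unique_tfs, method = "spearman")
cat(sprintf("spearman(AUC, unique TFs measured in the first third): %.3f\n",
            rho))

ranked <- sh$order[order(sh$auc, decreasing = TRUE)]
chosen <- c(head(ranked, 3), tail(ranked, 3))
welch <- subsample_compare(sim, chosen, fractions = c(0.9, 0.5),
                           n_subsamples = 50, seed = world$seed + 1)
write.table(welch, file.path("results", "order_welch.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("subsampled Welch comparison vs the real order:\n")
print(welch[, c("order", "fraction", "mean_auc", "mean_auc_real", "t", "p")],
      row.names = FALSE, digits = 4)
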