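#!/usr/bin/env Rscript
# Call expressed/not-expressed per (TF, cell line) with the one-step
# threshold, aggregate to cell-type classes, and build the
# measured/unmeasured/not-expressed inventory of TF-sample pairs.

library(tfcoverage)

world <- read_world(file.path("results", "world"))
dir.create("results", showWarnings = FALSE)

calls <- call_expression(world$expression)
write.table(calls$fits, file.path("results", "step_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("fit %d TFs (%d flat, %d unfittable)\n", nrow(calls$fits),
            sum(calls$fits$flat), length(calls$skipped)))

# sanity against the generator's ground truth
truth <- world$ground_truth$true_expressed
called <- which(calls$calls == TRUE, arr.ind = TRUE)
called_pairs <- paste(rownames(calls$calls)[called[, 1]],
                      colnames(calls$calls)[called[, 2]])
acc <- mean(c(called_pairs %in% paste(truth$tf, truth$cell_type),
              paste(truth$tf, truth$cell_type) %in% called_pairs))
cat(sprintf("agreement with generator truth: %.3f\n", acc))

expr_cls <- aggregate_to_class(calls$calls, world$class_map)
measured <- measured_pairs(world$metadata, "class", world$class_map)
inventory <- build_inventory(
  data.frame(tf = expr_cls$tf, sample = expr_cls$cell_type_class),
  measured,
  tf_universe = sort(rownames(world$expression)),
  sample_universe = sort(unique(world$class_map$cell_type_class)))
write.table(inventory, file.path("results", "inventory.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

uf <- unmeasured_fraction(inventory, "sample")
write.table(uf, file.path("results", "unmeasured_fraction.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("inventory: %d measured, %d unmeasured, %d not expressed\n",
            sum(inventory$status == "measured"),
            sum(inventory$status == "unmeasured"),
            sum(inventory$status == "not_expressed")))
cat("unmeasured fraction of expressed TFs per class:\n")
print(uf[, c("sample", "n_unmeasured", "n_expressed", "fraction")],
      row.names = FALSE)
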