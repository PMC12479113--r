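#!/usr/bin/env Rscript
# Quantify the inequality of experiment counts across TFs and cell types
# (Gini / Lorenz), contrast it with the counterfactual in which every
# expressed pair had been measured once, and measure the research-
# attention correlations (publications vs experiments; early vs late
# experiment counts).

library(tfcoverage)

world <- read_world(file.path("results", "world"))

tf_levels <- sort(rownames(world$expression))
ct_levels <- sort(unique(world$class_map$cell_type))
tf_counts <- as.numeric(table(factor(world$metadata$antigen, tf_levels)))
ct_counts <- as.numeric(table(factor(world$metadata$cell_type, ct_levels)))

g_tf <- gini(tf_counts)
g_ct <- gini(ct_counts)
calls <- call_expression(world$expression)$calls
idx <- which(calls == TRUE, arr.ind = TRUE)
g_cf <- counterfactual_gini(data.frame(tf = rownames(calls)[idx[, 1]],
                                       sample = colnames(calls)[idx[, 2]]))
cat(sprintf("gini of experiment counts: TFs %.3f, cell types %.3f\n",
            g_tf, g_ct))
cat(sprintf("counterfactual gini (all expressed pairs measured once): %.3f\n",
            g_cf))
cat("-> the gap between observed and counterfactual gini is the\n",
    "  inequality added by uneven research attention, not biology\n")

write.table(lorenz_curve(tf_counts), file.path("results", "lorenz_tf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lorenz_curve(ct_counts),
            file.path("results", "lorenz_cell_type.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

yrs <- as.integer(format(world$metadata$deposit_date, "%Y"))
split_year <- floor(mean(range(yrs)))
att <- attention_correlations(
  stats::setNames(tf_counts, tf_levels), world$publications,
  world$metadata, split_year)
cat(sprintf("spearman publications vs experiments: %.3f\n",
            att$publications_vs_experiments))
cat(sprintf("spearman experiments <=%d vs >%d (rich-get-richer): %.3f\n",
            split_year, split_year, att$early_vs_late))

write.table(data.frame(
  quantity = c("gini_tf", "gini_cell_type", "gini_tf_counterfactual",
               "spearman_publications_vs_experiments",
               "spearman_early_vs_late"),
  value = c(g_tf, g_ct, g_cf, att$publications_vs_experiments,
            att$early_vs_late)),
  file.path("results", "inequality.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
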