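#!/usr/bin/env Rscript
# Annual cover-ratio trajectories: per cell line, the fraction of its
# top-quartile expressed genes with a ChIP-seq peak within TSS +/- 500 bp
# (Reg-TF cover ratio); per cell-type class, the fraction of GWAS SNPs
# overlapping any peak (GWAS-SNP cover ratio). Both pool peaks
# cumulatively by deposit year.

library(tfcoverage)

world <- read_world(file.path("results", "world"))
yrs <- as.integer(format(world$metadata$deposit_date, "%Y"))
years <- seq(min(yrs), max(yrs))

top_lines <- names(sort(table(world$metadata$cell_type), decreasing = TRUE))
top_lines <- head(intersect(top_lines, colnames(world$expression)), 5)
reg <- do.call(rbind, lapply(top_lines, function(cl) {
  annual_series("reg_tf", cl, years, world$metadata, world$peaks,
                expression_vector = world$expression[, cl],
                tss = world$tss)
}))
write.table(reg, file.path("results", "cover_reg_tf.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

classes <- sort(unique(world$class_map$cell_type_class))
gwas <- do.call(rbind, lapply(classes, function(cl) {
  annual_series("gwas_snp", cl, years, world$metadata, world$peaks,
                snps = world$snps, level = "class",
                mapping = world$class_map)
}))
write.table(gwas, file.path("results", "cover_gwas_snp.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

final_reg <- reg[reg$year == max(years), ]
final_gwas <- gwas[gwas$year == max(years), ]
cat("final-year Reg-TF cover ratio (busiest cell lines):\n")
print(final_reg[, c("entity", "numerator", "denominator", "ratio")],
      row.names = FALSE)
cat("final-year GWAS-SNP cover ratio per class:\n")
print(final_gwas[, c("entity", "numerator", "denominator", "ratio")],
      row.names = FALSE)

# diversity relationship: one dot per (class, year)
div <- do.call(rbind, lapply(classes, function(cl) {
  ids <- world$metadata$cell_type_class[
    match(world$metadata$cell_type, world$class_map$cell_type)] == cl
  merge(cumulative_unique_tfs(world$metadata[ids, , drop = FALSE], years),
        cbind(gwas[gwas$entity == cl, c("year", "ratio")]), by = "year")
}))
rho <- cor(div$n_unique_tfs, div$ratio, method = "spearman")
cat(sprintf("spearman(unique measured TFs, GWAS cover ratio) over %d\n",
            nrow(div)))
cat(sprintf("  class-year points: %.3f\n", rho))
write.table(div, file.path("results", "diversity_vs_cover.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
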