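test_that("promoter windows follow the half-open +/- flank definition", {
  tss <- data.frame(chrom = "chr1", pos = c(1000, 100, 50), gene = c("G1", "G2", "G3"))
  w <- make_promoter_windows(tss, flank = 500)
  expect_equal(w$start[1], 499); expect_equal(w$end[1], 1500)
  expect_equal(w$end[1] - w$start[1], 1001)
  expect_equal(w$start[2], 0); expect_equal(w$end[2], 600)   # clipped
  w0 <- make_promoter_windows(tss[1, ], flank = 0)
  expect_equal(c(w0$start, w0$end), c(999, 1000))            # 1 bp
})

test_that("intersect_any uses half-open semantics and matches brute force", {
  q <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_true(intersect_any(q, data.frame(chrom = "chr1", start = 150,
                                          end = 160)))
  expect_false(intersect_any(q, data.frame(chrom = "chr1", start = 200,
                                           end = 300)))   # abutting
  expect_false(intersect_any(q, data.frame(chrom = "chr2", start = 150,
                                           end = 160)))   # other chrom
  expect_equal(intersect_any(q[0, ], q), logical(0))
  expect_false(intersect_any(q, q[0, ]))

  set.seed(61)
  queries <- random_intervals(150, max_pos = 400, max_len = 20)
  peaks <- random_intervals(150, max_pos = 400, max_len = 20)
  expect_equal(intersect_any(queries, peaks), oracle_overlap(queries, peaks))
})

test_that("top-quartile gene selection uses the ceiling and tie rules", {
  v <- stats::setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("G", 1:8))
  expect_equal(top_quartile_genes(v), c("G1", "G2"))
  v5 <- stats::setNames(c(5, 4, 3, 2, 1), paste0("G", 1:5))
  expect_equal(length(top_quartile_genes(v5)), 2)  # ceiling(1.25)
  # ties at the cut: deterministic by ascending symbol
  vt <- stats::setNames(c(9, 5, 5, 5, 1, 1, 1, 1), paste0("G", 8:1))
  expect_equal(top_quartile_genes(vt), top_quartile_genes(sample(vt)))
  expect_error(top_quartile_genes(c(a = 1, b = 2, c = 3)), "at least 4")
})

cover_fixture <- function() {
  # 8 genes; top quartile (2 genes) is covered in controlled ways
  tss <- data.frame(chrom = "chr1", pos = (1:8) * 10000,
                    gene = paste0("G", 1:8))
  meta <- data.frame(experiment_id = c("E1", "E2"),
                     antigen = c("TFA", "TFB"),
                     cell_type = "K", cell_type_class = "Blood",
                     deposit_date = as.Date(c("2015-06-01", "2018-06-01")),
                     stringsAsFactors = FALSE)
  list(tss = tss, meta = meta)
}

test_that("reg-TF cover ratio matches the hand fixture and formula", {
  # 4 expressed genes, 3 covered -> 0.75
  tss <- data.frame(chrom = "chr1", pos = c(1e4, 2e4, 3e4, 4e4),
                    gene = paste0("G", 1:4))
  extra <- data.frame(chrom = "chr1", pos = (5:16) * 1e4,
                      gene = paste0("G", 5:16))
  tss <- rbind(tss, extra)
  expr <- stats::setNames(c(100, 90, 80, 70, rep(1, 12)), tss$gene)
  meta <- data.frame(experiment_id = "E1", antigen = "TFA",
                     cell_type = "K", cell_type_class = "Blood",
                     deposit_date = as.Date("2015-06-01"))
  peaks <- list(E1 = data.frame(chrom = "chr1",
                                start = c(1e4, 2e4, 3e4), end = c(1e4, 2e4, 3e4) + 50))
  r <- reg_tf_cover_ratio(expr, tss, peaks, meta, "K", 2016)
  expect_equal(r$denominator, 4)
  expect_equal(r$numerator, 3)
  expect_equal(r$ratio, 0.75)

  # before any experiment: ratio 0
  r0 <- reg_tf_cover_ratio(expr, tss, peaks, meta, "K", 2014)
  expect_equal(r0$ratio, 0)
  expect_error(reg_tf_cover_ratio(expr, tss, peaks, meta, "ABSENT", 2016),
               "not present")
})

test_that("reg-TF ratio equals a naive gene-by-peak recomputation", {
  w <- generate_world(tiny_config(seed = 12, tss_enrichment = 0.7))
  cl <- names(which.max(table(w$metadata$cell_type)))
  r <- reg_tf_cover_ratio(w$expression[, cl], w$tss, w$peaks, w$metadata,
                          cl, 2018, flank = w$config$flank)
  # naive loop: pool peaks by hand, test each expressed gene's window
  ids <- w$metadata$experiment_id[
    w$metadata$cell_type == cl &
      as.integer(format(w$metadata$deposit_date, "%Y")) <= 2018]
  pooled <- do.call(rbind, lapply(w$peaks[ids],
                                  function(p) p[, c("chrom", "start", "end")]))
  expressed <- top_quartile_genes(w$expression[, cl])
  n_hit <- 0
  for (g in expressed) {
    trow <- w$tss[w$tss$gene == g, ]
    win <- data.frame(chrom = trow$chrom,
                      start = max(0, trow$pos - 1 - w$config$flank),
                      end = trow$pos + w$config$flank)
    if (!is.null(pooled) && nrow(pooled) > 0 &&
        any(pooled$chrom == win$chrom & pooled$start < win$end &
              win$start < pooled$end))
      n_hit <- n_hit + 1
  }
  expect_equal(r$numerator, n_hit)
  expect_equal(r$denominator, length(expressed))
})

test_that("GWAS-SNP cover ratio matches hand fixture and SNP-level oracle", {
  snps <- data.frame(rsid = paste0("rs", 1:10), chrom = "chr1",
                     pos = (1:10) * 1000, start = (1:10) * 1000 - 1,
                     end = (1:10) * 1000)
  meta <- data.frame(experiment_id = "E1", antigen = "TFA",
                     cell_type = "K", cell_type_class = "Blood",
                     deposit_date = as.Date("2015-06-01"))
  peaks <- list(E1 = data.frame(chrom = "chr1", start = c(999, 1999, 2999),
                                end = c(1000, 2000, 3000)))
  mapping <- data.frame(cell_type = "K", cell_type_class = "Blood")
  r <- gwas_snp_cover_ratio(snps, peaks, meta, "Blood", "class", 2016,
                            mapping)
  expect_equal(r$ratio, 0.3)
  expect_equal(gwas_snp_cover_ratio(snps, peaks, meta, "Blood", "class",
                                    2014, mapping)$ratio, 0)
  expect_error(gwas_snp_cover_ratio(snps[0, ], peaks, meta, "Blood",
                                    "class", 2016, mapping), "empty")

  # synthetic fixture equals the per-SNP brute-force oracle
  w <- generate_world(tiny_config(seed = 13))
  cls <- w$metadata$cell_type_class[1]
  r <- gwas_snp_cover_ratio(w$snps, w$peaks, w$metadata, cls, "class",
                            2017, w$class_map)
  ids <- w$metadata$experiment_id[
    w$metadata$cell_type_class == cls &
      as.integer(format(w$metadata$deposit_date, "%Y")) <= 2017]
  pooled <- do.call(rbind, lapply(w$peaks[ids],
                                  function(p) p[, c("chrom", "start", "end")]))
  naive <- sum(vapply(seq_len(nrow(w$snps)), function(i) {
    any(pooled$chrom == w$snps$chrom[i] & pooled$start < w$snps$end[i] &
          w$snps$start[i] < pooled$end)
  }, logical(1)))
  expect_equal(r$numerator, naive)
})

test_that("annual series are monotone, split-invariant, and replayable", {
  w <- generate_world(tiny_config(seed = 14))
  cls <- names(which.max(table(w$metadata$cell_type_class)))
  years <- 2012:2020
  s <- annual_series("gwas_snp", cls, years, w$metadata, w$peaks,
                     snps = w$snps, level = "class",
                     mapping = w$class_map)
  expect_true(all(diff(s$ratio) >= 0))
  expect_equal(s$ratio, s$numerator / s$denominator)

  # splitting one experiment's peak file into two halves changes nothing
  # (pool by intervals, not by files)
  id <- w$metadata$experiment_id[w$metadata$cell_type_class == cls][1]
  p <- w$peaks[[id]]
  half <- nrow(p) %/% 2
  peaks2 <- w$peaks
  peaks2[[id]] <- p[seq_len(half), ]
  extra_id <- "EXTRA1"
  peaks2[[extra_id]] <- p[(half + 1):nrow(p), ]
  meta2 <- rbind(w$metadata,
                 data.frame(experiment_id = extra_id, antigen = "TFX",
                            cell_type = w$metadata$cell_type[
                              w$metadata$experiment_id == id],
                            cell_type_class = cls,
                            deposit_date = w$metadata$deposit_date[
                              w$metadata$experiment_id == id]))
  s2 <- annual_series("gwas_snp", cls, years, meta2, peaks2,
                      snps = w$snps, level = "class", mapping = w$class_map)
  expect_equal(s2$ratio, s$ratio)

  # a no-op experiment leaves the series unchanged; a cover-all drives to 1
  peaks3 <- w$peaks
  peaks3[["NOOP"]] <- data.frame(chrom = "chrA", start = 0L, end = 1L)[0, ]
  meta3 <- rbind(w$metadata,
                 data.frame(experiment_id = "NOOP", antigen = "TFX",
                            cell_type = w$metadata$cell_type[1],
                            cell_type_class = cls,
                            deposit_date = as.Date("2013-01-01")))
  s3 <- annual_series("gwas_snp", cls, years, meta3, peaks3, snps = w$snps,
                      level = "class", mapping = w$class_map)
  expect_equal(s3$ratio, s$ratio)

  peaks4 <- peaks3
  peaks4[["NOOP"]] <- data.frame(chrom = names(w$config$genome),
                                 start = 0L,
                                 end = as.integer(w$config$genome))
  s4 <- annual_series("gwas_snp", cls, years, meta3, peaks4, snps = w$snps,
                      level = "class", mapping = w$class_map)
  expect_true(all(s4$ratio[years >= 2013] == 1))
})

test_that("fast hit-set series agrees with the direct per-year computation", {
  w <- generate_world(tiny_config(seed = 15))
  cls <- names(which.max(table(w$metadata$cell_type_class)))
  years <- 2012:2020
  direct <- annual_series("gwas_snp", cls, years, w$metadata, w$peaks,
                          snps = w$snps, level = "class",
                          mapping = w$class_map)
  ids <- w$metadata$experiment_id[w$metadata$cell_type_class == cls]
  hits <- snp_hits_by_experiment(w$snps, w$peaks[ids])
  ey <- stats::setNames(as.integer(format(w$metadata$deposit_date, "%Y")),
                        w$metadata$experiment_id)[ids]
  fast <- gwas_series_from_hits(hits, ey, years, nrow(w$snps))
  expect_equal(fast$ratio, direct$ratio)
  expect_equal(fast$numerator, direct$numerator)
})
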