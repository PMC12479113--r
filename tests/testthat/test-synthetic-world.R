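test_that("every generated artifact is deterministic under the seed", {
  w1 <- generate_world(tiny_config(seed = 5))
  w2 <- generate_world(tiny_config(seed = 5))
  expect_identical(w1$metadata, w2$metadata)
  expect_identical(w1$expression, w2$expression)
  expect_identical(w1$peaks, w2$peaks)
  expect_identical(w1$deg, w2$deg)
  expect_identical(w1$ground_truth, w2$ground_truth)
  w3 <- generate_world(tiny_config(seed = 6))
  expect_false(identical(w1$metadata, w3$metadata))
})

test_that("attachment strength controls the Gini of per-TF counts", {
  gini_at <- function(alpha, seed) {
    cfg <- world_config(n_tfs = 10, n_cell_types = 6, n_classes = 3,
                        n_experiments = 500, attachment_strength = alpha,
                        seed = seed)
    m <- generate_metadata(cfg)
    gini(as.numeric(table(factor(m$antigen, levels = sprintf("TF%03d", 1:10)))))
  }
  g0 <- vapply(1:20, function(s) gini_at(0, s), numeric(1))
  g5 <- vapply(1:20, function(s) gini_at(5, s), numeric(1))
  expect_lt(max(g0), 0.3)
  expect_gt(min(g5), 0.6)
  expect_true(all(g5 > g0))  # stochastically larger, seed by seed
})

test_that("expression mixture structure matches its ground truth", {
  # separated mixture: thresholding recovers the truth exactly
  cfg0 <- tiny_config(seed = 2, sigma = 1e-8)
  e0 <- generate_expression(cfg0)
  calls <- call_expression(e0$matrix)$calls
  expect_identical(unname(calls), unname(truth_matrix(e0)))

  # pi_expressed = 1: no low-component values anywhere
  cfg1 <- tiny_config(seed = 3, pi_expressed = 1, sigma = 0.3)
  e1 <- generate_expression(cfg1)
  expect_equal(nrow(e1$true_expressed),
               cfg1$n_tfs * cfg1$n_cell_types)
  expect_gt(min(e1$matrix), exp(cfg1$mu_low + 2))
})

test_that("peak placement honors the TSS enrichment fraction", {
  # single gene, full enrichment: every peak overlaps that promoter window
  cfg <- world_config(n_tfs = 1, n_cell_types = 2, n_classes = 1,
                      n_experiments = 5, pi_expressed = 1,
                      tss_enrichment = 1, peaks_per_experiment = 8,
                      genome = c(chr1 = 1e5), n_snps = 10, n_gems = 0,
                      seed = 4)
  w <- generate_world(cfg)
  windows <- make_promoter_windows(w$tss, flank = cfg$flank)
  for (p in w$peaks)
    expect_true(all(intersect_any(p[, c("chrom", "start", "end")], windows)))

  # zero enrichment: overlap fraction matches the uniform-placement
  # expectation (exact hit probability from the start-position geometry)
  cfg0 <- world_config(n_tfs = 6, n_cell_types = 4, n_classes = 2,
                       n_experiments = 40, tss_enrichment = 0,
                       peaks_per_experiment = 25,
                       genome = c(chr1 = 5e5), n_snps = 10, n_gems = 0,
                       seed = 9)
  w0 <- generate_world(cfg0)
  windows <- make_promoter_windows(w0$tss, flank = cfg0$flank)
  all_peaks <- do.call(rbind, lapply(w0$peaks,
                                     function(p) p[, c("chrom", "start", "end")]))
  hit <- intersect_any(all_peaks, windows)
  # a peak (width w) overlaps window [s, e) iff its start lies in
  # [s - w + 1, e - 1]; union those start-intervals for the exact p
  w_ <- cfg0$peak_width
  starts <- IRanges::reduce(IRanges::IRanges(
    pmax(0L, windows$start - w_ + 1L), windows$end - 1L))
  p_hit <- sum(IRanges::width(starts)) / (cfg0$genome[[1]] - w_)
  n <- nrow(all_peaks)
  expect_lt(abs(mean(hit) - p_hit), 3 * sqrt(p_hit * (1 - p_hit) / n))

  # no peaks at all: empty BEDs and zero cover ratio
  cfge <- tiny_config(seed = 5, peaks_per_experiment = 0)
  we <- generate_world(cfge)
  expect_true(all(vapply(we$peaks, nrow, integer(1)) == 0L))
  r <- gwas_snp_cover_ratio(we$snps, we$peaks, we$metadata,
                            we$metadata$cell_type_class[1], "class",
                            year = 2030, mapping = we$class_map)
  expect_equal(r$ratio, 0)
})

test_that("planted gems satisfy all four defining predicates", {
  w <- generate_world(tiny_config(seed = 7, n_gems = 2))
  gems <- w$ground_truth$planted_gems
  expect_equal(nrow(gems), 2)
  # marker
  expect_true(all(gems$tf %in% w$markers))
  # unmeasured at class level
  meas <- measured_pairs(w$metadata, "class", w$class_map)
  expect_false(any(paste(gems$tf, gems$cell_type_class) %in%
                     paste(meas$tf, meas$sample)))
  # expressed at class level (truth)
  te <- w$ground_truth$true_expressed
  te_cls <- unique(paste(te$tf, w$class_map$cell_type_class[
    match(te$cell_type, w$class_map$cell_type)]))
  expect_true(all(paste(gems$tf, gems$cell_type_class) %in% te_cls))
  # DEG strictly above the threshold
  key <- paste(w$deg$tf, w$deg$sample)
  for (i in seq_len(nrow(gems))) {
    nd <- max(w$deg$n_deg[key == paste(gems$tf[i], gems$cell_type_class[i])])
    expect_gt(nd, w$config$gem_deg_threshold)
  }
})

test_that("marker DEG shift is detectable and infeasible planting errors", {
  pvals <- vapply(1:50, function(s) {
    cfg <- world_config(n_tfs = 24, n_cell_types = 6, n_classes = 3,
                        n_experiments = 40, marker_delta = 3,
                        genome = c(chr1 = 1e5), n_snps = 10, seed = s)
    meta <- generate_metadata(cfg)
    expr <- generate_expression(cfg)
    dm <- generate_deg_and_markers(cfg, meta, expr$true_expressed,
                                   generate_class_map(cfg))
    compare_deg_groups(dm$deg, grouping = "marker_vs_nonmarker")$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.95)

  cfg_bad <- tiny_config(seed = 1, n_gems = 10000)
  meta <- generate_metadata(cfg_bad)
  expr <- generate_expression(cfg_bad)
  expect_error(generate_deg_and_markers(cfg_bad, meta, expr$true_expressed,
                                        generate_class_map(cfg_bad)),
               "infeasible")
})

test_that("written worlds round-trip through the readers", {
  w <- generate_world(tiny_config(seed = 8))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  meta <- read_experiment_table(file.path(dir, "metadata.tsv"))
  attr(meta, "report") <- NULL
  expect_equal(meta, w$metadata)
  expect_equal(read_expression_matrix(file.path(dir, "expression.tsv")),
               w$expression, tolerance = 1e-6)
  snps <- read_snp_table(file.path(dir, "snps.tsv"))
  expect_equal(snps, w$snps)
  bed <- read_bed(file.path(dir, "peaks",
                            paste0(w$metadata$experiment_id[1], ".bed")))
  expect_equal(bed, w$peaks[[w$metadata$experiment_id[1]]])
  manifest <- yaml::read_yaml(file.path(dir, "world.yaml"))
  expect_equal(manifest$seed, w$config$seed)
})
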