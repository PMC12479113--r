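meta_fixture <- function() {
  data.frame(experiment_id = c("E1", "E2", "E3"),
             antigen = c("A", "A", "B"),
             cell_type = c("X", "X", "Y"),
             cell_type_class = c("C1", "C1", "C2"),
             deposit_date = as.Date(c("2015-01-01", "2016-01-01",
                                      "2017-01-01")),
             stringsAsFactors = FALSE)
}

test_that("measured_pairs counts multiplicity and matches brute force", {
  mp <- measured_pairs(meta_fixture(), "cell_type")
  expect_equal(mp$n_experiments[mp$tf == "A" & mp$sample == "X"], 2L)
  expect_equal(nrow(mp), 2)

  empty <- meta_fixture()[0, ]
  expect_equal(nrow(measured_pairs(empty, "cell_type")), 0)

  mapping <- data.frame(cell_type = c("X", "Y"),
                        cell_type_class = c("C1", "C2"))
  expect_error(measured_pairs(meta_fixture(), "class",
                              mapping[1, , drop = FALSE]),
               "missing from class map")

  set.seed(5)
  meta <- generate_metadata(tiny_config(seed = 5))
  mp <- measured_pairs(meta, "cell_type")
  for (r in sample(nrow(mp), 10)) {
    naive <- sum(meta$antigen == mp$tf[r] & meta$cell_type == mp$sample[r])
    expect_equal(mp$n_experiments[r], naive)
  }
  expect_equal(sum(mp$n_experiments), nrow(meta))
})

test_that("inventory statuses follow the definition and partition the universe", {
  expressed <- data.frame(tf = c("A", "B"), sample = c("X", "X"))
  measured <- data.frame(tf = "A", sample = "X", n_experiments = 1L)
  inv <- build_inventory(expressed, measured,
                         tf_universe = c("A", "B", "C"),
                         sample_universe = c("X", "Y"))
  expect_equal(nrow(inv), 6)
  get <- function(tf, s) inv$status[inv$tf == tf & inv$sample == s]
  expect_equal(get("B", "X"), "unmeasured")
  expect_equal(get("A", "X"), "measured")
  expect_equal(get("C", "X"), "not_expressed")
  expect_equal(sum(table(inv$status)), 6)  # statuses partition

  # measured-but-not-expressed stays measured, never unmeasured
  measured2 <- rbind(measured, data.frame(tf = "C", sample = "X",
                                          n_experiments = 1L))
  inv2 <- build_inventory(expressed, measured2,
                          tf_universe = c("A", "B", "C"),
                          sample_universe = c("X", "Y"))
  expect_equal(inv2$status[inv2$tf == "C" & inv2$sample == "X"], "measured")

  # measured pairs outside the universe surface separately
  measured3 <- rbind(measured, data.frame(tf = "Z", sample = "X",
                                          n_experiments = 1L))
  inv3 <- build_inventory(expressed, measured3,
                          tf_universe = c("A", "B"),
                          sample_universe = c("X", "Y"))
  expect_equal(attr(inv3, "outside_universe")$tf, "Z")
})

test_that("unmeasured fraction reports undefined groups as NA", {
  expressed <- data.frame(tf = c("A", "B", "C", "D"),
                          sample = rep("X", 4))
  measured <- data.frame(tf = "A", sample = "X", n_experiments = 1L)
  inv <- build_inventory(expressed, measured,
                         tf_universe = LETTERS[1:4],
                         sample_universe = c("X", "Y"))
  uf <- unmeasured_fraction(inv, "sample")
  expect_equal(uf$fraction[uf$sample == "X"], 0.75)
  expect_true(is.na(uf$fraction[uf$sample == "Y"]))
  expect_false(uf$defined[uf$sample == "Y"])
})

test_that("gini reproduces hand values and the pairwise-difference oracle", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)
  expect_error(gini(c(0, 0)), "all-zero")

  set.seed(14)
  for (i in 1:50) {
    x <- rpois(sample(2:40, 1), sample(1:20, 1))
    if (all(x == 0)) x[1] <- 1
    g <- gini(x)
    expect_equal(g, oracle_gini(x), tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / length(x) + 1e-12)
    expect_equal(gini(x * 7.3), g)  # scale invariance
  }
})

test_that("lorenz curve is a valid curve and integrates back to gini", {
  expect_equal(lorenz_curve(c(1, 1)),
               data.frame(p = c(0, 0.5, 1), L = c(0, 0.5, 1)))
  expect_equal(lorenz_curve(c(0, 1)),
               data.frame(p = c(0, 0.5, 1), L = c(0, 0, 1)))
  set.seed(15)
  for (i in 1:25) {
    x <- rlnorm(sample(2:50, 1), 2, 1)
    lc <- lorenz_curve(x)
    expect_equal(lc$p[1], 0); expect_equal(lc$L[1], 0)
    expect_equal(lc$p[nrow(lc)], 1); expect_equal(lc$L[nrow(lc)], 1)
    expect_true(all(diff(lc$L) >= 0))
    expect_true(all(diff(diff(lc$L)) >= -1e-12))  # convex
    auc <- sum(diff(lc$p) * (utils::head(lc$L, -1) + utils::tail(lc$L, -1)) / 2)
    expect_equal(1 - 2 * auc, gini(x), tolerance = 1e-9)
  }
})

test_that("counterfactual gini reflects expression breadth only", {
  all_pairs <- expand.grid(tf = LETTERS[1:5], sample = letters[1:4],
                           stringsAsFactors = FALSE)
  expect_equal(counterfactual_gini(all_pairs), 0)

  pairs <- data.frame(tf = c("A", "B", "C", rep("D", 5)),
                      sample = c("x", "x", "x", paste0("s", 1:5)))
  expect_equal(counterfactual_gini(pairs), 0.375)  # gini([1,1,1,5])
  expect_error(counterfactual_gini(pairs[0, ]), "nonempty")

  # skewed attention inflates observed gini above the counterfactual
  worse <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = s, attachment_strength = 3)
    meta <- generate_metadata(cfg)
    expr <- generate_expression(cfg)
    obs <- gini(as.numeric(table(factor(meta$antigen,
                                        levels = rownames(expr$matrix)))))
    cf <- counterfactual_gini(data.frame(tf = expr$true_expressed$tf,
                                         sample = expr$true_expressed$cell_type))
    cf < obs
  }, logical(1))
  expect_true(all(worse))
})

test_that("attention correlations equal Pearson on average ranks", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  meta <- data.frame(experiment_id = paste0("E", 1:6),
                     antigen = c("A", "A", "B", "B", "C", "C"),
                     cell_type = "X", cell_type_class = "C1",
                     deposit_date = as.Date(c("2010-01-01", "2011-06-01",
                                              "2012-01-01", "2013-01-01",
                                              "2014-01-01", "2015-01-01")))
  counts <- c(A = 3, B = 2, C = 1)
  pubs <- c(A = 30, B = 20, C = 10)
  att <- attention_correlations(counts, pubs, meta, split_year = 2012)
  expect_equal(att$publications_vs_experiments, 1)
  rev_pubs <- c(A = 1, B = 2, C = 3)
  expect_equal(attention_correlations(counts, rev_pubs, meta,
                                      2012)$publications_vs_experiments, -1)

  # tie handling: early/late correlation equals Pearson on average ranks
  set.seed(31)
  meta2 <- data.frame(experiment_id = paste0("E", 1:40),
                      antigen = sample(LETTERS[1:6], 40, TRUE),
                      cell_type = "X", cell_type_class = "C1",
                      deposit_date = as.Date("2008-06-01") +
                        sample(0:3650, 40, TRUE))
  counts2 <- table(meta2$antigen)
  pubs2 <- stats::setNames(sample(5, length(counts2), TRUE), names(counts2))
  att2 <- attention_correlations(
    stats::setNames(as.numeric(counts2), names(counts2)), pubs2, meta2, 2012)
  yr2 <- as.integer(format(meta2$deposit_date, "%Y"))
  tfs2 <- sort(unique(meta2$antigen))
  early <- vapply(tfs2, function(t) sum(meta2$antigen == t & yr2 <= 2012),
                  numeric(1))
  late <- vapply(tfs2, function(t) sum(meta2$antigen == t & yr2 > 2012),
                 numeric(1))
  expect_equal(att2$early_vs_late, stats::cor(rank(early), rank(late)))
  expect_equal(att2$publications_vs_experiments,
               stats::cor(rank(pubs2[tfs2]),
                          rank(as.numeric(counts2[tfs2]))))

  expect_error(attention_correlations(counts[1:2], pubs[1:2], meta, 2012),
               "at least 3")
})
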