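#' Wilcoxon rank-sum test with an explicit exact/approximate policy
#'
#' Thin policy wrapper around [stats::wilcox.test()]: the exact
#' distribution (full enumeration of rank assignments) is used when
#' `n + m <= 12` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used. When the
#' statistic equals its null expectation the two-sided p is reported as 1
#' (the symmetric-null value; a blind continuity correction would report
#' slightly less).
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x below y) or `"greater"`.
#' @return List `statistic` (Mann-Whitney U of `x`), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  p <- wt$p.value
  mu <- length(x) * length(y) / 2
  if (!use_exact && alternative == "two.sided" &&
      unname(wt$statistic) == mu)
    p <- 1
  list(statistic = unname(wt$statistic), p = p, exact = use_exact)
}

#' Compare knockout DEG counts between pair categories
#'
#' Joins the DEG table to the coverage inventory on (TF, sample) and runs a
#' two-sided Wilcoxon rank-sum test on `n_deg` between either marker vs
#' non-marker TFs or measured vs unmeasured pairs. Rows that fail the join
#' are counted, not silently dropped. No multiple-testing correction is
#' applied: each call is a single planned comparison.
#'
#' @param deg_table Data frame `tf`, `sample`, `n_deg` and (for the marker
#'   grouping) `is_marker`.
#' @param inventory Inventory from [build_inventory()] at the same sample
#'   level (needed for the measured/unmeasured grouping).
#' @param grouping `"marker_vs_nonmarker"` or `"measured_vs_unmeasured"`.
#' @return List `grouping`, `n` (group sizes), `medians`, `statistic`,
#'   `p`, `n_unjoined`.
#' @export
compare_deg_groups <- function(deg_table, inventory = NULL,
                               grouping = c("marker_vs_nonmarker",
                                            "measured_vs_unmeasured")) {
  grouping <- match.arg(grouping)
  if (grouping == "marker_vs_nonmarker") {
    stopifnot("is_marker" %in% names(deg_table))
    g1 <- deg_table$n_deg[deg_table$is_marker]
    g2 <- deg_table$n_deg[!deg_table$is_marker]
    labels <- c("marker", "nonmarker")
    n_unjoined <- 0L
  } else {
    stopifnot(!is.null(inventory))
    key <- paste(deg_table$tf, deg_table$sample, sep = "\r")
    ikey <- paste(inventory$tf, inventory$sample, sep = "\r")
    status <- inventory$status[match(key, ikey)]
    n_unjoined <- sum(is.na(status))
    g1 <- deg_table$n_deg[status %in% "measured"]
    g2 <- deg_table$n_deg[status %in% "unmeasured"]
    labels <- c("measured", "unmeasured")
  }
  if (length(g1) == 0L) stop("group '", labels[1], "' has no members")
  if (length(g2) == 0L) stop("group '", labels[2], "' has no members")
  wt <- wilcoxon_rank_sum(g1, g2, alternative = "two.sided")
  list(grouping = grouping,
       n = stats::setNames(c(length(g1), length(g2)), labels),
       medians = stats::setNames(c(stats::median(g1), stats::median(g2)),
                                 labels),
       statistic = wt$statistic, p = wt$p, n_unjoined = n_unjoined)
}

#' Hidden gems: unmeasured, high-impact, marker TF-sample pairs
#'
#' Filters the coverage inventory for pairs worth prioritizing in future
#' ChIP-seq experiments: status unmeasured, knockout DEG count strictly
#' above `deg_threshold`, and the TF annotated as a cell-type/tissue
#' marker. When several knockout experiments exist for one (TF, sample)
#' pair, the maximum DEG count is used by default (most permissive evidence
#' of regulatory impact); mean aggregation is available.
#'
#' @param inventory Inventory from [build_inventory()].
#' @param deg_table Data frame `tf`, `sample`, `n_deg`.
#' @param markers Character vector of marker TF symbols.
#' @param deg_threshold DEG count a gem must strictly exceed (default
#'   1000).
#' @param aggregate `"max"` (default) or `"mean"` across multiple knockout
#'   records of the same pair.
#' @return Data frame audit of every (TF, sample) pair with a DEG record:
#'   `tf`, `sample`, `n_deg` (aggregated), `unmeasured`, `above_threshold`,
#'   `marker`, `gem` (the conjunction). Gems are the `gem == TRUE` rows.
#' @export
hidden_gems <- function(inventory, deg_table, markers,
                        deg_threshold = 1000,
                        aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "max") max else mean
  agg <- stats::aggregate(list(n_deg = deg_table$n_deg),
                          by = list(tf = deg_table$tf,
                                    sample = deg_table$sample),
                          FUN = agg_fun)
  ikey <- paste(inventory$tf, inventory$sample, sep = "\r")
  akey <- paste(agg$tf, agg$sample, sep = "\r")
  status <- inventory$status[match(akey, ikey)]
  agg$unmeasured <- status %in% "unmeasured"
  agg$above_threshold <- agg$n_deg > deg_threshold
  agg$marker <- agg$tf %in% markers
  agg$gem <- agg$unmeasured & agg$above_threshold & agg$marker
  agg <- agg[order(agg$tf, agg$sample), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
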