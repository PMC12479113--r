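#' Measured TF-sample pairs from experiment metadata
#'
#' @param metadata Experiment table ([read_experiment_table()]).
#' @param level `"cell_type"` (sample = cell line/type) or `"class"`
#'   (sample = cell-type class via `mapping`).
#' @param mapping Cell-type to class map, required at class level; every
#'   cell type appearing in `metadata` must map.
#' @return Data frame `tf`, `sample`, `n_experiments` — one row per pair
#'   with at least one experiment, with its multiplicity.
#' @export
measured_pairs <- function(metadata, level = c("cell_type", "class"),
                           mapping = NULL) {
  level <- match.arg(level)
  if (nrow(metadata) == 0L)
    return(data.frame(tf = character(), sample = character(),
                      n_experiments = integer(), stringsAsFactors = FALSE))
  sample_ <- if (level == "cell_type") {
    metadata$cell_type
  } else {
    if (is.null(mapping))
      stop("class level requires a cell-type to class mapping")
    unmapped <- setdiff(metadata$cell_type, mapping$cell_type)
    if (length(unmapped) > 0L)
      stop("cell types missing from class map: ",
           paste(unmapped, collapse = ", "))
    mapping$cell_type_class[match(metadata$cell_type, mapping$cell_type)]
  }
  agg <- stats::aggregate(list(n_experiments = metadata$experiment_id),
                          by = list(tf = metadata$antigen, sample = sample_),
                          FUN = length)
  agg <- agg[order(agg$tf, agg$sample), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Build the measured/unmeasured/not-expressed inventory
#'
#' The central audit object: every (TF, sample) pair of the configured pair
#' universe receives one status. A pair is `unmeasured` when the TF is
#' expressed in the sample but no ChIP-seq experiment exists for the pair;
#' `measured` whenever an experiment exists (regardless of the expression
#' call); `not_expressed` otherwise. The universe is the cross of the TFs
#' with an expression call and the supplied sample universe; measured pairs
#' outside that universe (e.g. TFs never assayed by RNA-seq) are returned
#' separately, not forced into a status.
#'
#' @param expressed_pairs Data frame `tf`, `sample` of expressed pairs.
#' @param measured Data frame from [measured_pairs()] at the same level.
#' @param tf_universe,sample_universe Character vectors defining the pair
#'   universe (default: all TFs/samples seen in `expressed_pairs`).
#' @param level Label recorded on the result (`"cell_type"` or `"class"`).
#' @return Data frame `tf`, `sample`, `expressed`, `measured`, `status`
#'   covering the full universe, with attribute `outside_universe` listing
#'   measured pairs not in the universe and attribute `level`.
#' @export
build_inventory <- function(expressed_pairs, measured,
                            tf_universe = NULL, sample_universe = NULL,
                            level = "class") {
  if (is.null(tf_universe)) tf_universe <- sort(unique(expressed_pairs$tf))
  if (is.null(sample_universe))
    sample_universe <- sort(unique(expressed_pairs$sample))
  inv <- expand.grid(tf = tf_universe, sample = sample_universe,
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  inv <- inv[order(inv$tf, inv$sample), , drop = FALSE]
  rownames(inv) <- NULL
  key <- function(tf, s) paste(tf, s, sep = "\r")
  inv$expressed <- key(inv$tf, inv$sample) %in%
    key(expressed_pairs$tf, expressed_pairs$sample)
  inv$measured <- key(inv$tf, inv$sample) %in%
    key(measured$tf, measured$sample)
  inv$status <- ifelse(inv$measured, "measured",
                       ifelse(inv$expressed, "unmeasured", "not_expressed"))
  outside <- measured[!(key(measured$tf, measured$sample) %in%
                          key(inv$tf, inv$sample)), , drop = FALSE]
  attr(inv, "outside_universe") <- outside
  attr(inv, "level") <- level
  inv
}

#' Fraction of expressed TFs that remain unmeasured, per group
#'
#' @param inventory Inventory from [build_inventory()].
#' @param group_by Grouping column(s): `"sample"` and/or `"tf"`.
#' @return Data frame with `n_unmeasured`, `n_expressed` and `fraction`
#'   (= unmeasured / expressed) per group; groups with zero expressed pairs
#'   get `fraction = NA` and `defined = FALSE` rather than 0.
#' @export
unmeasured_fraction <- function(inventory, group_by = "sample") {
  stopifnot(all(group_by %in% c("sample", "tf")))
  sp <- split(inventory, inventory[, group_by, drop = FALSE], drop = FALSE)
  rows <- lapply(names(sp), function(g) {
    d <- sp[[g]]
    n_exp <- sum(d$expressed)
    n_unm <- sum(d$status == "unmeasured")
    data.frame(group = g, n_unmeasured = n_unm, n_expressed = n_exp,
               fraction = if (n_exp > 0) n_unm / n_exp else NA_real_,
               defined = n_exp > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- paste(group_by, collapse = ".")
  rownames(out) <- NULL
  out
}

#' Gini coefficient of a count vector
#'
#' Mean-absolute-difference definition
#' `G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`, computed via the
#' equivalent sorted form. Zeros count: entities in the universe with no
#' experiments contribute to the inequality they embody.
#'
#' @param counts Nonnegative numeric vector, `n >= 1`, not all zero.
#' @return Gini coefficient in `[0, 1 - 1/n]`.
#' @examples
#' gini(c(1, 1, 1, 1))  # 0
#' gini(c(0, 0, 0, 1))  # 0.75
#' @export
gini <- function(counts) {
  stopifnot(length(counts) >= 1, all(is.finite(counts)), all(counts >= 0))
  if (all(counts == 0)) stop("gini undefined for an all-zero vector")
  x <- sort(counts)
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Lorenz curve of a count vector
#'
#' Entities sorted ascending by count; cumulative shares on both axes,
#' including the (0, 0) origin. Twice the area between the diagonal and the
#' curve (trapezoidal) equals [gini()] exactly.
#'
#' @param counts As in [gini()].
#' @return Data frame `p` (cumulative entity share), `L` (cumulative count
#'   share), both from 0 to 1.
#' @export
lorenz_curve <- function(counts) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (all(counts == 0)) stop("Lorenz curve undefined for an all-zero vector")
  x <- sort(counts)
  n <- length(x)
  data.frame(p = c(0, seq_len(n) / n), L = c(0, cumsum(x) / sum(x)))
}

#' Counterfactual Gini under complete coverage of expressed pairs
#'
#' Supposes every expressed (TF, sample) pair had been measured exactly
#' once; the per-TF experiment count then equals the number of samples the
#' TF is expressed in. The Gini of those counts isolates the inequality
#' intrinsic to expression breadth from the inequality added by uneven
#' research attention.
#'
#' @param expressed_pairs Data frame `tf`, `sample` (nonempty).
#' @return Gini coefficient of the hypothetical per-TF counts.
#' @export
counterfactual_gini <- function(expressed_pairs) {
  if (nrow(expressed_pairs) == 0L)
    stop("counterfactual_gini requires a nonempty expressed set")
  counts <- table(expressed_pairs$tf)
  gini(as.numeric(counts))
}

#' Research-attention rank correlations
#'
#' Two Spearman correlations over TFs: (i) publication counts vs total
#' ChIP-seq experiment counts (attention tracks data accrual) and (ii)
#' experiment counts dated up to `split_year` vs those dated from
#' `split_year + 1` (the rich-get-richer signature). Spearman is computed
#' as Pearson on average ranks, exact under ties.
#'
#' @param experiment_counts Named numeric vector: total experiments per TF.
#' @param publication_counts Named numeric vector: publications per TF.
#' @param metadata Experiment table, used for the temporal split.
#' @param split_year Integer year; early period is `<= split_year`.
#' @return List `publications_vs_experiments`, `early_vs_late`, and the
#'   underlying aligned tables.
#' @export
attention_correlations <- function(experiment_counts, publication_counts,
                                   metadata, split_year) {
  tfs <- intersect(names(experiment_counts), names(publication_counts))
  if (length(tfs) < 3L)
    stop("need at least 3 TFs aligned across both count vectors")
  rho_pub <- stats::cor(publication_counts[tfs], experiment_counts[tfs],
                        method = "spearman")
  yr <- as.integer(format(as.Date(metadata$deposit_date), "%Y"))
  stopifnot(split_year >= min(yr), split_year < max(yr))
  all_tfs <- sort(unique(metadata$antigen))
  early <- table(factor(metadata$antigen[yr <= split_year], levels = all_tfs))
  late <- table(factor(metadata$antigen[yr > split_year], levels = all_tfs))
  rho_time <- stats::cor(as.numeric(early), as.numeric(late),
                         method = "spearman")
  list(publications_vs_experiments = rho_pub,
       early_vs_late = rho_time,
       table = data.frame(tf = all_tfs, early = as.numeric(early),
                          late = as.numeric(late), stringsAsFactors = FALSE))
}
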