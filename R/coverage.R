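#' Convert 0-based half-open intervals to GRanges
#' @noRd
.as_granges <- function(df) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

#' Promoter windows around transcription start sites
#'
#' Extends each TSS symmetrically by `flank` bp (strand ignored). For a
#' 1-based TSS position `t` the window is the 0-based half-open interval
#' `[max(0, t - 1 - flank), t + flank)`: `2*flank + 1` bases except where
#' clipped at the chromosome start.
#'
#' @param tss Data frame with `chrom`, `pos` (1-based TSS position) and
#'   `gene` (symbol).
#' @param flank Flank size in bp (default 500, i.e. TSS +/- 500 bp).
#' @return Data frame `chrom`, `start`, `end`, `gene` (0-based half-open).
#' @export
make_promoter_windows <- function(tss, flank = 500L) {
  stopifnot(flank >= 0, all(tss$pos >= 1))
  data.frame(chrom = tss$chrom,
             start = pmax(0L, as.integer(tss$pos) - 1L - as.integer(flank)),
             end = as.integer(tss$pos) + as.integer(flank),
             gene = tss$gene,
             stringsAsFactors = FALSE)
}

#' Any-overlap test between query intervals and peaks
#'
#' Half-open semantics: intervals overlap iff they share at least one base
#' (`q.start < p.end` and `p.start < q.end` on the same chromosome);
#' abutting intervals do not overlap.
#'
#' @param queries,peaks Data frames `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Logical vector, one entry per query.
#' @export
intersect_any <- function(queries, peaks) {
  if (nrow(queries) == 0L) return(logical(0))
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(queries)))
  # disjoint chromosome sets are a legitimate all-FALSE, not a warning
  suppressWarnings(
    IRanges::overlapsAny(.as_granges(queries), .as_granges(peaks)))
}

#' Top-quartile expressed genes of a cell line
#'
#' "Expressed" for the regulatory-TF cover ratio means the top 25% most
#' highly expressed genes of the cell line: genes ranked descending by
#' value with ties broken by ascending symbol, keeping the first
#' `ceiling(0.25 * n)`.
#'
#' @param expression_vector Named numeric vector (names = gene symbols);
#'   `NA` entries are dropped; at least 4 genes required.
#' @return Character vector of expressed gene symbols.
#' @export
top_quartile_genes <- function(expression_vector) {
  v <- expression_vector[!is.na(expression_vector)]
  if (length(v) < 4L)
    stop("top_quartile_genes requires at least 4 genes with values")
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(ceiling(0.25 * length(v)))]
}

#' Pool peaks of an entity's experiments up to a target year
#' @noRd
.pooled_peaks <- function(peaks_by_experiment, metadata, entity, level,
                          year, mapping = NULL) {
  sample_ <- if (level == "cell_type") {
    metadata$cell_type
  } else {
    if (is.null(mapping))
      stop("class level requires a cell-type to class mapping")
    mapping$cell_type_class[match(metadata$cell_type, mapping$cell_type)]
  }
  yr <- as.integer(format(as.Date(metadata$deposit_date), "%Y"))
  ids <- metadata$experiment_id[sample_ == entity & yr <= year]
  ids <- intersect(ids, names(peaks_by_experiment))
  if (length(ids) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(peaks_by_experiment[ids],
                        function(p) p[, c("chrom", "start", "end")]))
}

#' Regulatory-TF cover ratio of a cell line at a target year
#'
#' Fraction of the cell line's expressed genes (top 25% by expression)
#' whose promoter window (TSS +/- `flank` bp) overlaps at least one ChIP-seq
#' peak from that cell line's experiments deposited up to and including the
#' target year:
#' `ratio = n(expressed genes with any peak in window) / n(expressed genes)`.
#'
#' @param expression_vector Named numeric vector of the cell line's gene
#'   expression values.
#' @param tss TSS table (`chrom`, `pos`, `gene`).
#' @param peaks_by_experiment Named list of peak BED data frames, one per
#'   experiment ID.
#' @param metadata Experiment table.
#' @param cell_line Cell line name (must appear in `metadata$cell_type`).
#' @param year Target year (deposits with year `<= year` count).
#' @param flank Promoter flank in bp.
#' @return List `ratio`, `numerator`, `denominator`, `expressed_genes`.
#' @export
reg_tf_cover_ratio <- function(expression_vector, tss, peaks_by_experiment,
                               metadata, cell_line, year, flank = 500L) {
  if (!cell_line %in% metadata$cell_type)
    stop("cell line not present in metadata: ", cell_line)
  expressed <- top_quartile_genes(expression_vector)
  if (length(expressed) == 0L) stop("zero expressed genes")
  windows <- make_promoter_windows(tss[tss$gene %in% expressed, , drop = FALSE],
                                   flank = flank)
  pooled <- .pooled_peaks(peaks_by_experiment, metadata, cell_line,
                          "cell_type", year)
  hit_genes <- unique(windows$gene[intersect_any(windows, pooled)])
  list(ratio = length(hit_genes) / length(expressed),
       numerator = length(hit_genes),
       denominator = length(expressed),
       expressed_genes = expressed)
}

#' GWAS-SNP cover ratio of an entity at a target year
#'
#' Fraction of all GWAS SNPs (1-bp half-open intervals) overlapping at
#' least one ChIP-seq peak from the entity's experiments deposited up to
#' and including the target year. The denominator is the full de-duplicated
#' SNP table.
#'
#' @param snps SNP table from [read_snp_table()] (or any data frame with
#'   `rsid`, `chrom`, `start`, `end`).
#' @param peaks_by_experiment Named list of peak data frames per experiment.
#' @param metadata Experiment table.
#' @param entity Cell type or class label.
#' @param level `"cell_type"` or `"class"`; the published statistic is per
#'   cell-type class.
#' @param year Target year.
#' @param mapping Cell-type to class map (class level only).
#' @return List `ratio`, `numerator`, `denominator`.
#' @export
gwas_snp_cover_ratio <- function(snps, peaks_by_experiment, metadata,
                                 entity, level = c("class", "cell_type"),
                                 year, mapping = NULL) {
  level <- match.arg(level)
  if (nrow(snps) == 0L) stop("empty SNP table")
  snps <- snps[!duplicated(snps$rsid), , drop = FALSE]
  pooled <- .pooled_peaks(peaks_by_experiment, metadata, entity, level,
                          year, mapping)
  num <- sum(intersect_any(snps[, c("chrom", "start", "end")], pooled))
  list(ratio = num / nrow(snps), numerator = num, denominator = nrow(snps))
}

#' Per-experiment SNP hit sets
#'
#' Precomputes, for each experiment, the indices of SNPs its peaks overlap.
#' Annual trajectories over many shuffled acquisition orders then reduce to
#' cumulative unions of these index sets, avoiding repeated interval work.
#'
#' @param snps De-duplicated SNP table.
#' @param peaks_by_experiment Named list of peak data frames.
#' @return Named list (per experiment ID) of integer SNP indices.
#' @export
snp_hits_by_experiment <- function(snps, peaks_by_experiment) {
  snps <- snps[!duplicated(snps$rsid), , drop = FALSE]
  sgr <- .as_granges(snps[, c("chrom", "start", "end")])
  lapply(peaks_by_experiment, function(p) {
    if (nrow(p) == 0L) return(integer(0))
    which(IRanges::overlapsAny(sgr, .as_granges(p)))
  })
}

#' Annual cover-ratio series for one entity
#'
#' One ratio per year over an inclusive year range, with cumulative peak
#' pooling (deposit year `<=` target year), so the series is monotone
#' nondecreasing. Numerators and denominators are retained for audit.
#'
#' @param statistic `"reg_tf"` or `"gwas_snp"`.
#' @param entity Cell line (`reg_tf`; also `gwas_snp` at cell_type level)
#'   or class label.
#' @param years Integer vector of target years (ascending).
#' @param metadata Experiment table.
#' @param peaks_by_experiment Named list of peak data frames.
#' @param snps SNP table (`gwas_snp` only).
#' @param expression_vector,tss,flank Reg-TF inputs (see
#'   [reg_tf_cover_ratio()]).
#' @param level,mapping Entity level and class map (`gwas_snp`).
#' @return Data frame `entity`, `statistic`, `year`, `numerator`,
#'   `denominator`, `ratio`.
#' @export
annual_series <- function(statistic = c("reg_tf", "gwas_snp"), entity, years,
                          metadata, peaks_by_experiment, snps = NULL,
                          expression_vector = NULL, tss = NULL, flank = 500L,
                          level = "class", mapping = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(years) >= 1, !is.unsorted(years))
  rows <- lapply(years, function(y) {
    r <- if (statistic == "reg_tf") {
      reg_tf_cover_ratio(expression_vector, tss, peaks_by_experiment,
                         metadata, entity, y, flank)
    } else {
      gwas_snp_cover_ratio(snps, peaks_by_experiment, metadata, entity,
                           level, y, mapping)
    }
    data.frame(entity = entity, statistic = statistic, year = y,
               numerator = r$numerator, denominator = r$denominator,
               ratio = r$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fast annual GWAS series from precomputed hit sets
#'
#' Equivalent to [annual_series()] with `statistic = "gwas_snp"` but driven
#' by [snp_hits_by_experiment()] output; used by the acquisition-order
#' simulation where thousands of trajectories are needed.
#'
#' @param hits Named list of SNP index sets per experiment.
#' @param experiment_years Named integer vector: deposit year per
#'   experiment ID (same ID namespace as `hits`).
#' @param years Ascending target years.
#' @param n_snps Denominator (size of the de-duplicated SNP table).
#' @param experiment_ids Optional subset of experiments to include.
#' @return Data frame `year`, `numerator`, `denominator`, `ratio`.
#' @export
gwas_series_from_hits <- function(hits, experiment_years, years, n_snps,
                                  experiment_ids = names(hits)) {
  stopifnot(!is.unsorted(years))
  ids <- intersect(experiment_ids, names(hits))
  yrs <- experiment_years[ids]
  covered <- logical(n_snps)
  num <- integer(length(years))
  ord <- ids[order(yrs)]
  pos <- 1L
  yrs_sorted <- sort(yrs)
  for (k in seq_along(years)) {
    while (pos <= length(ord) && yrs_sorted[pos] <= years[k]) {
      covered[hits[[ord[pos]]]] <- TRUE
      pos <- pos + 1L
    }
    num[k] <- sum(covered)
  }
  data.frame(year = years, numerator = num, denominator = n_snps,
             ratio = num / n_snps)
}
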