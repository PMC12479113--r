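#' Read a ChIP-seq experiment metadata table
#'
#' Reads a tab-separated metadata table in the style of ChIP-Atlas
#' `experimentList.tab` (one row per experiment) into a validated data frame.
#' Column names differ between compendia (ChIP-Atlas, GTRD, ReMap), so the
#' mapping from the canonical fields to the file's headers is supplied by the
#' caller rather than hard-coded.
#'
#' Rows whose deposit date cannot be parsed, or whose parsed year falls
#' outside `[min_year, max_year]`, are dropped and enumerated in the attached
#' load report; dropped + kept always equals the input row count.
#'
#' @param path Path to a TSV file with a header row.
#' @param columns Named character vector mapping the canonical field names
#'   `experiment_id`, `antigen`, `cell_type`, `cell_type_class`,
#'   `deposit_date` to the file's column headers. Defaults to the identity
#'   mapping.
#' @param min_year,max_year Inclusive bounds on the deposit year; rows
#'   outside are dropped and reported.
#' @return A data frame with columns `experiment_id`, `antigen`, `cell_type`,
#'   `cell_type_class`, `deposit_date` (class `Date`), with attribute
#'   `report`: a data frame enumerating every dropped row and the reason.
#' @export
read_experiment_table <- function(path,
                                  columns = c(experiment_id = "experiment_id",
                                              antigen = "antigen",
                                              cell_type = "cell_type",
                                              cell_type_class = "cell_type_class",
                                              deposit_date = "deposit_date"),
                                  min_year = 1990, max_year = 2100) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  canonical <- c("experiment_id", "antigen", "cell_type",
                 "cell_type_class", "deposit_date")
  missing_map <- setdiff(canonical, names(columns))
  if (length(missing_map) > 0L)
    stop("column mapping lacks canonical fields: ",
         paste(missing_map, collapse = ", "))
  missing_cols <- setdiff(unname(columns[canonical]), names(raw))
  if (length(missing_cols) > 0L)
    stop("required columns absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(experiment_id = raw[[columns[["experiment_id"]]]],
                   antigen = raw[[columns[["antigen"]]]],
                   cell_type = raw[[columns[["cell_type"]]]],
                   cell_type_class = raw[[columns[["cell_type_class"]]]],
                   deposit_date_raw = raw[[columns[["deposit_date"]]]],
                   stringsAsFactors = FALSE)
  dup <- df$experiment_id[duplicated(df$experiment_id)]
  if (length(dup) > 0L)
    stop("duplicate experiment_id values: ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(df$antigen)) || any(!nzchar(df$cell_type)))
    stop("antigen and cell_type must be non-empty")

  parsed <- as.Date(df$deposit_date_raw, format = "%Y-%m-%d")
  yr <- as.integer(format(parsed, "%Y"))
  bad_date <- is.na(parsed)
  bad_year <- !bad_date & (yr < min_year | yr > max_year)
  drop <- bad_date | bad_year
  report <- data.frame(row = which(drop),
                       experiment_id = df$experiment_id[drop],
                       value = df$deposit_date_raw[drop],
                       reason = ifelse(bad_date[drop], "unparseable_date",
                                       "year_out_of_range"),
                       stringsAsFactors = FALSE)
  out <- df[!drop, c("experiment_id", "antigen", "cell_type",
                     "cell_type_class")]
  out$deposit_date <- parsed[!drop]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Write an experiment metadata table
#'
#' Inverse of [read_experiment_table()]: round-trips field-for-field.
#'
#' @param metadata Data frame as returned by [read_experiment_table()].
#' @param path Output TSV path.
#' @export
write_experiment_table <- function(metadata, path) {
  out <- metadata[, c("experiment_id", "antigen", "cell_type",
                      "cell_type_class", "deposit_date")]
  out$deposit_date <- format(as.Date(out$deposit_date), "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' Minimal BED reader for peak and promoter-window files: whitespace
#' delimited, no header, at least chrom/start/end; a fourth column, when
#' present, is kept as `name`. Coordinates are BED-native 0-based half-open
#' and are validated (`0 <= start < end`).
#'
#' @param path Path to a BED file (may be empty: returns zero rows).
#' @return Data frame with columns `chrom`, `start`, `end` and, if present,
#'   `name`; input row order preserved.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[ \t]+")
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L)
    stop("BED line with fewer than 3 fields (line ",
         which.min(lengths(fields)), ")")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_c <- vapply(fields, `[[`, character(1), 2L)
  end_c <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(start_c))
  end <- suppressWarnings(as.numeric(end_c))
  bad_num <- is.na(start) | is.na(end) |
    start != floor(start) | end != floor(end)
  if (any(bad_num))
    stop("non-integer coordinate at line ", which(bad_num)[1])
  bad_ord <- start >= end | start < 0
  if (any(bad_ord))
    stop("invalid interval (start >= end or start < 0) at line ",
         which(bad_ord)[1])
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (ncol_min >= 4L)
    out$name <- vapply(fields, `[[`, character(1), 4L)
  out
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TF-by-cell-line expression matrix
#'
#' Accepts a wide TSV (first column = gene/TF symbol, remaining columns =
#' cell lines) or a long TSV with columns `gene`, `cell_line`, `value`
#' (nTPM-like). Values must be finite and nonnegative; pairs absent from a
#' long table are recorded as `NA` (absent), never as zero.
#'
#' @param path Path to the TSV.
#' @param format `"wide"` or `"long"`.
#' @return Numeric matrix, rows = TF symbols, columns = cell lines; `NA`
#'   marks absent measurements.
#' @export
read_expression_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (format == "wide") {
    mat <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- raw[[1]]
  } else {
    need <- c("gene", "cell_line", "value")
    if (!all(need %in% names(raw)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    genes <- sort(unique(raw$gene))
    lines_ <- sort(unique(raw$cell_line))
    mat <- matrix(NA_real_, length(genes), length(lines_),
                  dimnames = list(genes, lines_))
    mat[cbind(match(raw$gene, genes), match(raw$cell_line, lines_))] <-
      as.numeric(raw$value)
  }
  vals <- mat[!is.na(mat)]
  if (any(!is.finite(vals)))
    stop("non-finite expression value")
  if (any(vals < 0))
    stop("negative expression value")
  mat
}

#' Write an expression matrix as a wide TSV
#'
#' @param mat Numeric matrix with TF rownames and cell-line colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS SNP table
#'
#' Expects a TSV with header columns `rsid`, `chrom`, `pos` (1-based
#' position, as published by the GWAS catalog). Duplicate rsIDs are
#' de-duplicated keeping the first occurrence. Positions are converted to
#' 0-based half-open 1-bp intervals for overlap work.
#'
#' @param path Path to the TSV.
#' @return Data frame `rsid`, `chrom`, `pos` (1-based), `start`, `end`
#'   (0-based half-open).
#' @export
read_snp_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(raw)))
    stop("SNP table requires columns: ", paste(need, collapse = ", "))
  raw$pos <- as.integer(raw$pos)
  if (any(is.na(raw$pos)) || any(raw$pos < 1L))
    stop("SNP positions must be integers >= 1")
  raw <- raw[!duplicated(raw$rsid), , drop = FALSE]
  raw$start <- raw$pos - 1L
  raw$end <- raw$pos
  rownames(raw) <- NULL
  raw[, c("rsid", "chrom", "pos", "start", "end")]
}

#' Read a knockout DEG-count table
#'
#' One row per TF knockout/knockdown experiment: columns `tf`, `sample`
#' (cell type or class label) and `n_deg` (nonnegative integer count of
#' differentially expressed genes), in the style of KnockTF summaries.
#'
#' @param path Path to the TSV.
#' @return Validated data frame.
#' @export
read_deg_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "sample", "n_deg")
  if (!all(need %in% names(raw)))
    stop("DEG table requires columns: ", paste(need, collapse = ", "))
  raw$n_deg <- as.integer(raw$n_deg)
  if (any(is.na(raw$n_deg)) || any(raw$n_deg < 0L))
    stop("n_deg must be a nonnegative integer")
  raw
}

#' Read a TF-marker annotation table
#'
#' @param path Path to a TSV with at least a `tf` column; every listed TF is
#'   treated as a cell-type/tissue marker.
#' @return Character vector of marker TF symbols (unique).
#' @export
read_marker_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"tf" %in% names(raw))
    stop("marker table requires a 'tf' column")
  unique(raw$tf)
}

#' Read a cell-type to cell-type-class ontology mapping
#'
#' @param path Path to a TSV with columns `cell_type`, `cell_type_class`.
#' @return Data frame; duplicated cell types with conflicting classes are an
#'   error (the mapping must be a function).
#' @export
read_class_map <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "cell_type_class")
  if (!all(need %in% names(raw)))
    stop("class map requires columns: ", paste(need, collapse = ", "))
  raw <- unique(raw[, need])
  dup <- raw$cell_type[duplicated(raw$cell_type)]
  if (length(dup) > 0L)
    stop("cell types mapped to multiple classes: ",
         paste(unique(dup), collapse = ", "))
  raw
}
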