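# Small world configurations and independent oracles shared across tests.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_tfs = 12, n_cell_types = 8, n_classes = 4,
               n_experiments = 60, years = c(2012, 2020),
               genome = c(chrA = 2e5, chrB = 1e5),
               peaks_per_experiment = 10, n_snps = 120, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(world_config, args)
}

# exhaustive one-step fit: scan every breakpoint, track minimal SSE
oracle_step <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- NULL
  for (k in 1:(n - 1)) {
    lo <- v[1:k]; hi <- v[(k + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(breakpoint = k, sse = sse,
                   low_mean = mean(lo), high_mean = mean(hi))
  }
  best
}

# mean-absolute-difference Gini, double loop
oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# per-base interval overlap: expand both sides to base sets and intersect
oracle_overlap <- function(q, peaks) {
  bases <- function(chrom, start, end) paste(chrom, seq(start, end - 1))
  peak_bases <- unlist(mapply(bases, peaks$chrom, peaks$start, peaks$end,
                              SIMPLIFY = FALSE))
  vapply(seq_len(nrow(q)), function(i) {
    any(bases(q$chrom[i], q$start[i], q$end[i]) %in% peak_bases)
  }, logical(1))
}

# ground-truth expressed calls as a logical matrix
truth_matrix <- function(expr) {
  m <- matrix(FALSE, nrow(expr$matrix), ncol(expr$matrix),
              dimnames = dimnames(expr$matrix))
  m[cbind(match(expr$true_expressed$tf, rownames(m)),
          match(expr$true_expressed$cell_type, colnames(m)))] <- TRUE
  m
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 50) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}
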