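#' Shuffle the acquisition order of a compendium
#'
#' Randomly permutes the deposit dates over the fixed experiment set: the
#' multiset of dates is conserved exactly, only the assignment of dates to
#' experiment IDs changes. This simulates an alternative history in which
#' the same experiments were performed in a different order.
#'
#' @param metadata Experiment table (>= 2 rows).
#' @param seed Integer seed; the permutation is deterministic per seed.
#' @return Metadata with permuted `deposit_date` and attribute
#'   `provenance` set to `"shuffled"` with the seed recorded.
#' @export
shuffle_order <- function(metadata, seed) {
  stopifnot(nrow(metadata) >= 2)
  set.seed(as.integer(seed))
  out <- metadata
  out$deposit_date <- metadata$deposit_date[sample.int(nrow(metadata))]
  attr(out, "provenance") <- list(kind = "shuffled", seed = as.integer(seed))
  out
}

#' Span-normalized AUC of an annual trajectory
#'
#' Trapezoidal integral of the ratio over the year axis divided by the
#' year span, so the result lies in `[0, 1]` and equals the time-averaged
#' ratio of the piecewise-linear trend. A higher AUC means coverage was
#' gained earlier.
#'
#' @param series Data frame with `year` (ascending, >= 2 values) and
#'   `ratio` columns, e.g. from [annual_series()].
#' @param method `"trapezoid"` (default) or `"mean"` (plain mean of the
#'   annual points).
#' @return AUC in `[0, 1]`.
#' @examples
#' trajectory_auc(data.frame(year = 1:4, ratio = c(0, 1, 1, 1)))  # 0.8333
#' @export
trajectory_auc <- function(series, method = c("trapezoid", "mean")) {
  method <- match.arg(method)
  y <- series$year
  r <- series$ratio
  if (length(y) < 2L) stop("trajectory_auc requires at least 2 years")
  stopifnot(!is.unsorted(y, strictly = TRUE))
  if (method == "mean") return(mean(r))
  dy <- diff(y)
  sum((r[-1] + r[-length(r)]) / 2 * dy) / (y[length(y)] - y[1])
}

#' Cumulative number of unique TFs measured by each year
#'
#' @param metadata Experiment table (any acquisition order).
#' @param years Ascending target years.
#' @return Data frame `year`, `n_unique_tfs` — distinct TFs with at least
#'   one experiment deposited up to each year (nondecreasing).
#' @export
cumulative_unique_tfs <- function(metadata, years) {
  yr <- as.integer(format(as.Date(metadata$deposit_date), "%Y"))
  n <- vapply(years, function(y) {
    length(unique(metadata$antigen[yr <= y]))
  }, integer(1))
  data.frame(year = years, n_unique_tfs = n)
}

#' Simulate alternative acquisition orders and score them by AUC
#'
#' Generates `n_reps` shuffled orders (plus the real order), computes each
#' order's annual GWAS-SNP cover-ratio trajectory for one entity, its
#' span-normalized AUC, and its cumulative-unique-TF series. All orders of
#' the same world share the final-year ratio, since every order eventually
#' includes every experiment.
#'
#' @param metadata Experiment table (the real order).
#' @param snps SNP table.
#' @param peaks_by_experiment Named list of peak data frames.
#' @param entity,level,mapping Entity whose trajectory is scored (see
#'   [gwas_snp_cover_ratio()]).
#' @param years Ascending target years.
#' @param n_reps Number of shuffled orders (default 100).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param auc_method Passed to [trajectory_auc()].
#' @return List with `results` (data frame: `order`, `seed`, `auc`,
#'   `final_ratio`, `early_unique_tfs` = unique TFs in the first third of
#'   the year span), `trajectories` and `cumulative_tfs` (named lists of
#'   per-order data frames). The real order is `"real"`; replicates are
#'   `"shuffle_001"`, ...
#' @export
run_order_simulation <- function(metadata, snps, peaks_by_experiment,
                                 entity, level = "class", mapping = NULL,
                                 years, n_reps = 100, seed = 1,
                                 auc_method = "trapezoid") {
  snps <- snps[!duplicated(snps$rsid), , drop = FALSE]
  sample_ <- if (level == "cell_type") {
    metadata$cell_type
  } else {
    mapping$cell_type_class[match(metadata$cell_type, mapping$cell_type)]
  }
  meta_e <- metadata[sample_ == entity, , drop = FALSE]
  stopifnot(nrow(meta_e) >= 2)
  hits <- snp_hits_by_experiment(snps,
                                 peaks_by_experiment[
                                   intersect(meta_e$experiment_id,
                                             names(peaks_by_experiment))])
  early_cut <- years[1] + floor((years[length(years)] - years[1]) / 3)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  orders <- c(list(real = meta_e),
              stats::setNames(lapply(rep_seeds,
                                     function(s) shuffle_order(meta_e, s)),
                              sprintf("shuffle_%03d", seq_len(n_reps))))
  trajectories <- list()
  cum_tfs <- list()
  rows <- lapply(names(orders), function(nm) {
    om <- orders[[nm]]
    ey <- stats::setNames(as.integer(format(as.Date(om$deposit_date), "%Y")),
                          om$experiment_id)
    traj <- gwas_series_from_hits(hits, ey, years, nrow(snps))
    ct <- cumulative_unique_tfs(om, years)
    trajectories[[nm]] <<- traj
    cum_tfs[[nm]] <<- ct
    data.frame(order = nm,
               seed = if (nm == "real") NA_integer_
                      else rep_seeds[match(nm, names(orders)) - 1L],
               auc = trajectory_auc(traj, method = auc_method),
               final_ratio = traj$ratio[nrow(traj)],
               early_unique_tfs = ct$n_unique_tfs[match(early_cut, ct$year)],
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), trajectories = trajectories,
       cumulative_tfs = cum_tfs, entity = entity, years = years,
       metadata = meta_e, hits = hits, n_snps = nrow(snps),
       orders = orders)
}

#' Welch's two-sample t-test (Satterthwaite degrees of freedom)
#'
#' Closed-form Welch statistic with an explicit branch for degenerate
#' zero-variance inputs, which the textbook formula cannot handle: when
#' both samples are constant and equal the test is uninformative and `p`
#' is reported as 1 with `degenerate = TRUE`.
#'
#' @param x,y Numeric samples (>= 2 each).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return List `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p = 0, degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Compare chosen acquisition orders to the real order by subsampled AUC
#'
#' For each chosen order and each retention fraction, experiments are
#' repeatedly subsampled uniformly without replacement (keeping
#' `ceiling(f * N)`), the trajectory and AUC recomputed, and the order's
#' AUC distribution compared to the real order's with Welch's t-test. An
#' independent seed stream drives each (order, fraction) cell.
#'
#' @param sim Result of [run_order_simulation()].
#' @param chosen_orders Character vector of order names to test against
#'   `"real"` (e.g. the top-3 and bottom-3 AUC orders).
#' @param fractions Retention fractions (default 0.9 and 0.5).
#' @param n_subsamples Subsamples per order and fraction (default 50).
#' @param seed Master seed for the subsampling streams.
#' @param alternative Sidedness of the Welch test (two-sided default).
#' @return Data frame `order`, `fraction`, `mean_auc`, `mean_auc_real`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
subsample_compare <- function(sim, chosen_orders, fractions = c(0.9, 0.5),
                              n_subsamples = 50, seed = 1,
                              alternative = "two.sided") {
  stopifnot(n_subsamples >= 2)
  orders <- unique(c("real", chosen_orders))
  n_exp <- nrow(sim$metadata)
  aucs <- list()
  set.seed(as.integer(seed))
  stream_seeds <- matrix(sample.int(2147483646L,
                                    length(orders) * length(fractions)),
                         nrow = length(orders),
                         dimnames = list(orders, as.character(fractions)))
  for (nm in orders) {
    om <- sim$orders[[nm]]
    if (is.null(om)) stop("unknown order: ", nm)
    ey <- stats::setNames(as.integer(format(as.Date(om$deposit_date), "%Y")),
                          om$experiment_id)
    for (f in fractions) {
      set.seed(stream_seeds[nm, as.character(f)])
      keep_n <- ceiling(f * n_exp)
      aucs[[paste(nm, f)]] <- vapply(seq_len(n_subsamples), function(b) {
        ids <- om$experiment_id[sample.int(n_exp, keep_n)]
        traj <- gwas_series_from_hits(sim$hits, ey, sim$years, sim$n_snps,
                                      experiment_ids = ids)
        trajectory_auc(traj)
      }, numeric(1))
    }
  }
  rows <- lapply(setdiff(orders, "real"), function(nm) {
    do.call(rbind, lapply(fractions, function(f) {
      w <- welch_t(aucs[[paste(nm, f)]], aucs[[paste("real", f)]],
                   alternative = alternative)
      data.frame(order = nm, fraction = f,
                 mean_auc = mean(aucs[[paste(nm, f)]]),
                 mean_auc_real = mean(aucs[[paste("real", f)]]),
                 t = w$t, df = w$df, p = w$p, degenerate = w$degenerate,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "auc_samples") <- aucs
  out
}
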