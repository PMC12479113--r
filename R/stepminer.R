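#' Fit a one-step function to an expression profile
#'
#' StepMiner-style binary thresholding: the values are sorted ascending and
#' every breakpoint `k` in `1..n-1` splits them into a low block (first `k`)
#' and a high block (the rest). The fit minimizes the residual sum of
#' squares around the two block means; the expression threshold is the
#' midpoint of the two means. Ties in SSE are broken toward the smallest
#' breakpoint, which yields the most conservative "expressed" set.
#'
#' Profiles whose range is negligible (below `eps * max(1, range)`) carry no
#' step evidence and are flagged `flat`; flat profiles are treated as
#' not-expressed everywhere downstream.
#'
#' @param values Numeric vector, `n >= 2`, all finite.
#' @param eps Relative flatness tolerance.
#' @return List with `breakpoint` (index into the ascending sort),
#'   `low_mean`, `high_mean`, `threshold`, `sse`, `flat`.
#' @examples
#' fit_step(c(0, 0, 0, 10, 10, 10))  # breakpoint 3, threshold 5
#' @export
fit_step <- function(values, eps = 1e-9) {
  if (length(values) < 2L)
    stop("fit_step requires at least 2 values")
  if (any(!is.finite(values)))
    stop("fit_step requires finite values")
  v <- sort(values)
  n <- length(v)
  rng <- v[n] - v[1]
  if (rng < eps * max(1, rng)) {
    return(list(breakpoint = NA_integer_, low_mean = mean(v),
                high_mean = mean(v), threshold = NA_real_,
                sse = 0, flat = TRUE))
  }
  # SSE(k) = sum(v^2) - S_k^2/k - (T - S_k)^2/(n - k), via prefix sums
  cs <- cumsum(v)
  tot <- cs[n]
  ss <- sum(v^2)
  k <- seq_len(n - 1L)
  sse <- ss - cs[k]^2 / k - (tot - cs[k])^2 / (n - k)
  best <- which.min(sse)  # which.min takes the first minimum: smallest k
  low_mean <- cs[best] / best
  high_mean <- (tot - cs[best]) / (n - best)
  list(breakpoint = as.integer(best),
       low_mean = low_mean,
       high_mean = high_mean,
       threshold = (low_mean + high_mean) / 2,
       sse = max(0, sse[best]),
       flat = FALSE)
}

#' Call expressed/not-expressed per TF and cell line
#'
#' Fits [fit_step()] to each TF's row of the expression matrix (missing
#' entries excluded from the fit, never imputed) and calls a cell line
#' expressed when its value strictly exceeds the TF's threshold. Values
#' exactly at the threshold are not-expressed. Flat TFs are called
#' all-false. TF rows with fewer than two non-missing values cannot be fit
#' and are listed in the skip report with all-`NA` calls.
#'
#' nTPM-like expression values are heavy-tailed, so by default the step is
#' fit on the `log1p` scale, where the expressed/not-expressed mixture is
#' near-symmetric and the midpoint threshold separates the components; the
#' threshold is reported back on the data scale (`expm1`), and the calls
#' are identical to comparing transformed values against the transformed
#' threshold.
#'
#' @param mat Numeric matrix, rows = TFs, columns = cell lines; `NA` =
#'   absent measurement.
#' @param eps Flatness tolerance passed to [fit_step()].
#' @param transform `"log1p"` (default) or `"identity"`: scale on which
#'   the step is fit.
#' @return List with `calls` (logical matrix, same dimnames as `mat`; `NA`
#'   where the input was missing or the row was skipped), `fits` (data frame
#'   of per-TF breakpoint, block means and sse on the fit scale, threshold
#'   on the data scale, flat flag) and `skipped` (character vector of
#'   unfittable TFs).
#' @export
call_expression <- function(mat, eps = 1e-9,
                            transform = c("log1p", "identity")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fwd <- if (transform == "log1p") log1p else identity
  bwd <- if (transform == "log1p") expm1 else identity
  calls <- matrix(NA, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  fits <- vector("list", nrow(mat))
  skipped <- character()
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    ok <- !is.na(row)
    if (sum(ok) < 2L) {
      skipped <- c(skipped, rownames(mat)[i])
      next
    }
    f <- fit_step(fwd(row[ok]), eps = eps)
    threshold <- if (f$flat) NA_real_ else bwd(f$threshold)
    fits[[i]] <- data.frame(tf = rownames(mat)[i],
                            breakpoint = f$breakpoint,
                            low_mean = f$low_mean, high_mean = f$high_mean,
                            threshold = threshold, sse = f$sse,
                            flat = f$flat, fit_scale = transform,
                            stringsAsFactors = FALSE)
    calls[i, ok] <- if (f$flat) FALSE else row[ok] > threshold
  }
  list(calls = calls,
       fits = do.call(rbind, fits[!vapply(fits, is.null, logical(1))]),
       skipped = skipped)
}

#' Aggregate cell-line expression calls to cell-type classes
#'
#' A (TF, class) pair is expressed when at least one constituent cell line
#' of the class is called expressed.
#'
#' @param calls Logical call matrix from [call_expression()].
#' @param mapping Data frame `cell_type`, `cell_type_class` covering every
#'   column of `calls` (unmapped cell lines are an error).
#' @return Data frame of expressed pairs with columns `tf`, `cell_type_class`.
#' @export
aggregate_to_class <- function(calls, mapping) {
  lines_ <- colnames(calls)
  unmapped <- setdiff(lines_, mapping$cell_type)
  if (length(unmapped) > 0L)
    stop("cell lines missing from class map: ",
         paste(unmapped, collapse = ", "))
  cls <- mapping$cell_type_class[match(lines_, mapping$cell_type)]
  out <- list()
  for (cl in unique(cls)) {
    member <- calls[, cls == cl, drop = FALSE]
    any_true <- apply(member, 1L, function(x) any(x %in% TRUE))
    tfs <- rownames(calls)[any_true]
    if (length(tfs) > 0L)
      out[[cl]] <- data.frame(tf = tfs, cell_type_class = cl,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(tf = character(), cell_type_class = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$tf, res$cell_type_class), , drop = FALSE]
  rownames(res) <- NULL
  res
}
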