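#' Normalize a cell-line name
#'
#' Case-folds and strips whitespace, hyphens, underscores and periods so
#' that vendor spellings like "K-562", "K562" and "K 562" collapse to one
#' canonical form before similarity scoring.
#'
#' @param s Character vector.
#' @return Canonical lower-case names.
#' @export
normalize_name <- function(s) {
  s <- tolower(trimws(s))
  gsub("[[:space:]_.-]+", "", s)
}

#' Jaro-Winkler string similarity
#'
#' Standard definition: characters match when equal and within a window of
#' `floor(max(|a|,|b|)/2) - 1` positions; with `m` matches and `t`
#' transpositions (half the count of order-mismatched matched characters)
#' the Jaro similarity is `(m/|a| + m/|b| + (m-t)/m)/3`, boosted by the
#' Winkler prefix bonus `sim + l * p * (1 - sim)` with shared-prefix length
#' `l` capped at 4 and scaling `p = 0.1`.
#'
#' @param a,b Single strings (empty allowed; two empties score 1).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaro_winkler("martha", "marhta")  # 0.9611
#' @export
jaro_winkler <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  window <- max(floor(max(la, lb) / 2) - 1, 0)
  match_a <- logical(la); match_b <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!match_b[j] && sa[i] == sb[j]) {
        match_a[i] <- TRUE; match_b[j] <- TRUE
        break
      }
    }
  }
  m <- sum(match_a)
  if (m == 0L) return(0)
  # transpositions: matched characters compared in order
  t_half <- sum(sa[match_a] != sb[match_b]) / 2
  jaro <- (m / la + m / lb + (m - t_half) / m) / 3
  l <- 0L
  while (l < min(4L, la, lb) && sa[l + 1L] == sb[l + 1L]) l <- l + 1L
  jaro + l * 0.1 * (1 - jaro)
}

#' Digit-consistency check for name pairs
#'
#' Cell-line identity often hinges on a numeric suffix (K-562 vs K-563), so
#' a fuzzy match is only trusted when the two raw names carry exactly the
#' same multiset of digit characters.
#'
#' @param a,b Single strings (raw, un-normalized).
#' @return `TRUE` iff the digit multisets are equal.
#' @export
digit_consistent <- function(a, b) {
  da <- sort(strsplit(gsub("[^0-9]", "", a), "")[[1]])
  db <- sort(strsplit(gsub("[^0-9]", "", b), "")[[1]])
  identical(da, db)
}

#' Match cell-line names across two resources
#'
#' Greedy one-to-one record linkage: every cross pair is scored with
#' [jaro_winkler()] on [normalize_name()]-canonicalized names, candidates
#' are ranked by similarity (descending, ties broken lexicographically by
#' the pair), and a pair is accepted when the similarity reaches
#' `threshold`, the raw names are [digit_consistent()], and neither side is
#' already matched. The digit check runs on raw names so normalization
#' cannot erase the digit signal.
#'
#' @param list_a,list_b Character vectors of names.
#' @param threshold Acceptance threshold in `[0, 1]` (default 0.9).
#' @return Data frame of all candidate pairs (`source_name`, `target_name`,
#'   `similarity`, `digit_ok`, `accepted`), ranked; the accepted rows form a
#'   one-to-one matching.
#' @export
match_cell_lines <- function(list_a, list_b, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  list_a <- unique(list_a); list_b <- unique(list_b)
  na_ <- normalize_name(list_a); nb <- normalize_name(list_b)
  grid <- expand.grid(i = seq_along(list_a), j = seq_along(list_b))
  sim <- mapply(function(i, j) jaro_winkler(na_[i], nb[j]),
                grid$i, grid$j)
  digit_ok <- mapply(function(i, j) digit_consistent(list_a[i], list_b[j]),
                     grid$i, grid$j)
  cand <- data.frame(source_name = list_a[grid$i],
                     target_name = list_b[grid$j],
                     similarity = sim, digit_ok = digit_ok,
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$similarity, cand$source_name, cand$target_name), ]
  rownames(cand) <- NULL
  used_a <- character(); used_b <- character()
  accepted <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$similarity[r] < threshold) break  # ranked: nothing below passes
    if (!cand$digit_ok[r]) next
    if (cand$source_name[r] %in% used_a || cand$target_name[r] %in% used_b)
      next
    accepted[r] <- TRUE
    used_a <- c(used_a, cand$source_name[r])
    used_b <- c(used_b, cand$target_name[r])
  }
  cand$accepted <- accepted
  cand
}
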