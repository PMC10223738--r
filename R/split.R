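#' Case-level dataset splitting
#'
#' Shuffles the case identifiers with a seeded generator and assigns them
#' contiguously to validation, test and training sets in the given ratio
#' (default 8:17:75), with set sizes chosen by largest-remainder rounding.
#' Splitting at the case level keeps all patches from one case in the same
#' set (leakage control).
#'
#' @param case_ids Vector of unique case identifiers.
#' @param ratios Positive weights for (validation, test, training);
#'   normalized internally.
#' @param seed Integer seed for the shuffle.
#' @return List with elements `validation`, `test`, `training`.
#' @export
split_cases <- function(case_ids, ratios = c(8, 17, 75), seed = 1L) {
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  n <- length(case_ids)
  if (n < 3L) stop("fewer cases than splits")
  sizes <- .largest_remainder(n, ratios / sum(ratios))
  rng <- .seeded_rng(seed)
  shuffled <- rng$sample(case_ids)
  cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
  list(validation = shuffled[seq_len(cut1)],
       test = shuffled[(cut1 + 1):cut2],
       training = shuffled[(cut2 + 1):n])
}

# Apportion n into integer parts proportional to p (sums to 1) by the
# largest-remainder method.
.largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' k-fold partition of cases
#'
#' Seeded shuffle followed by a near-equal contiguous partition into `k`
#' folds (sizes differ by at most one; the union is the input).
#'
#' @param case_ids Vector of unique case identifiers.
#' @param k Number of folds (>= 2, <= number of cases).
#' @param seed Integer seed.
#' @return List of `k` disjoint vectors of case ids.
#' @export
kfold_cases <- function(case_ids, k = 10L, seed = 1L) {
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  n <- length(case_ids)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= number of cases")
  rng <- .seeded_rng(seed)
  shuffled <- rng$sample(case_ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
}

#' Rebalance a labeled patch set to a target class ratio
#'
#' Seeded subsampling without replacement of the over-represented class so
#' that positives:negatives matches `ratio` (within one item by integer
#' rounding). Never duplicates items; errors if the ratio would require
#' oversampling.
#'
#' @param labels 0/1 vector for the current items.
#' @param ratio Length-2 numeric `c(pos, neg)` target ratio, e.g. `c(1, 1)`
#'   or `c(1, 4)`.
#' @param seed Integer seed.
#' @return Integer vector of retained item indices (sorted).
#' @export
rebalance <- function(labels, ratio = c(1, 1), seed = 1L) {
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be nonempty")
  # keep the limiting class whole, subsample the other
  want_neg <- round(length(pos) * ratio[2] / ratio[1])
  if (want_neg >= 1 && want_neg <= length(neg)) {
    rng <- .seeded_rng(seed)
    keep_neg <- if (want_neg == length(neg)) neg else rng$sample(neg, want_neg)
    return(sort(c(pos, keep_neg)))
  }
  want_pos <- round(length(neg) * ratio[1] / ratio[2])
  if (want_pos >= 1 && want_pos <= length(pos)) {
    rng <- .seeded_rng(seed)
    keep_pos <- if (want_pos == length(pos)) pos else rng$sample(pos, want_pos)
    return(sort(c(keep_pos, neg)))
  }
  stop(sprintf("ratio %g:%g unreachable without oversampling (%d pos, %d neg)",
               ratio[1], ratio[2], length(pos), length(neg)))
}
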