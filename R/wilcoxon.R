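# Wilcoxon tests used for window comparisons.
#
# The two-group rank-sum form is exact (full enumeration of group
# assignments over mid-ranks) when n1 + n2 <= 12 and falls back to the
# tie-corrected normal approximation above that. The permutation
# distribution of the rank-sum is symmetric about its mean even under
# mid-ranks, so the two-sided p equals the doubled tail.

# cache of combn index matrices keyed by "N:n1"
.combn_cache <- new.env(parent = emptyenv())

combn_indices <- function(N, n1) {
  key <- paste0(N, ":", n1)
  got <- .combn_cache[[key]]
  if (is.null(got)) {
    got <- combn(N, n1)
    .combn_cache[[key]] <- got
  }
  got
}

EXACT_RANKSUM_LIMIT <- 12L

#' Two-sided Wilcoxon p-value for a window
#'
#' Compares the two per-site methylation level vectors of a window.
#' `test = "ranksum"` treats them as independent groups (Mann-Whitney form);
#' the null distribution is enumerated exactly over all group assignments of
#' the mid-ranks when `n1 + n2 <= 12` and approximated by the tie-corrected
#' normal otherwise. `test = "signed_rank"` pairs the vectors by site, drops
#' zero differences, and enumerates all sign assignments when the number of
#' non-zero differences is <= 16.
#'
#' @param levels_s1,levels_s2 Numeric vectors of per-site levels. Equal
#'   length is required for `signed_rank`.
#' @param test `"ranksum"` (default) or `"signed_rank"`.
#' @return Two-sided p-value in (0, 1]. All-tied input gives p = 1.
#' @export
window_test <- function(levels_s1, levels_s2,
                        test = c("ranksum", "signed_rank")) {
  test <- match.arg(test)
  if (!length(levels_s1) || (test == "ranksum" && !length(levels_s2))) {
    abort("window_test needs non-empty level vectors")
  }
  if (test == "ranksum") {
    ranksum_p(levels_s1, levels_s2)
  } else {
    if (length(levels_s1) != length(levels_s2)) {
      abort("signed_rank requires paired vectors of equal length")
    }
    signed_rank_p(levels_s1 - levels_s2)
  }
}

ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  dev <- abs(w - mu)
  if (N <= EXACT_RANKSUM_LIMIT) {
    idx <- combn_indices(N, n1)
    W <- colSums(matrix(r[idx], nrow = n1))
    mean(abs(W - mu) >= dev - 1e-9)
  } else {
    tie_tab <- table(r)
    tie_cor <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_cor / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    min(1, 2 * pnorm(-dev / sqrt(sigma2)))
  }
}

EXACT_SIGNED_RANK_LIMIT <- 16L

signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  dev <- abs(w - mu)
  if (n <= EXACT_SIGNED_RANK_LIMIT) {
    # distribution of W+ over all 2^n sign assignments
    W <- 0
    for (ri in r) W <- c(W, W + ri)
    mean(abs(W - mu) >= dev - 1e-9)
  } else {
    sigma2 <- sum(r^2) / 4
    if (sigma2 <= 0) return(1)
    min(1, 2 * pnorm(-dev / sqrt(sigma2)))
  }
}
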