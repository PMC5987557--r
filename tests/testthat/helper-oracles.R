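# Independent brute-force oracles. These deliberately use different
# algorithms from the package internals (bitmask subset enumeration,
# pairwise fix-point merging, factorial hypergeometric probabilities,
# quadratic all-pairs overlap scans).

# mid-ranks computed from scratch (average of sorted positions per value)
oracle_midranks <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}

# exact two-sided rank-sum p by enumerating every subset of size n1
# via bitmasks; "as or more extreme" = |W - E[W]| at least the observed
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- oracle_midranks(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  count <- 0L; total <- 0L
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[1:N]
    if (sum(bits) != n1) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) count <- count + 1L
  }
  count / total
}

# same-direction interval union by repeated pairwise merging to a fix point
oracle_merge_intervals <- function(df) {
  # df: chrom, start, end, direction
  parts <- split(df, paste(df$chrom, df$direction))
  merged <- lapply(parts, function(p) {
    ivs <- lapply(seq_len(nrow(p)), function(i) c(p$start[i], p$end[i]))
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in seq_along(ivs)) {
        for (j in seq_along(ivs)) {
          if (i >= j || is.null(ivs[[i]]) || is.null(ivs[[j]])) next
          a <- ivs[[i]]; b <- ivs[[j]]
          if (a[1] <= b[2] && b[1] <= a[2]) {      # overlap or abut
            ivs[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
            ivs[[j]] <- NULL
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    ivs <- Filter(Negate(is.null), ivs)
    data.frame(chrom = p$chrom[1],
               start = vapply(ivs, `[`, 0, 1),
               end = vapply(ivs, `[`, 0, 2),
               direction = p$direction[1])
  })
  out <- do.call(rbind, merged)
  out[order(out$chrom, out$start), c("chrom", "start", "end", "direction")]
}

# exact two-sided Fisher p via explicit factorial probabilities
oracle_fisher_p <- function(a, b, c, d) {
  prob_table <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    if (min(b2, c2, d2) < 0) return(NA_real_)
    exp(lfactorial(a + b) + lfactorial(c + d) + lfactorial(a + c) +
          lfactorial(b + d) - lfactorial(a + b + c + d) -
          lfactorial(a2) - lfactorial(b2) - lfactorial(c2) - lfactorial(d2))
  }
  p_obs <- prob_table(a)
  ps <- vapply(0:(a + b + c + d), prob_table, 0)
  ps <- ps[!is.na(ps)]
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# quadratic all-pairs half-open interval overlap (>= 1 bp)
oracle_overlap_pairs <- function(q, s) {
  hits <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j] &&
          q$start[i] < s$end[j] && s$start[j] < q$end[i]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}
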