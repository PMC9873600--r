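# Independent oracles used to validate the implementation, written from
# first principles and kept free of package internals.

# Pairwise Pearson correlation of matrix rows, one pair at a time.
oracle_pearson_matrix <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- x[i, ]; b <- x[j, ]
      num <- sum((a - mean(a)) * (b - mean(b)))
      den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
      out[i, j] <- num / den
    }
  }
  out
}

# Closed-form one-way fixed-effects ANOVA from the sum-of-squares
# decomposition.
oracle_anova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  grand <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw,
       ss_total = sum((unlist(groups) - grand)^2))
}

# Exact minimum within-cluster sum of squares over all partitions of the
# rows of x into exactly k nonempty groups, by enumerating every k-ary
# labeling and keeping the surjective ones.
oracle_partition_inertia <- function(x, k) {
  n <- nrow(x)
  stopifnot(k <= n)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      w <- 0
      for (c_ in seq_len(k)) {
        rows <- x[labels == c_, , drop = FALSE]
        ctr <- colMeans(rows)
        w <- w + sum(sweep(rows, 2L, ctr, "-")^2)
      }
      if (w < best) best <- w
    }
    # next k-ary counter; fix label 1 of row 1 to kill label-permutation
    # copies (any partition can be relabeled so row 1 is in group 1)
    pos <- n
    while (pos >= 2L) {
      if (labels[pos] < k) {
        labels[pos] <- labels[pos] + 1L
        if (pos < n) labels[(pos + 1L):n] <- 1L
        break
      }
      pos <- pos - 1L
    }
    if (pos < 2L) break
  }
  best
}

# Minimum assignment cost over all permutations, brute force.
oracle_min_assignment <- function(cost) {
  k <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  min(vapply(perms(seq_len(k)),
             function(p) sum(cost[cbind(seq_len(k), p)]), numeric(1)))
}
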