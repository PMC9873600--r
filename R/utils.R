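# Internal helpers shared across modules.

# All permutations of 1:k in lexicographic order, one per row.
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[i, ]])
    }
  }
  out
}

# Minimum-cost one-to-one assignment between rows and columns of a square
# cost matrix, by exhaustive enumeration over permutations (k is small:
# the number of clusters). Ties are broken toward the lexicographically
# smallest permutation, i.e. lowest-label-first.
best_permutation <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  perms <- permutations(k)
  costs <- vapply(
    seq_len(nrow(perms)),
    function(i) sum(cost[cbind(seq_len(k), perms[i, ])]),
    numeric(1)
  )
  best <- which(costs < min(costs) + 1e-12)[1L]
  list(perm = perms[best, ], cost = costs[best],
       tied = sum(costs < min(costs) + 1e-12) > 1L)
}

# Connected components of a voxel set under 6-connectivity (face adjacency).
# coords: n x 3 integer matrix of voxel indices. Returns integer component
# ids 1..n_components.
connected_components6 <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = ",")
  idx <- seq_len(n)
  names(idx) <- key
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- integer(n)
  current <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    current <- current + 1L
    queue <- start
    comp[start] <- current
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- sweep(offs, 2L, as.numeric(coords[v, ]), "+")
      nb_key <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
      hit <- idx[nb_key]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- current
      queue <- c(queue, new)
    }
  }
  comp
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two integer labelings of the same
#' items; 1 means identical partitions (up to label permutation), 0 is the
#' expected value under independent random labelings.
#'
#' @param a,b Integer vectors of equal length (cluster labels).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# Derive a per-subject RNG seed from the cohort root seed; stable under
# subject-parallel generation and kept below 2^31.
subject_seed <- function(root_seed, subject_index) {
  as.integer((as.double(root_seed) * 7919 + subject_index * 104729) %% 2147483629)
}
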