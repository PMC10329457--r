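# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and the fast formulas inside stats
# where practical) so they can serve as references.

# Pearson correlation from the definitional sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Benjamini-Hochberg step-up from the textbook definition: sort p ascending,
# q_(i) = min_{j >= i} ( p_(j) * n / j ), capped at 1, mapped back.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Brute-force Ward.D2 agglomeration: at every step recompute the merge cost
# between every pair of current clusters directly from the Lance-Williams
# recurrence on squared dissimilarities, take the global minimum (lowest
# index pair on ties), and record sqrt(cost) as the merge height together
# with the partition after the merge.
oracle_ward_d2 <- function(D) {
  n <- nrow(D)
  d2 <- D^2
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); best_cost <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (d2[i, j] < best_cost) {
          best_cost <- d2[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    clusters <- c(clusters[keep], list(sort(c(clusters[[i]], clusters[[j]]))))
    sizes <- c(sizes[keep], ni + nj)
    heights <- c(heights, sqrt(best_cost))
    partitions[[length(partitions) + 1L]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# Canonical representation of a partition: sorted list of sorted members.
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, numeric(1), 1L))]
}

# Partition sequence implied by an hclust merge matrix, for comparison with
# oracle_ward_d2().
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  nodes <- as.list(seq_len(n))      # leaves
  merged <- list()
  alive <- as.list(seq_len(n))
  partitions <- list()
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) -v else NULL
    members <- function(v) {
      if (v < 0) v_abs <- -v else return(merged[[v]])
      v_abs
    }
    a <- members(hc$merge[s, 1L]); b <- members(hc$merge[s, 2L])
    merged[[s]] <- sort(c(a, b))
    alive <- Filter(function(x) !all(x %in% merged[[s]]), alive)
    alive <- c(alive, list(merged[[s]]))
    partitions[[s]] <- canonical_partition(alive)
  }
  partitions
}

# Brute-force hotspot grouping: build the adjacency relation between genes
# from raw coordinates (consecutive in start order with intervening distance
# strictly below gap_bp, running max of ends) and take connected components
# via transitive closure of the adjacency matrix.
oracle_hotspot_components <- function(genes, gap_bp) {
  out <- list()
  for (scf in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == scf, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    n <- nrow(g)
    A <- diag(n) > 0
    run_end <- g$end[1L]
    for (i in seq_len(n - 1L)) {
      gap <- g$start[i + 1L] - run_end - 1
      if (gap < gap_bp) A[i, i + 1L] <- A[i + 1L, i] <- TRUE
      run_end <- max(run_end, g$end[i + 1L])
    }
    # transitive closure
    repeat {
      A2 <- (A %*% A) > 0 | A
      if (identical(A2, A)) break
      A <- A2
    }
    comp <- rep(NA_integer_, n)
    next_id <- 0L
    for (i in seq_len(n)) {
      if (is.na(comp[i])) {
        next_id <- next_id + 1L
        comp[which(A[i, ])] <- next_id
      }
    }
    out[[scf]] <- split(g$gene_id, comp)
  }
  out
}

# Upper-tail hypergeometric probability from binomial coefficients.
oracle_hyper_upper <- function(x, K, N, n) {
  sum(vapply(x:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}
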