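# Independent oracles used to check the package's sequence and clustering
# kernels. These deliberately share no code with the implementation: the
# edit-distance oracle is a memoised top-down recursion, the linkage oracle
# a naive O(n^3) agglomeration on the raw matrix.

# Recursive weighted edit distance. `cost` is a function(x, y) -> [0, 1].
ld_oracle <- function(a, b, cost = function(x, y) as.numeric(x != y),
                      indel = 1) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <-
      if (i == 0L && j == 0L) 0
      else if (i == 0L) j * indel
      else if (j == 0L) i * indel
      else min(rec(i - 1L, j - 1L) + cost(a[i], b[j]),
               rec(i - 1L, j) + indel,
               rec(i, j - 1L) + indel)
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Naive average-linkage: returns the cophenetic distance matrix implied by
# agglomerating with cluster distance = mean pairwise original distance.
upgma_oracle_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Random symmetric substitution-cost matrix over `labels` satisfying the
# cost_matrix contract (entries in [0, 1], zero diagonal).
random_cost_matrix <- function(labels) {
  n <- length(labels)
  m <- matrix(runif(n * n), n, n, dimnames = list(labels, labels))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  cost_matrix(m)
}
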