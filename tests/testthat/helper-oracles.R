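# Independent brute-force oracles used to cross-check the package's graph
# metrics and statistics. Deliberately naive implementations: different
# algorithms, different code paths.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_char_path_length <- function(A) {
  D <- oracle_floyd_warshall(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracle_global_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + (if (is.finite(D[i, j])) 1 / D[i, j] else 0)
  tot / (n * (n - 1))
}

# clustering by explicit triangle enumeration around each node
oracle_clustering <- function(A) {
  n <- nrow(A)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b)
      e <- e + (A[nb[a], nb[b]] > 0)
    Ci[i] <- 2 * e / (k * (k - 1))
  }
  mean(Ci)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# Erdos-Renyi 0/1 adjacency
random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.integer(runif(length(ut)) < p)
  A + t(A)
}

# random symmetric matrix with unit diagonal and all-distinct entries
random_sym_matrix <- function(n, seed) {
  set.seed(seed)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- sample(seq_len(n * (n - 1) / 2)) / (n * n)
  M <- M + t(M)
  diag(M) <- 1
  M
}

# small named adjacency helpers
graph_complete <- function(n) { A <- matrix(1L, n, n); diag(A) <- 0L; A }
graph_path3 <- function() rbind(c(0,1,0), c(1,0,1), c(0,1,0))
graph_star4 <- function() rbind(c(0,1,1,1), c(1,0,0,0), c(1,0,0,0), c(1,0,0,0))
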