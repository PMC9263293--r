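test_that("binarize realizes K = round(s * N(N-1)/2) with nested edge sets", {
  M <- random_sym_matrix(30, seed = 11)
  b <- binarize(M, 0.12)
  expect_equal(b$K, 52)  # round(0.12 * 435)
  expect_equal(sum(b$adjacency) / 2, 52)
  expect_true(isSymmetric(b$adjacency))
  expect_true(all(diag(b$adjacency) == 0))
  prev <- NULL
  for (s in sparsity_grid()) {
    bs <- binarize(M, s)
    expect_equal(sum(bs$adjacency) / 2, bs$K)
    if (!is.null(prev)) expect_true(all(bs$adjacency[prev > 0] == 1))
    prev <- bs$adjacency
  }
})

test_that("binarize single-edge case and cutoff tie rule", {
  M <- random_sym_matrix(6, seed = 2)
  b1 <- binarize(M, 1 / 15 - 1e-9)  # K = 1
  expect_equal(b1$K, 1)
  top <- which(M == max(M[upper.tri(M)]), arr.ind = TRUE)
  expect_equal(b1$adjacency[top[1, 1], top[1, 2]], 1L)
  # exact tie at the cutoff: (1,3) and (2,4) share the boundary value;
  # the lexicographically smaller pair must win
  M2 <- matrix(0, 4, 4)
  M2[1, 2] <- 0.9; M2[1, 3] <- 0.5; M2[2, 4] <- 0.5; M2[3, 4] <- 0.1
  M2 <- M2 + t(M2); diag(M2) <- 1
  b <- binarize(M2, 2 / 6 + 1e-9)  # K = 2
  expect_equal(b$K, 2)
  expect_equal(b$adjacency[1, 3], 1L)
  expect_equal(b$adjacency[2, 4], 0L)
  expect_error(binarize(random_sym_matrix(4, 1), 0.01), "degenerate")
  expect_error(binarize(M, 0), "sparsity")
  expect_error(binarize(matrix(runif(16), 4), 0.5), "symmetric")
})

test_that("closed-form metric values on K3, K4, path and star graphs", {
  k3 <- graph_complete(3)
  expect_equal(characteristic_path_length(k3)$L, 1)
  expect_equal(clustering_coefficient(k3)$C, 1)
  expect_equal(global_efficiency(k3), 1)
  k4 <- graph_complete(4)
  expect_equal(local_efficiency(k4), 1)
  for (n in c(3, 5, 8)) {  # complete graph: all four metrics are 1
    kn <- graph_complete(n)
    m <- global_metrics(kn)
    expect_equal(unlist(m[c("L", "C", "Eglobal", "Elocal")]),
                 c(L = 1, C = 1, Eglobal = 1, Elocal = 1))
  }
  p3 <- graph_path3()
  expect_equal(shortest_path_lengths(p3)[1, 3], 2)
  expect_equal(characteristic_path_length(p3)$L, 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)
  s4 <- graph_star4()
  expect_equal(characteristic_path_length(s4)$L, 1.5)
  expect_equal(clustering_coefficient(s4)$C, 0)
  expect_equal(local_efficiency(s4), 0)
  dimnames(s4) <- list(c("FZ", "O1", "O2", "OZ"), c("FZ", "O1", "O2", "OZ"))
  deg <- nodal_degrees(s4, montage_1020(c("FZ", "O1", "O2", "OZ")))
  expect_equal(unname(deg$degree), c(3, 1, 1, 1))
  expect_equal(deg$mean_degree, 1.5)
  # K4 minus one edge: C = 5/6 (confirmed by the enumeration oracle)
  k4e <- graph_complete(4); k4e[1, 2] <- k4e[2, 1] <- 0L
  expect_equal(clustering_coefficient(k4e)$C, 5 / 6)
  expect_equal(oracle_clustering(k4e), 5 / 6)
})

test_that("metrics equal brute-force oracles on random graphs (N <= 12)", {
  for (seed in 1:100) {
    n <- sample(4:12, 1)
    A <- random_graph(n, runif(1, 0.2, 0.6), seed)
    D <- shortest_path_lengths(A)
    expect_identical(unname(D), oracle_floyd_warshall(A))
    d <- D[upper.tri(D)]
    if (any(is.finite(d))) {
      expect_equal(characteristic_path_length(A)$L, oracle_char_path_length(A))
    }
    expect_equal(global_efficiency(A), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(A)$C, oracle_clustering(A))
    expect_equal(local_efficiency(A), oracle_local_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_degrees(A, montage_1020(paste0("ch", 1:n)))$degree),
                 rowSums(A))
  }
})

test_that("degree handshake and montage aggregation", {
  mont <- montage_1020()
  for (seed in 1:50) {
    M <- random_sym_matrix(30, seed)
    dimnames(M) <- list(mont$channel, mont$channel)
    b <- binarize(M, 0.2)
    nd <- nodal_degrees(b, mont)
    expect_equal(sum(nd$degree), 2 * b$K)
    expect_equal(nd$mean_degree, 2 * b$K / 30)
    expect_setequal(names(nd$lobe_means),
                    c("frontal", "parietal", "temporal", "occipital", "central"))
  }
  expect_error(nodal_degrees(graph_star4(), montage_1020(c("a", "b", "c", "d"))),
               "montage mismatch")
})

test_that("metric_sweep: 29 rows, Eglobal monotone, deterministic per matrix", {
  M <- random_sym_matrix(30, seed = 5)
  sw <- metric_sweep(M)
  expect_equal(nrow(sw$metrics), 29)
  expect_equal(sw$metrics$sparsity, (12:40) / 100)
  expect_true(all(diff(sw$metrics$Eglobal) >= 0))
  expect_true(all(sw$metrics$C >= 0 & sw$metrics$C <= 1))
  expect_true(all(sw$metrics$L >= 1))
  expect_true(all(sw$metrics$Elocal >= 0 & sw$metrics$Elocal <= 1))
  sw2 <- metric_sweep(M)
  expect_identical(sw$metrics, sw2$metrics)
  expect_equal(nrow(sw$nodal), 29 * 30)
  expect_equal(unname(sw$mean_degree),
               unname(colMeans(matrix(sw$nodal$degree, nrow = 29, byrow = TRUE))))
})

test_that("masked PLV entries rank last in binarization", {
  M <- random_sym_matrix(6, seed = 7)
  M[1, 2] <- M[2, 1] <- NA
  b <- binarize(M, 14 / 15 - 1e-9)  # K = 14 of 15: only the masked pair left out
  expect_equal(b$adjacency[1, 2], 0L)
  expect_equal(sum(b$adjacency) / 2, 14)
})
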