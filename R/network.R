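# Sparsity-thresholded binarization and binary graph metrics.
#
# Sparsity is the ratio K / (N(N-1)/2) of realized to possible edges. The
# analysis sweep constructs, for each subject and band, a series of binary
# networks over a sparsity grid and computes the characteristic path length
# L, clustering coefficient C, global efficiency Eglobal, local efficiency
# Elocal and nodal degrees at every grid point.

#' Default sparsity grid
#'
#' @param from,to,by grid bounds and step as percentages of possible edges;
#'   default 12 to 40 by 1 (29 values).
#' @return numeric vector of sparsity fractions, strictly increasing in (0,1).
#' @export
sparsity_grid <- function(from = 12, to = 40, by = 1) {
  g <- seq.int(from, to, by) / 100
  if (any(g <= 0) || any(g >= 1) || is.unsorted(g, strictly = TRUE))
    stop("sparsity grid must be strictly increasing inside (0,1)")
  g
}

# round half away from zero (the pinned K convention)
round_half_away <- function(x) floor(x + 0.5)

# ranking of off-diagonal upper-triangle entries: decreasing value, ties by
# lexicographic (i, j); masked/NA entries rank last. Returns i/j index vectors
# in rank order.
edge_ranking <- function(values) {
  n <- nrow(values)
  ut <- which(upper.tri(values), arr.ind = TRUE)
  v <- values[ut]
  v[is.na(v)] <- -Inf
  o <- order(-v, ut[, 1], ut[, 2])
  list(i = ut[o, 1], j = ut[o, 2], n = n)
}

#' Binarize a PLV matrix at a stated sparsity
#'
#' Keeps the K = round(sparsity * N(N-1)/2) largest off-diagonal entries as
#' edges (round half away from zero). Exact ties at the cutoff are broken by
#' lexicographic (i, j) order; masked entries rank last. Edge sets are nested
#' across increasing sparsity for the same matrix.
#'
#' @param pm a [plv_matrix()] or a symmetric numeric matrix.
#' @param sparsity fraction in (0, 1).
#' @return object of class \code{binary_network}: list with \code{adjacency}
#'   (0/1 symmetric, zero diagonal), \code{sparsity}, \code{K},
#'   \code{channel_labels}.
#' @export
binarize <- function(pm, sparsity) {
  vals <- if (inherits(pm, "plv_matrix")) pm$values else as.matrix(pm)
  labels <- if (inherits(pm, "plv_matrix")) pm$channel_labels else rownames(vals)
  if (!isTRUE(all.equal(vals, t(vals), check.attributes = FALSE,
                        tolerance = 1e-8)))
    stop("matrix must be symmetric")
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0,1)")
  n <- nrow(vals)
  npairs <- n * (n - 1) / 2
  K <- round_half_away(sparsity * npairs)
  if (K < 1) stop("degenerate network: K = 0 at sparsity ", sparsity)
  r <- edge_ranking(vals)
  A <- matrix(0L, n, n)
  sel <- seq_len(K)
  A[cbind(r$i[sel], r$j[sel])] <- 1L
  A <- A + t(A)
  dimnames(A) <- list(labels, labels)
  structure(list(adjacency = A, sparsity = sparsity, K = K,
                 channel_labels = labels),
            class = "binary_network")
}

as_adjacency <- function(network) {
  if (inherits(network, "binary_network")) network$adjacency
  else as.matrix(network)
}

#' Shortest-path hop counts of a binary network
#'
#' Breadth-first distances computed by iterated boolean adjacency products;
#' unreachable pairs are \code{Inf}.
#'
#' @param network a [binarize()] result or 0/1 adjacency matrix.
#' @return N x N matrix of hop counts (0 diagonal, Inf where disconnected).
#' @export
shortest_path_lengths <- function(network) {
  A0 <- as_adjacency(network)
  D <- bfs_distances(A0 > 0)
  dimnames(D) <- dimnames(A0)
  D
}

# plain matrix BFS distances (no dimnames, minimal overhead)
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- A
  storage.mode(reach) <- "double"
  d <- 1
  repeat {
    new <- reach > 0 & !is.finite(D)
    if (!any(new)) break
    D[new] <- d
    if (d >= n) break
    reach <- reach %*% A
    d <- d + 1
  }
  D
}

#' Characteristic path length
#'
#' Mean hop count over unordered node pairs. Disconnected pairs are excluded
#' from the average; the number of connected pairs is reported so callers can
#' detect fragmentation.
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @return list with \code{L} and \code{n_connected_pairs}.
#' @export
characteristic_path_length <- function(network) {
  D <- shortest_path_lengths(network)
  d <- D[upper.tri(D)]
  fin <- is.finite(d)
  if (!any(fin)) stop("fully disconnected network: L undefined")
  list(L = mean(d[fin]), n_connected_pairs = sum(fin))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the reciprocal shortest path length, with
#' 1/Inf = 0, so disconnection needs no special casing.
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @return Eglobal in [0, 1].
#' @export
global_efficiency <- function(network) {
  D <- shortest_path_lengths(network)
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Clustering coefficient
#'
#' Per node, the fraction of pairs of its neighbors that are themselves
#' connected: \code{C_i = 2 E_i / (k_i (k_i - 1))}, with the convention
#' \code{C_i = 0} for degree < 2. The network coefficient is the mean of
#' \code{C_i} over all N nodes.
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @return list with \code{C} and per-node \code{Ci}.
#' @export
clustering_coefficient <- function(network) {
  A <- as_adjacency(network)
  k <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)  # 2 * E_i within each neighborhood
  Ci <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  list(C = mean(Ci), Ci = Ci)
}

#' Local efficiency
#'
#' Mean over all nodes of the global efficiency of the subgraph induced by
#' each node's neighbors (the node itself excluded); nodes with fewer than
#' two neighbors contribute 0.
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @return Elocal in [0, 1].
#' @export
local_efficiency <- function(network) {
  A <- as_adjacency(network)
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    m <- length(nb)
    if (m < 2) return(0)
    D <- bfs_distances(A[nb, nb, drop = FALSE] > 0)
    inv <- 1 / D
    diag(inv) <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  mean(vals)
}

#' All four global metrics of one network
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @return list with \code{L}, \code{C}, \code{Eglobal}, \code{Elocal},
#'   \code{n_connected_pairs}.
#' @export
global_metrics <- function(network) {
  cpl <- characteristic_path_length(network)
  list(L = cpl$L, C = clustering_coefficient(network)$C,
       Eglobal = global_efficiency(network),
       Elocal = local_efficiency(network),
       n_connected_pairs = cpl$n_connected_pairs)
}

#' Nodal degrees with lobe aggregation
#'
#' Row sums of the adjacency (k_i), the network mean degree 2K/N, and
#' per-zone mean degrees over the montage lobe sets. The central zone
#' (C3/Cz/C4) is listed as its own zone, separate from the four classical
#' lobes.
#'
#' @param network a [binarize()] result or adjacency matrix.
#' @param montage a [montage_1020()] data.frame matching the network labels.
#' @return list with \code{degree} (named vector), \code{mean_degree},
#'   \code{lobe_means} (named vector).
#' @export
nodal_degrees <- function(network, montage = montage_1020()) {
  A <- as_adjacency(network)
  labels <- colnames(A)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(A)))
  lobe <- montage$lobe[match(labels, montage$channel)]
  if (anyNA(lobe))
    stop("montage mismatch: no lobe for ",
         paste(labels[is.na(lobe)], collapse = ", "))
  k <- rowSums(A)
  names(k) <- labels
  lm <- tapply(k, lobe, mean)
  list(degree = k, mean_degree = mean(k), lobe_means = lm)
}

#' Metric sweep over a sparsity grid
#'
#' Binarizes one PLV matrix at every sparsity of the grid and computes the
#' global metrics and nodal degrees at each level. Because the grid reuses a
#' single ranking of the matrix entries, edge sets are nested and global
#' efficiency is non-decreasing along the grid.
#'
#' @param pm a [plv_matrix()] (or symmetric matrix).
#' @param grid sparsity values, default [sparsity_grid()].
#' @param montage a [montage_1020()] for lobe aggregation.
#' @return list with \code{metrics} (data.frame: one row per sparsity with
#'   subject_id, band, sparsity, K, L, C, Eglobal, Elocal,
#'   n_connected_pairs), \code{nodal} (long data.frame: subject_id, band,
#'   sparsity, channel, lobe, degree), and \code{mean_degree} (named
#'   per-channel mean of degree across the grid).
#' @export
metric_sweep <- function(pm, grid = sparsity_grid(), montage = montage_1020()) {
  subject <- if (inherits(pm, "plv_matrix")) pm$subject_id else "subject"
  band <- if (inherits(pm, "plv_matrix") && !is.null(pm$band)) pm$band$name else NA_character_
  vals <- if (inherits(pm, "plv_matrix")) pm$values else as.matrix(pm)
  labels <- if (!is.null(colnames(vals))) colnames(vals) else paste0("ch", seq_len(ncol(vals)))
  lobe <- montage$lobe[match(labels, montage$channel)]
  n <- nrow(vals)
  npairs <- n * (n - 1) / 2
  rank_ <- edge_ranking(vals)  # one ranking shared across the grid: nested sets
  ng <- length(grid)
  out <- matrix(NA_real_, ng, 6,
                dimnames = list(NULL, c("K", "L", "C", "Eglobal", "Elocal",
                                        "n_connected_pairs")))
  degacc <- matrix(0L, ng, n)
  A <- matrix(0L, n, n)
  prevK <- 0L
  for (g in seq_len(ng)) {
    K <- round_half_away(grid[g] * npairs)
    if (K < 1) stop("degenerate network: K = 0 at sparsity ", grid[g])
    if (K > prevK) {
      sel <- (prevK + 1L):K
      A[cbind(rank_$i[sel], rank_$j[sel])] <- 1L
      A[cbind(rank_$j[sel], rank_$i[sel])] <- 1L
      prevK <- K
    }
    D <- shortest_path_lengths(A)
    dut <- D[upper.tri(D)]
    fin <- is.finite(dut)
    if (!any(fin)) stop("fully disconnected network at sparsity ", grid[g])
    inv <- 1 / D
    diag(inv) <- 0
    k <- rowSums(A)
    tri2 <- diag(A %*% A %*% A)
    Ci <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
    out[g, ] <- c(K, mean(dut[fin]), mean(Ci), sum(inv) / (n * (n - 1)),
                  local_efficiency(A), sum(fin))
    degacc[g, ] <- k
  }
  metrics <- data.frame(subject_id = subject, band = band, sparsity = grid,
                        K = out[, "K"], L = out[, "L"], C = out[, "C"],
                        Eglobal = out[, "Eglobal"], Elocal = out[, "Elocal"],
                        n_connected_pairs = out[, "n_connected_pairs"],
                        stringsAsFactors = FALSE)
  nodal <- data.frame(subject_id = subject, band = band,
                      sparsity = rep(grid, each = n),
                      channel = rep(labels, ng),
                      lobe = rep(lobe, ng),
                      degree = as.vector(t(degacc)),
                      stringsAsFactors = FALSE)
  mean_degree <- colMeans(degacc)
  names(mean_degree) <- labels
  list(metrics = metrics, nodal = nodal, mean_degree = mean_degree)
}
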