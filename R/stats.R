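# Non-parametric group inference and the demographic tests.

#' Two-sample permutation test on the group mean difference
#'
#' Statistic: mean(a) - mean(b). Group labels are shuffled without
#' replacement; the two-sided p-value is
#' \code{(#\{|perm stat| >= |observed|\} + 1) / (n_permutations + 1)} for
#' sampled permutations, or the exact proportion over all label splits when
#' \code{exact = TRUE}. Deterministic given \code{seed}.
#'
#' @param values_a,values_b numeric samples (non-empty).
#' @param n_permutations number of sampled permutations (default 10000).
#' @param seed integer seed.
#' @param exact enumerate all \code{choose(na+nb, na)} splits instead of
#'   sampling (feasible for small samples only).
#' @return list of class \code{permutation_result}: \code{observed},
#'   \code{p_value}, \code{n_permutations}, \code{seed}, \code{tail}.
#' @export
permutation_test <- function(values_a, values_b, n_permutations = 10000,
                             seed = 1L, exact = FALSE) {
  if (!length(values_a) || !length(values_b)) stop("both samples must be non-empty")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  obs <- mean(values_a) - mean(values_b)
  if (stats::var(pooled) == 0) {
    warning("zero variance in pooled sample; p = 1")
    return(structure(list(observed = obs, p_value = 1,
                          n_permutations = n_permutations, seed = seed,
                          tail = "two-sided"),
                     class = "permutation_result"))
  }
  if (exact) {
    splits <- utils::combn(length(pooled), na)
    stats_perm <- apply(splits, 2, function(idx)
      mean(pooled[idx]) - mean(pooled[-idx]))
    p <- mean(abs(stats_perm) >= abs(obs) - 1e-12)
    n_permutations <- ncol(splits)
  } else {
    set.seed(as.integer(seed))
    stats_perm <- replicate(n_permutations, {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    p <- (sum(abs(stats_perm) >= abs(obs) - 1e-12) + 1) / (n_permutations + 1)
  }
  structure(list(observed = obs, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 tail = "two-sided"),
            class = "permutation_result")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Pooled-variance two-sample t-test
#'
#' Equal-variance t statistic with \code{na + nb - 2} degrees of freedom.
#'
#' @param values_a,values_b numeric samples with >= 2 values each.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
two_sample_t <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("need >= 2 values per group")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance: t undefined")
  tstat <- (mean(values_a) - mean(values_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df), df = df)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' 1 degree of freedom, no continuity correction.
#'
#' @param table 2 x 2 matrix of nonnegative counts.
#' @return list with \code{chi2}, \code{p}, \code{df}.
#' @export
chi_square_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2 x 2 table")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: chi-square undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}

# Vectorized permutation engine: X is subjects x tests, is_a a logical group
# indicator. One shared permutation set is used for all columns (same
# relabellings across tests, which also preserves cross-test coherence).
# Returns observed stats and two-sided p per column.
perm_engine <- function(X, is_a, n_permutations, seed) {
  X <- as.matrix(X)
  na <- sum(is_a); nb <- sum(!is_a)
  obs <- colMeans(X[is_a, , drop = FALSE]) - colMeans(X[!is_a, , drop = FALSE])
  set.seed(as.integer(seed))
  n <- nrow(X)
  W <- matrix(0, n_permutations, n)
  for (p in seq_len(n_permutations)) W[p, sample.int(n, na)] <- 1
  S <- (W %*% X) / na - ((1 - W) %*% X) / nb
  pvals <- (colSums(abs(S) >= rep(abs(obs) - 1e-12, each = n_permutations)) + 1) /
    (n_permutations + 1)
  list(observed = obs, p = pvals)
}

#' Group contrasts across bands, sparsity levels and nodes
#'
#' For every band in a metric table this runs two-sided permutation tests on
#' the group mean difference at three granularities:
#' \itemize{
#'   \item range level: each global metric averaged across the sparsity grid
#'     per subject;
#'   \item threshold level: each global metric at every grid point, with
#'     Benjamini-Hochberg adjustment across the grid (per band and metric);
#'   \item nodal: the across-grid mean degree of every channel, BH-adjusted
#'     across channels (per band).
#' }
#' The study reports uncorrected per-threshold significance; both uncorrected
#' and BH-adjusted p-values are emitted.
#'
#' @param metric_table data.frame as stacked from [metric_sweep()]
#'   \code{$metrics} across subjects (needs subject_id, band, sparsity, L, C,
#'   Eglobal, Elocal).
#' @param cohort_table data.frame with \code{subject_id} and \code{group}
#'   (two levels; the first level alphabetically last, "TC", is the "a" side:
#'   statistic = mean(TC) - mean(control)).
#' @param nodal_table optional stacked \code{$nodal} data.frame for the
#'   degree contrasts.
#' @param n_permutations permutations (default 10000).
#' @param seed integer seed.
#' @return list with data.frames \code{range_level} (band, metric, observed,
#'   p), \code{threshold_level} (band, sparsity, metric, observed, p, p_bh),
#'   \code{nodal} (band, channel, lobe, observed, p, p_bh).
#' @export
group_contrast_sweep <- function(metric_table, cohort_table,
                                 nodal_table = NULL,
                                 n_permutations = 10000, seed = 1L) {
  metrics <- c("L", "C", "Eglobal", "Elocal")
  stopifnot(all(c("subject_id", "band", "sparsity", metrics) %in%
                  names(metric_table)))
  grp <- cohort_table$group[match(unique(metric_table$subject_id),
                                  cohort_table$subject_id)]
  if (anyNA(grp)) stop("subject mismatch between metric table and cohort table")
  subjects <- unique(metric_table$subject_id)
  levels_g <- sort(unique(cohort_table$group), decreasing = TRUE)  # "TC" first
  if (length(levels_g) != 2L) stop("need exactly two groups")
  is_a <- grp == levels_g[1]
  range_rows <- list(); thr_rows <- list(); nodal_rows <- list()
  test_i <- 0L
  for (bn in unique(metric_table$band)) {
    mb <- metric_table[metric_table$band == bn, ]
    grid <- sort(unique(mb$sparsity))
    # subjects x (metrics x grid) matrix
    Xthr <- sapply(metrics, function(m) {
      sapply(grid, function(s) {
        v <- mb[mb$sparsity == s, ]
        v[[m]][match(subjects, v$subject_id)]
      })
    })  # subjects x grid per metric, column-bound
    Xthr <- matrix(Xthr, nrow = length(subjects))
    colnames(Xthr) <- as.vector(outer(grid, metrics,
                                      function(s, m) paste(m, s, sep = "@")))
    Xrange <- sapply(metrics, function(m) {
      rowMeans(sapply(grid, function(s) {
        v <- mb[mb$sparsity == s, ]
        v[[m]][match(subjects, v$subject_id)]
      }))
    })
    test_i <- test_i + 1L
    res_r <- perm_engine(Xrange, is_a, n_permutations, seed + test_i)
    range_rows[[bn]] <- data.frame(band = bn, metric = metrics,
                                   observed = unname(res_r$observed),
                                   p = unname(res_r$p),
                                   stringsAsFactors = FALSE)
    test_i <- test_i + 1L
    res_t <- perm_engine(Xthr, is_a, n_permutations, seed + test_i)
    parts <- strsplit(colnames(Xthr), "@", fixed = TRUE)
    thr <- data.frame(band = bn,
                      sparsity = as.numeric(vapply(parts, `[`, "", 2)),
                      metric = vapply(parts, `[`, "", 1),
                      observed = unname(res_t$observed),
                      p = unname(res_t$p), stringsAsFactors = FALSE)
    thr$p_bh <- stats::ave(thr$p, thr$metric,
                           FUN = function(p) stats::p.adjust(p, "BH"))
    thr_rows[[bn]] <- thr
    if (!is.null(nodal_table)) {
      nb <- nodal_table[nodal_table$band == bn, ]
      channels <- unique(nb$channel)
      Xn <- sapply(channels, function(ch) {
        v <- nb[nb$channel == ch, ]
        md <- tapply(v$degree, v$subject_id, mean)
        as.numeric(md[subjects])
      })
      test_i <- test_i + 1L
      res_n <- perm_engine(Xn, is_a, n_permutations, seed + test_i)
      nodal_rows[[bn]] <- data.frame(
        band = bn, channel = channels,
        lobe = nb$lobe[match(channels, nb$channel)],
        observed = unname(res_n$observed), p = unname(res_n$p),
        p_bh = stats::p.adjust(res_n$p, "BH"),
        stringsAsFactors = FALSE)
    }
  }
  list(range_level = do.call(rbind, c(range_rows, list(make.row.names = FALSE))),
       threshold_level = do.call(rbind, c(thr_rows, list(make.row.names = FALSE))),
       nodal = if (length(nodal_rows))
         do.call(rbind, c(nodal_rows, list(make.row.names = FALSE))) else NULL)
}

#' Within-group correlations of reaction time with range-level metrics
#'
#' Pearson correlation of mean reaction time against each global metric
#' averaged across the sparsity grid, computed separately within each group.
#'
#' @param metric_table stacked [metric_sweep()] \code{$metrics} data.frame.
#' @param cohort_table data.frame with subject_id, group, rt_ms.
#' @return data.frame: group, band, metric, r, p, n.
#' @export
rt_metric_correlations <- function(metric_table, cohort_table) {
  metrics <- c("L", "C", "Eglobal", "Elocal")
  out <- list()
  for (bn in unique(metric_table$band)) {
    mb <- metric_table[metric_table$band == bn, ]
    agg <- stats::aggregate(mb[metrics], by = list(subject_id = mb$subject_id),
                            FUN = mean)
    agg <- merge(agg, cohort_table[c("subject_id", "group", "rt_ms")],
                 by = "subject_id")
    for (g in unique(agg$group)) {
      sub <- agg[agg$group == g, ]
      for (m in metrics) {
        ct <- if (nrow(sub) >= 3 && stats::var(sub$rt_ms) > 0 &&
                  stats::var(sub[[m]]) > 0)
          pearson_correlation(sub$rt_ms, sub[[m]])
        else list(r = NA_real_, p_value = NA_real_, n = nrow(sub))
        out[[length(out) + 1L]] <- data.frame(
          group = g, band = bn, metric = m, r = ct$r, p = ct$p_value,
          n = ct$n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
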