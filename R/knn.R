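# K-nearest-neighbour randomisation test for multivariate isotopic
# separation of diet-item categories, and pooling of indistinguishable
# categories before mixing-model fitting.

# k nearest neighbours of every point (self excluded), Euclidean distance,
# ties broken by stable index order. X: n x J matrix. Returns n x k index
# matrix plus a degeneracy flag.
knn_neighbours <- function(X, k) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of pooled points")
  D <- as.matrix(stats::dist(X))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    idx <- seq_len(n)[-i]
    ord <- order(d, idx)              # stable: index order breaks ties
    nn[i, ] <- idx[ord[seq_len(k)]]
  }
  degenerate <- all(D[upper.tri(D)] == 0)
  list(nn = nn, degenerate = degenerate)
}

# Mean same-label fraction among each point's k nearest neighbours.
knn_statistic <- function(nn, labels) {
  mean(matrix(labels[nn], nrow(nn)) == labels)
}

#' K-nearest-neighbour randomisation test for two multivariate groups
#'
#' Tests whether two groups of isotope vectors occupy distinguishable
#' regions of isotope space. The statistic is the mean fraction, over all
#' pooled points, of each point's `k` Euclidean nearest neighbours (self
#' excluded) that share its group label. The null distribution is obtained
#' by randomly relabelling points while preserving group sizes; the p-value
#' uses the add-one permutation estimator
#' \eqn{p = (1 + \#\{stat^* \ge stat\}) / (1 + n_{perm})}, so it is never
#' exactly zero. With `exact = TRUE` all distinct label assignments are
#' enumerated instead and the p-value is the exact tail fraction.
#'
#' @param a,b Numeric matrices (rows = samples, columns = shared isotope
#'   channels; a vector is treated as one column). At least 2 rows each.
#' @param k Number of neighbours (default 3); must be `< nrow(a) + nrow(b)`.
#' @param n_perm Number of random relabelings (ignored when `exact`).
#' @param seed Integer RNG seed; the test is deterministic given `seed`.
#' @param standardize Scale each channel to unit SD before computing
#'   distances (default `FALSE`: raw per-mil coordinates).
#' @param exact Enumerate all label assignments (feasible for small n).
#' @return An object of class `knn_test`: `observed_stat`, `p_value`,
#'   `n_permutations`, `k`, `seed`, `degenerate`, group sizes.
#' @export
knn_randomization_test <- function(a, b, k = 3, n_perm = 999, seed = NULL,
                                   standardize = FALSE, exact = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each group needs at least 2 samples")
  if (ncol(a) != ncol(b)) stop("groups must share the same channels")
  X <- rbind(a, b)
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  na <- nrow(a); n <- nrow(X)
  labels <- rep(c(1L, 2L), c(na, n - na))
  nb <- knn_neighbours(X, k)
  obs <- knn_statistic(nb$nn, labels)
  if (exact) {
    combs <- utils::combn(n, na)
    stats_all <- apply(combs, 2, function(ix) {
      lab <- rep(2L, n); lab[ix] <- 1L
      knn_statistic(nb$nn, lab)
    })
    p <- mean(stats_all >= obs - 1e-12)
    n_used <- ncol(combs)
  } else {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      lab <- sample(labels)
      if (knn_statistic(nb$nn, lab) >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(observed_stat = obs, p_value = p, n_permutations = n_used,
                 k = k, seed = seed, exact = exact,
                 degenerate = nb$degenerate, n_a = na, n_b = n - na,
                 standardize = standardize),
            class = "knn_test")
}

#' @export
print.knn_test <- function(x, ...) {
  cat(sprintf(
    "KNN randomisation test (k=%d, %s): stat = %.4f, p = %.4g (n=%d+%d)\n",
    x$k, if (x$exact) "exact enumeration"
         else sprintf("%d permutations", x$n_permutations),
    x$observed_stat, x$p_value, x$n_a, x$n_b))
  if (x$degenerate)
    cat("  note: all coordinates identical; ties broken by index order\n")
  invisible(x)
}

#' All pairwise KNN tests between diet-item categories
#'
#' Runs the KNN randomisation test on every pair of categories over their
#' shared isotope channels, and derives the Bonferroni-adjusted per-test
#' threshold `family_alpha / m` from the number of pairs actually tested
#' (for the study's five categories, m = 10 gives 0.005). Each pair uses an
#' independent RNG substream derived from `seed`, so results do not depend
#' on the order in which pairs are run.
#'
#' @param samples Source-sample data.frame with `category` plus isotope
#'   channel columns.
#' @param family_alpha Familywise error target (default 0.05).
#' @param k,n_perm,seed Passed to [knn_randomization_test()].
#' @param channels Channels to use; default those measured in all samples.
#' @return A list of class `pairwise_knn`: `p_matrix` (symmetric, NA
#'   diagonal), `alpha_adjusted`, `m`, `k`, `tests`, `dropped` (categories
#'   with fewer than 2 samples, excluded with a warning).
#' @export
pairwise_source_tests <- function(samples, family_alpha = 0.05, k = 3,
                                  n_perm = 999, seed = 1,
                                  channels = shared_channels(samples)) {
  if (!length(channels)) stop("no shared isotope channels")
  counts <- table(samples$category)
  dropped <- names(counts)[counts < 2]
  if (length(dropped))
    warning("categories with < 2 samples excluded: ",
            paste(dropped, collapse = ", "))
  cats <- sort(names(counts)[counts >= 2])
  if (length(cats) < 2) stop("need at least 2 testable categories")
  m <- choose(length(cats), 2)
  if (1 / (n_perm + 1) > family_alpha / m)
    warning("permutation p-value floor 1/(n_perm+1) exceeds the ",
            "Bonferroni-adjusted threshold; no pair can test significant. ",
            "Increase n_perm.")
  pm <- matrix(NA_real_, length(cats), length(cats),
               dimnames = list(cats, cats))
  tests <- list()
  pair_id <- 0L
  for (i in seq_along(cats)[-length(cats)]) for (j in (i + 1):length(cats)) {
    pair_id <- pair_id + 1L
    ai <- as.matrix(samples[samples$category == cats[i], channels])
    bj <- as.matrix(samples[samples$category == cats[j], channels])
    tt <- knn_randomization_test(ai, bj, k = k, n_perm = n_perm,
                                 seed = seed + 7919L * pair_id)
    pm[i, j] <- pm[j, i] <- tt$p_value
    tests[[paste(cats[i], cats[j], sep = " vs ")]] <- tt
  }
  structure(list(p_matrix = pm, alpha_adjusted = family_alpha / m, m = m,
                 family_alpha = family_alpha, k = k, tests = tests,
                 dropped = dropped, channels = channels),
            class = "pairwise_knn")
}

#' @export
print.pairwise_knn <- function(x, ...) {
  cat(sprintf(
    "Pairwise KNN tests: %d pairs, Bonferroni-adjusted alpha = %.4g\n",
    x$m, x$alpha_adjusted))
  print(round(x$p_matrix, 4))
  invisible(x)
}

#' Pool isotopically indistinguishable diet-item categories
#'
#' Categories connected (transitively) by pairs whose p-value is at or
#' above the adjusted threshold are pooled into one group; pooled group
#' statistics are recomputed from the union of member samples, and pooled
#' names concatenate the members alphabetically with `+`. When transitive
#' closure merges a pair that individually tested significant, the result
#' is flagged.
#'
#' @param tests A [pairwise_source_tests()] result (or a list with
#'   `p_matrix` and `alpha_adjusted`).
#' @param samples The source samples the tests were run on.
#' @param channels Channels for the pooled group statistics.
#' @return A list of class `source_partition`: `mapping` (data.frame
#'   category -> group), `groups` (a [source_groups()] object),
#'   `alpha_adjusted`, `p_matrix`, `merged_significant_pair`.
#' @export
merge_sources <- function(tests, samples,
                          channels = shared_channels(samples)) {
  pm <- tests$p_matrix
  alpha <- tests$alpha_adjusted
  cats <- rownames(pm)
  # union-find over non-significant pairs
  parent <- seq_along(cats)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(cats)[-length(cats)]) for (j in (i + 1):length(cats))
    if (!is.na(pm[i, j]) && pm[i, j] >= alpha) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  comp <- vapply(seq_along(cats), find, integer(1))
  merged_sig <- FALSE
  for (i in seq_along(cats)[-length(cats)]) for (j in (i + 1):length(cats))
    if (comp[i] == comp[j] && !is.na(pm[i, j]) && pm[i, j] < alpha)
      merged_sig <- TRUE
  group_of <- vapply(seq_along(cats), function(i)
    paste(sort(cats[comp == comp[i]]), collapse = "+"), character(1))
  mapping <- data.frame(category = cats, group = group_of)
  pooled <- samples[samples$category %in% cats, , drop = FALSE]
  pooled$category <- mapping$group[match(pooled$category, mapping$category)]
  structure(list(mapping = mapping,
                 groups = source_groups(pooled, channels),
                 alpha_adjusted = alpha, p_matrix = pm,
                 merged_significant_pair = merged_sig),
            class = "source_partition")
}

#' @export
print.source_partition <- function(x, ...) {
  cat("Source partition (adjusted alpha =", format(x$alpha_adjusted), ")\n")
  for (g in unique(x$mapping$group))
    cat("  ", g, "\n")
  if (x$merged_significant_pair)
    cat("  note: transitive closure merged a significant pair\n")
  invisible(x)
}
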