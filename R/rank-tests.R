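# Nonparametric comparisons of isotope values across periods and
# subgroups: Kruskal-Wallis, Steel-Dwass all-pairs, Wilcoxon rank-sum.

rank_test_result <- function(statistic, df, p_value, method, groups, n) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, groups = groups, n = n),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, ": ", names(x$statistic), " = ",
      format(x$statistic, digits = 5),
      if (!is.null(x$df)) paste0(", ", x$df, " df"),
      ", p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis test of identical location across two or
#' more groups, with the statistic referred to a chi-squared distribution
#' on (number of groups - 1) degrees of freedom. The statistic is reported
#' under the letter `W`, the label used in historical-ecology reports of
#' this test; it is the standard H.
#'
#' @param values A named list of numeric vectors, one per group.
#' @return A `rank_test` object with `statistic` (`W`), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values) {
  if (length(values) < 2) stop("need at least 2 groups")
  n <- vapply(values, length, integer(1))
  if (any(n < 1) || sum(n) < 3) stop("each group needs data; total n >= 3")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values) %||% seq_along(values), n))
  if (length(unique(x)) == 1L)
    return(rank_test_result(c(W = 0), length(values) - 1L, 1,
                            "Kruskal-Wallis rank test",
                            levels(g), as.integer(n)))
  kt <- stats::kruskal.test(x, g)
  rank_test_result(c(W = unname(kt$statistic)),
                   unname(kt$parameter), kt$p.value,
                   "Kruskal-Wallis rank test", levels(g), as.integer(n))
}

# Standardized two-sample rank statistic for one pair, tie-corrected.
sd_pair_stat <- function(a, b) {
  ni <- length(a); nj <- length(b); N <- ni + nj
  r <- rank(c(a, b))
  R <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(c(t = 0, var = V))
  c(t = (R - E) / sqrt(V), var = V)
}

#' Steel-Dwass all-pairs nonparametric comparisons
#'
#' For each pair of groups, ranks are computed within the pair only and the
#' standardized rank-sum statistic (tie-corrected variance) is referred to
#' the studentized-range distribution with the total number of groups,
#' making the familywise pairwise p-values jointly valid at their nominal
#' level without further adjustment. A per-pair permutation variant is
#' available for small samples (`method = "permutation"`); it reports the
#' exact within-pair two-sided permutation p-value of the standardized
#' statistic, enumerated exhaustively when the pair admits at most
#' `max_enum` splits and sampled otherwise.
#'
#' @param values A named list of numeric vectors, one per group (>= 2
#'   observations each; >= 3 groups recommended).
#' @param method `"asymptotic"` (studentized range) or `"permutation"`.
#' @param n_perm Random permutations per pair when enumeration is too big.
#' @param max_enum Enumeration limit on choose(N, n_i) per pair.
#' @param seed RNG seed for the sampled-permutation fallback.
#' @return A data.frame with one row per pair: `group_a`, `group_b`,
#'   `statistic` (standardized), `p_value`, `method`.
#' @export
steel_dwass <- function(values, method = c("asymptotic", "permutation"),
                        n_perm = 9999, max_enum = 200000, seed = 1) {
  method <- match.arg(method)
  g <- length(values)
  if (g < 2) stop("need at least 2 groups")
  n <- vapply(values, length, integer(1))
  if (any(n < 2)) stop("each group needs at least 2 observations")
  nms <- names(values) %||% as.character(seq_len(g))
  rows <- list()
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    a <- values[[i]]; b <- values[[j]]
    st <- sd_pair_stat(a, b)
    if (st[["var"]] <= 0) {        # all pooled values identical
      p <- 1; tval <- 0; meth <- method
    } else if (method == "asymptotic") {
      tval <- st[["t"]]
      p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = g, df = Inf,
                         lower.tail = FALSE)
      meth <- "studentized-range asymptotic"
    } else {
      tval <- st[["t"]]
      pool <- c(a, b); ni <- length(a); N <- length(pool)
      if (choose(N, ni) <= max_enum) {
        splits <- utils::combn(N, ni)
        tstar <- apply(splits, 2, function(ix)
          abs(sd_pair_stat(pool[ix], pool[-ix])[["t"]]))
        p <- mean(tstar >= abs(tval) - 1e-12)
        meth <- "exact within-pair permutation"
      } else {
        old <- get0(".Random.seed", globalenv())
        set.seed(seed + 1000L * i + j)
        tstar <- replicate(n_perm, {
          ix <- sample.int(N, ni)
          abs(sd_pair_stat(pool[ix], pool[-ix])[["t"]])
        })
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        p <- (1 + sum(tstar >= abs(tval) - 1e-12)) / (1 + n_perm)
        meth <- "sampled within-pair permutation"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = nms[i], group_b = nms[j], n_a = n[i], n_b = n[j],
      statistic = tval, p_value = p, method = meth)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact rank-sum distribution when the combined sample size is at
#' most 20 and there are no ties, and the normal approximation with
#' continuity correction otherwise; the variant used is recorded in the
#' result's `method`.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return A `rank_test` object with the rank-sum statistic `U` and
#'   two-sided `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  rank_test_result(c(U = unname(wt$statistic)), NULL, wt$p.value,
                   paste0("Wilcoxon rank-sum (",
                          if (exact) "exact" else
                            "normal approximation, continuity-corrected",
                          ")"),
                   c("a", "b"), c(length(a), length(b)))
}
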