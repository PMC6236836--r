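#' Pooled-variance two-sample t-test
#'
#' Student's t-test for independent samples with pooled variance and a
#' two-tailed p-value on `n1 + n2 - 2` degrees of freedom.  Degenerate
#' inputs are handled explicitly: zero pooled variance with equal means
#' gives `t = 0, p = 1`; zero pooled variance with unequal means gives
#' `t = Inf` (signed) and `p = 0`, flagged with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors, each of length >= 2 with finite values.
#' @return list with `t`, `p`, `df`, and `degenerate`.
#' @examples
#' t_test_two_group(c(1, 2, 3), c(4, 5, 6))  # |t| = 3.674, p = 0.0214
#' @export
t_test_two_group <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(c(x, y))))
  df <- length(x) + length(y) - 2
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (pooled == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = df, degenerate = FALSE)
}

#' One-way ANOVA across three or more groups
#'
#' Equal-variance one-way analysis of variance, used for the flip-angle
#' contrast where more than two levels are compared; for exactly two groups
#' `F` equals the squared pooled t statistic.  All groups identical gives
#' `F = 0, p = 1`.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, and degrees of freedom `df1`, `df2`.
#' @export
anova_multi_group <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  df1 <- length(groups) - 1L
  df2 <- sum(lengths(groups)) - length(groups)
  if (all(vapply(groups, stats::var, 1) == 0) &&
      length(unique(vapply(groups, mean, 1))) == 1)
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value, df1 = df1, df2 = df2)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: with `m` tests and sorted
#' p-values `p_(1) <= ... <= p_(m)`,
#' `q_(k) = min_{j >= k} (m p_(j) / j)`, capped at 1.  Ties keep their
#' original order; `NA` p-values stay `NA` and do not count toward `m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order as the input.
#' @examples
#' benjamini_hochberg(c(0.005, 0.1))  # 0.01, 0.1
#' @export
benjamini_hochberg <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(q)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(adj)))       # step-up minimum from the largest p down
  adj <- pmin(adj, 1)
  qo <- numeric(m)
  qo[o] <- adj
  q[ok] <- qo
  q
}

#' Test every feature for sensitivity to one acquisition contrast
#'
#' For each feature column, compares slices across the levels of the
#' contrast variable: two levels use the pooled two-sample t-test, three or
#' more (the flip-angle contrast) one-way ANOVA.  The Benjamini-Hochberg
#' family is the set of features tested within this one contrast.
#'
#' @param features data frame with one row per slice: feature columns plus a
#'   grouping column named by `contrast`.
#' @param contrast name of the grouping column (e.g. `"NEX"`).
#' @param feature_cols feature column names; default the 41 core features
#'   (one Benjamini-Hochberg family of 41 tests, matching the emulated
#'   study's per-table correction).  Pass
#'   `c(feature_names()$core, feature_names()$extras)` to include the three
#'   report extras in the family.
#' @param alpha significance level applied to q-values (default 0.05).
#' @return data frame of class `comparison_result`, one row per feature:
#'   per-level `mean_*`, `sd_*`, `n_*`, the test statistic, `p_value`,
#'   `q_value`, `significant`.
#' @export
run_contrast <- function(features, contrast, feature_cols = NULL,
                         alpha = 0.05) {
  stopifnot(is.data.frame(features), contrast %in% names(features))
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_names()$core, names(features))
  }
  stopifnot(length(feature_cols) > 0, all(feature_cols %in% names(features)))
  g <- factor(features[[contrast]])
  lev <- levels(g)
  if (length(lev) < 2) stop("contrast '", contrast, "' has fewer than 2 levels")

  rows <- lapply(feature_cols, function(fc) {
    byg <- split(features[[fc]], g)
    stat_cols <- unlist(lapply(lev, function(l) {
      v <- byg[[l]]
      stats::setNames(c(mean(v), stats::sd(v), length(v)),
                      paste0(c("mean_", "sd_", "n_"), l))
    }))
    res <- if (length(lev) == 2) {
      tt <- t_test_two_group(byg[[1]], byg[[2]])
      c(statistic = tt$t, p_value = tt$p)
    } else {
      av <- anova_multi_group(byg)
      c(statistic = av$F, p_value = av$p)
    }
    c(stat_cols, res)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(feature = feature_cols, out, stringsAsFactors = FALSE)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  attr(out, "contrast") <- contrast
  attr(out, "levels") <- lev
  attr(out, "test") <- if (length(lev) == 2) "pooled t" else "one-way ANOVA"
  class(out) <- c("comparison_result", "data.frame")
  out
}
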