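# Nonparametric statistics: two-sample Kolmogorov-Smirnov with the
# block-pooling rule, and Kruskal-Wallis with Dunn's post hoc test.

new_gold_test <- function(method, statistic, p_value, ...) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = unname(p_value)), list(...)),
            class = "gold_test")
}

#' @export
print.gold_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

# Asymptotic two-sided Kolmogorov distribution tail Q(lambda).
kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the exact supremum of the absolute difference between
#' the two empirical distribution functions, evaluated over the pooled
#' sample points (ties handled exactly). The two-sided p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n1 n2 / (n1 + n2)`; for small samples (both n <= 10, or `exact = TRUE`)
#' the exact p-value is used instead.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @param exact Logical or `NULL` (default: exact iff both n <= 10).
#' @return A `gold_test` with fields `statistic` (D), `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("ks_two_sample: empty sample")
  if (length(x) < 2 || length(y) < 2)
    stop("ks_two_sample: each sample needs at least 2 observations")
  n1 <- length(x); n2 <- length(y)
  v <- sort(unique(c(x, y)))
  f1 <- findInterval(v, sort(x)) / n1
  f2 <- findInterval(v, sort(y)) / n2
  D <- max(abs(f1 - f2))
  use_exact <- if (is.null(exact)) (n1 <= 10 && n2 <= 10) else isTRUE(exact)
  p <- if (use_exact) {
    suppressWarnings(stats::ks.test(x, y, exact = TRUE)$p.value)
  } else {
    ne <- n1 * n2 / (n1 + n2)
    kolmogorov_tail(sqrt(ne) * D)
  }
  new_gold_test("Two-sample Kolmogorov-Smirnov", D, p, n1 = n1, n2 = n2)
}

#' Block-pooling rule for distance samples
#'
#' Data from separate blocks (animals) are merged only when no pairwise
#' two-sample Kolmogorov-Smirnov comparison finds a significant difference:
#' pooling happens iff the minimum pairwise p-value is at least `alpha`.
#' Otherwise pooling is refused and the per-block samples are returned. A
#' single block pools trivially with the decision flagged `"not tested"`.
#'
#' @param samples Named list of numeric per-block samples.
#' @param alpha Decision threshold (default 0.05).
#' @return An object of class `pooling_check`: list with `pooled` (logical),
#'   `sample` (pooled vector or `NULL`), `blocks` (the input), `pairwise`
#'   (data frame of pairwise KS results or `NULL`), `min_p`, `decision`.
#' @export
pooling_check <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("block", seq_along(samples))
  if (length(samples) == 1) {
    return(structure(list(pooled = TRUE, sample = samples[[1]],
                          blocks = samples, pairwise = NULL, min_p = NA_real_,
                          decision = "not tested", alpha = alpha),
                     class = "pooling_check"))
  }
  cmb <- utils::combn(names(samples), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    ks <- ks_two_sample(samples[[a]], samples[[b]])
    data.frame(block1 = a, block2 = b, statistic = ks$statistic,
               p_value = ks$p_value, stringsAsFactors = FALSE)
  }))
  min_p <- min(pw$p_value)
  pooled <- min_p >= alpha
  structure(list(pooled = pooled,
                 sample = if (pooled) unname(unlist(samples)) else NULL,
                 blocks = samples, pairwise = pw, min_p = min_p,
                 decision = if (pooled) "pooled" else "pooling refused",
                 alpha = alpha),
            class = "pooling_check")
}

#' @export
print.pooling_check <- function(x, ...) {
  cat(sprintf("Pooling check (%d block(s)): %s", length(x$blocks), x$decision))
  if (!is.na(x$min_p)) cat(sprintf(" (min pairwise KS p = %.4g, alpha = %g)",
                                   x$min_p, x$alpha))
  cat("\n")
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis rank-sum test (with tie correction, chi-square p-value)
#' across named groups, followed when significant structure is of interest
#' by Dunn's z test for all pairs of groups, with multiplicity adjustment
#' (Bonferroni by default). If every observation is identical the H
#' statistic is 0 with p = 1 and no post hoc table is produced.
#'
#' @param groups Named list of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha Significance level used to flag pairs (default 0.05).
#' @param adjust Multiplicity adjustment method for the pairwise p-values
#'   (any method of [stats::p.adjust()]; default `"bonferroni"`).
#' @return A `gold_test` with fields `statistic` (H), `p_value`, `df`,
#'   `group_sizes`, and `pairwise` (data frame with Dunn z, unadjusted and
#'   adjusted p-values, and a significance flag), or `pairwise = NULL` for
#'   degenerate input.
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 2))
    stop("kruskal_dunn: each group needs at least 2 observations")
  values <- unname(unlist(groups))
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(values)) == 1) {
    return(new_gold_test("Kruskal-Wallis (Dunn post hoc)", 0, 1,
                         df = length(groups) - 1L,
                         group_sizes = lengths(groups), pairwise = NULL,
                         adjust = adjust, alpha = alpha))
  }
  kw <- stats::kruskal.test(values, g)
  # Dunn's z for all pairs, from pooled mid-ranks with tie correction
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    z <- (rbar[[a]] - rbar[[b]]) / sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    data.frame(group1 = a, group2 = b, z = z,
               p_unadjusted = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_unadjusted, method = adjust)
  pw$significant <- pw$p_adjusted < alpha
  new_gold_test("Kruskal-Wallis (Dunn post hoc)",
                kw$statistic, kw$p.value, df = unname(kw$parameter),
                group_sizes = lengths(groups), pairwise = pw,
                adjust = adjust, alpha = alpha)
}

#' Write test results as TSV
#'
#' One row per test: method, statistic, p-value and (where applicable) the
#' pooling decision. UTF-8, LF, tab-separated.
#'
#' @param tests A `gold_test`/`pooling_check` or list of them.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_stats_tsv <- function(tests, path) {
  if (inherits(tests, c("gold_test", "pooling_check"))) tests <- list(tests)
  rows <- lapply(tests, function(t) {
    if (inherits(t, "pooling_check"))
      data.frame(method = "Pairwise KS pooling rule",
                 statistic = NA_real_, p_value = t$min_p,
                 pooling_decision = t$decision, stringsAsFactors = FALSE)
    else
      data.frame(method = t$method, statistic = t$statistic,
                 p_value = t$p_value, pooling_decision = NA_character_,
                 stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

# Deterministic TSV writer: UTF-8, LF, '.' decimal (internal).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
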