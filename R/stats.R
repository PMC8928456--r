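# Elementary two-sample tests with the exact conventions the pipeline
# relies on: Mann-Whitney U (exact small-sample null, tie-corrected normal
# approximation otherwise), Pearson chi-square without continuity
# correction, and the Welch t test.

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of (x, y) pairs with x > y, counting ties as 1/2
#' (computed from rank sums).  When both samples have at most 8
#' observations and there are no ties, the exact null distribution of U
#' is used; otherwise the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (U for `x`), `p.value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 8 && n2 <= 8) {
    p <- 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))
    method <- "exact"
  } else {
    t_tab <- table(r)
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) return(list(statistic = u, p.value = 1,
                                 method = "normal approximation (degenerate)"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    if (u == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = unname(u), p.value = min(p, 1), method = method)
}

#' Pearson chi-square test of homogeneity
#'
#' No continuity correction at any table size.  A table with an all-zero
#' row or column is degenerate: the p-value is `NA` with `undefined =
#' TRUE` (never 1).
#'
#' @param contingency matrix/table of non-negative counts (at least 2x2).
#' @return list with `statistic`, `df`, `p.value`, `undefined`.
#' @export
chi_square <- function(contingency) {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must contain non-negative integer counts",
         call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2x2", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    return(list(statistic = NA_real_,
                df = (nrow(tab) - 1) * (ncol(tab) - 1),
                p.value = NA_real_, undefined = TRUE))
  e <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), undefined = FALSE)
}

#' Welch two-sample t test (two-sided)
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom.  When
#' both samples have zero variance: equal means give p = 1 (flagged);
#' unequal means give p = 0 with an infinite statistic (flagged).
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list with `statistic`, `df`, `p.value`, `degenerate`.
#' @export
t_test_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples must have at least 2 observations", call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  m1 <- mean(x); m2 <- mean(y)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2)
      return(list(statistic = 0, df = NA_real_, p.value = 1,
                  degenerate = TRUE))
    return(list(statistic = sign(m1 - m2) * Inf, df = NA_real_,
                p.value = 0, degenerate = TRUE))
  }
  se2 <- v1 / length(x) + v2 / length(y)
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x)^2 * (length(x) - 1)) +
                   v2^2 / (length(y)^2 * (length(y) - 1)))
  list(statistic = stat, df = df,
       p.value = 2 * pt(-abs(stat), df), degenerate = FALSE)
}
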