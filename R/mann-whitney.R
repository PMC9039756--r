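#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for sample sizes `m` and `n` without ties, the number of rank
#' assignments giving each U value, by the standard lattice recursion.
#'
#' @param m,n Group sizes.
#' @return Numeric vector of length `m * n + 1`; element `u + 1` is the
#'   probability of observing `U = u` under the null.
#' @keywords internal
mw_exact_null <- function(m, n) {
  # N(u; i, j) = N(u - j; i - 1, j) + N(u; i, j - 1): the largest pooled
  # value comes either from A (adding j concordant pairs) or from B
  maxu <- m * n
  unit <- function() { v <- numeric(maxu + 1); v[1] <- 1; v }
  g <- replicate(n + 1, unit(), simplify = FALSE)  # i = 0 row: U = 0 always
  for (i in seq_len(m)) {
    newg <- vector("list", n + 1)
    newg[[1]] <- unit()
    for (j in seq_len(n)) {
      shifted <- c(numeric(j), g[[j + 1]])[seq_len(maxu + 1)]
      newg[[j + 1]] <- shifted + newg[[j]]
    }
    g <- newg
  }
  g[[n + 1]] / choose(m + n, n)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test comparing two groups of values. In `"exact"` mode the p
#' value is computed from the exact permutation null of U (untied data); in
#' `"normal"` mode from the normal approximation with tie and continuity
#' correction. `"auto"` uses the exact null when `n1 * n2 <= 400` and the
#' data contain no ties, otherwise the normal approximation.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @param feature Optional label carried into the result.
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble: `feature`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `u_statistic`, `p_value`, `direction` (which group has the larger
#'   median, or `"none"`), `mode_used`.
#' @export
mann_whitney <- function(values_a, values_b, mode = c("auto", "exact", "normal"),
                         feature = NA_character_,
                         labels = c("a", "b")) {
  mode <- match.arg(mode)
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  m <- length(values_a); n <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else if (mode == "exact" || (mode == "auto" && m * n <= 400 && !has_ties)) {
    if (has_ties) {
      abort("exact Mann-Whitney mode requires untied data; use mode = 'normal'")
    }
    null <- mw_exact_null(m, n)
    # symmetric null: two-sided p sums both tails at least as extreme
    dev <- abs(seq(0, m * n) - m * n / 2)
    p <- min(1, sum(null[dev >= abs(u - m * n / 2)]))
    mode <- "exact"
  } else {
    mu <- m * n / 2
    nt <- m + n
    ties <- table(pooled)
    sigma2 <- m * n / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    mode <- "normal"
  }

  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  direction <- if (med_a > med_b) labels[1] else if (med_b > med_a) labels[2] else "none"
  tibble(feature = feature, group_a = labels[1], group_b = labels[2],
         n_a = m, n_b = n, u_statistic = u, p_value = p,
         direction = direction, mode_used = mode)
}
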