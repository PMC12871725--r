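# Self-contained nonparametric kernels used by every stage.
# Base R's wilcox.test / kruskal.test / p.adjust are deliberately NOT called
# here: these functions are the package's own reference kernels with fully
# specified tie handling, and the base functions serve as independent
# cross-checks in the test suite.

new_test_result <- function(statistic, p_value, method, exact) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, exact = exact),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(x$method, if (x$exact) "(exact)" else "(approximate)", "\n")
  cat("  statistic =", format(x$statistic), "  p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The statistic is the rank sum of `x` in the pooled sample (mid-ranks for
#' ties). When both groups have at most `exact_max_n` observations and the
#' pooled sample is tie-free, the two-sided p-value is computed by complete
#' enumeration of the permutation distribution of the rank sum:
#' `p = P(|W - E W| >= |w - E W|)`. Otherwise a normal approximation with
#' tie-corrected variance and (optionally) a continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty
#' @param exact_max_n largest per-group size for exact enumeration (default 10)
#' @param correct apply the continuity correction in the normal approximation
#' @return an `np_test` with fields statistic, p_value, method, exact
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 10, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  mr <- midranks(pooled)                 # mid-ranks + tie-group sizes
  r <- mr$rank
  ties <- mr$tie_sizes
  has_ties <- any(ties > 1L)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2

  if (length(ties) == 1L) {              # fully degenerate: no information
    return(new_test_result(mu, 1, "Wilcoxon rank-sum", exact = FALSE))
  }

  if (!has_ties && nx <= exact_max_n && ny <= exact_max_n) {
    sums <- utils::combn(r, nx, sum)     # all C(n, nx) assignments
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(new_test_result(w, p, "Wilcoxon rank-sum", exact = TRUE))
  }

  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(new_test_result(mu, 1, "Wilcoxon rank-sum", exact = FALSE))
  }
  d <- w - mu
  if (correct) d <- sign(d) * max(0, abs(d) - 0.5)
  z <- d / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(w, p, "Wilcoxon rank-sum", exact = FALSE)
}

# mid-ranks via one radix sort; returns the tie-group sizes as a byproduct
midranks <- function(v) {
  n <- length(v)
  o <- order(v, method = "radix")
  s <- v[o]
  grp <- cumsum(c(TRUE, s[-1L] != s[-n]))
  cnt <- tabulate(grp)
  ends <- cumsum(cnt)
  mid <- ends - (cnt - 1) / 2
  r <- numeric(n)
  r[o] <- mid[grp]
  list(rank = r, tie_sizes = cnt)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-squared distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups list of at least two non-empty numeric vectors
#' @return an `np_test`
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis needs a list of at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- rle(sort(pooled))$lengths
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) {                       # every observation tied
    return(new_test_result(0, 1, "Kruskal-Wallis", exact = FALSE))
  }
  h <- h / corr
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  new_test_result(h, p, "Kruskal-Wallis", exact = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the adjusted p-values `q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / rank(j)`, clipped to 1, in the input order. `NA`/`NaN` entries
#' propagate and are excluded from `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same length and order
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)      # step-up from the largest p
  adj <- pmin(1, cummin(m / rev(seq_len(m)) * pv[o]))
  qq <- numeric(m)
  qq[o] <- adj
  q[ok] <- qq
  q
}
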