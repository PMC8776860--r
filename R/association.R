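#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test on `post - pre`. Zero differences are discarded
#' (classic convention, logged). For `n_used <= 25` the p-value is exact,
#' computed from the full null distribution of the signed-rank sum over all
#' 2^n sign assignments (dynamic programming over doubled average ranks, so
#' ties are handled exactly); for larger n the normal approximation with the
#' tie-corrected variance is used.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2).
#' @return A list of class `paired_test_result`: `statistic` (V, the sum of
#'   ranks of positive differences), `p_value`, `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  if (anyNA(d)) stop("missing values in paired differences", call. = FALSE)
  n_zero <- sum(d == 0)
  if (n_zero > 0L) {
    mx_log("wilcoxon signed-rank: %d zero difference(s) discarded", n_zero)
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all paired differences are zero; test degenerate", call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - n * (n + 1) / 4) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximation"
  }
  structure(list(statistic = v, p_value = min(p, 1), n_used = n,
                 method = method),
            class = "paired_test_result")
}

# Exact two-sided p for the signed-rank sum: distribution of S = sum of
# (doubled) ranks over positive-sign subsets via convolution; p is the
# probability mass at least as far from the (symmetric) center as observed.
signed_rank_exact_p <- function(ranks, v) {
  s <- as.integer(round(2 * ranks))   # average ranks are multiples of 1/2
  total <- sum(s)
  f <- numeric(total + 1L)            # f[k+1] = #subsets with doubled sum k
  f[1L] <- 1
  for (si in s) {
    shifted <- c(numeric(si), f[seq_len(total + 1L - si)])
    f <- f + shifted
  }
  v2 <- round(2 * v)
  mu <- total / 2
  dev <- abs(v2 - mu)
  k <- 0:total
  sum(f[abs(k - mu) >= dev - 1e-9]) / 2^length(s)
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.4g (n = %d, %s)\n",
              x$statistic, x$p_value, x$n_used, x$method))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Flagged-missing (`NA`) entries are removed pairwise (count logged). Ties
#' receive average ranks and rho is the Pearson correlation of the ranks, so
#' the estimate is invariant to strictly monotone transforms of either
#' argument. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 df (the method is recorded in
#' the result); an exact permutation p over all n! orderings is available
#' for n <= 10.
#'
#' @param x,y Equal-length numeric vectors with >= 3 complete pairs.
#' @param method `"t-approximation"` (default) or `"exact"` (n <= 10).
#' @return A list of class `spearman_result`: `rho`, `p_value`, `n`,
#'   `method`.
#' @export
spearman_cor <- function(x, y, method = c("t-approximation", "exact")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    mx_log("spearman: %d pair(s) with flagged-missing values excluded",
           n_dropped)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector; rho undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 10L) stop("exact permutation p limited to n <= 10", call. = FALSE)
    p <- spearman_exact_p(rx, ry, rho)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "spearman_result")
}

# Exact permutation p: P(|rho_perm| >= |rho_obs|) over all n! orderings of y.
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  count <- 0L
  total <- 0L
  idx <- seq_len(n)
  recurse <- function(perm, remaining) {
    if (length(remaining) == 0L) {
      r <- stats::cor(rx, ry[perm])
      total <<- total + 1L
      if (abs(r) >= abs(rho_obs) - 1e-12) count <<- count + 1L
      return(invisible(NULL))
    }
    for (j in remaining) {
      recurse(c(perm, j), setdiff(remaining, j))
    }
  }
  recurse(integer(0), idx)
  count / total
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman: rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' Quadratic least-squares fit with pointwise 95% confidence band
#'
#' Fits `y ~ 1 + x + x^2` by least squares and returns the fitted curve with
#' a pointwise confidence band from the t distribution with n - 3 df —
#' the scatter-plot visualization layer for the fold-change vs PFS panels.
#'
#' @param x,y Numeric vectors, n >= 4.
#' @param grid Evaluation points; default 100 points over `range(x)`.
#' @param level Confidence level, default 0.95.
#' @return A list of class `quad_fit`: `coefficients` (intercept, linear,
#'   quadratic), `band` (data.frame x, fit, lower, upper), `model` (the lm
#'   fit).
#' @export
quadratic_fit_ci <- function(x, y, grid = NULL, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("quadratic fit needs n >= 4", call. = FALSE)
  if (length(unique(x)) < 3L) {
    stop("collinear design: fewer than 3 distinct x values", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100L)
  pr <- stats::predict(fit, newdata = data.frame(x = grid),
                       interval = "confidence", level = level)
  structure(list(
    coefficients = stats::setNames(stats::coef(fit),
                                   c("intercept", "linear", "quadratic")),
    band = data.frame(x = grid, fit = pr[, "fit"], lower = pr[, "lwr"],
                      upper = pr[, "upr"]),
    model = fit
  ), class = "quad_fit")
}
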