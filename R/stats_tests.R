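# Rank and contingency tests with exact small-sample enumeration, matching
# the comparisons used in the report layer.

comparison_result <- function(test, statistic, p_value, alternative, n,
                              method, extra = NULL) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   alternative = alternative, n = n, method = method),
              extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s, %s): statistic = %.4g, p = %.4g, n = %s\n", x$test,
              x$method, x$alternative, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

# exact permutation distribution of the x-group rank sum (doubled average
# ranks, so sums are integers even with ties), by dynamic programming over
# "choose nx of n values summing to s"
ranksum_exact_dist <- function(s2, nx) {
  n <- length(s2)
  maxsum <- sum(sort(s2, decreasing = TRUE)[seq_len(nx)])
  dp <- matrix(0, nx + 1, maxsum + 1)
  dp[1, 1] <- 1
  for (v in s2) {
    kmax <- nx
    for (k in kmax:1) {
      src <- dp[k, 1:(maxsum + 1 - v)]
      if (any(src != 0))
        dp[k + 1, (v + 1):(maxsum + 1)] <-
          dp[k + 1, (v + 1):(maxsum + 1)] + src
    }
  }
  dp[nx + 1, ] / choose(n, nx)
}

#' Mann-Whitney U test
#'
#' U counts pairs (x_i, y_j) with x_i > y_j (ties contribute 1/2). When
#' n_x n_y <= 400 the p-value comes from the exact permutation distribution
#' of the rank sum (tie-aware, computed by dynamic programming over doubled
#' average ranks); otherwise from the tie-corrected normal approximation
#' with continuity correction. \code{alternative = "greater"} tests whether
#' x tends to exceed y.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative \code{"two.sided"}, \code{"greater"} or \code{"less"}.
#' @return A \code{"comparison_result"} with the U statistic.
#' @export
mwu <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  all_r <- rank(c(x, y))
  w_obs <- sum(all_r[seq_len(nx)])
  U <- w_obs - nx * (nx + 1) / 2
  if (nx * ny <= 400) {
    s2 <- round(2 * all_r)
    dist <- ranksum_exact_dist(s2, nx)
    w2 <- round(2 * w_obs)
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(all_r)
    mu <- nx * (n + 1) / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z_g <- (w_obs - 0.5 - mu) / sqrt(sig2)
    z_l <- (w_obs + 0.5 - mu) / sqrt(sig2)
    p <- switch(alternative,
                greater = pnorm(z_g, lower.tail = FALSE),
                less = pnorm(z_l),
                two.sided = min(1, 2 * min(pnorm(z_l),
                                           pnorm(z_g, lower.tail = FALSE))))
    method <- "normal approximation (tie-corrected)"
  }
  comparison_result("Mann-Whitney U", U, p, alternative, c(nx, ny), method)
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Spearman rank correlation test
#'
#' rho on average ranks. For n <= 8 the p-value is exact, from the full
#' permutation distribution of rho (ties included); otherwise from the
#' t-approximation t = rho sqrt((n-2)/(1-rho^2)).
#'
#' @param x,y numeric vectors, n >= 3.
#' @param alternative \code{"two.sided"}, \code{"greater"} or \code{"less"}.
#' @return A \code{"comparison_result"} with statistic rho.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(comparison_result("Spearman rank correlation", NA_real_,
                             NA_real_, alternative, n,
                             "degenerate (constant ranks)"))
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- all_perms(n)
    rhos <- apply(perms, 1, function(pm) cor(rx, ry[pm]))
    eps <- 1e-12
    p <- switch(alternative,
                greater = mean(rhos >= rho - eps),
                less = mean(rhos <= rho + eps),
                two.sided = mean(abs(rhos) >= abs(rho) - eps))
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p_g <- if (rho >= 1) 0 else 1
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_g <- pt(tstat, df = n - 2, lower.tail = FALSE)
    }
    p <- switch(alternative,
                greater = p_g,
                less = 1 - p_g,
                two.sided = min(1, 2 * min(p_g, 1 - p_g)))
    method <- "t approximation"
  }
  comparison_result("Spearman rank correlation", rho, p, alternative, n,
                    method)
}

#' Chi-squared test with Yates's continuity correction
#'
#' 2 x 2 contingency test (df = 1), delegating to
#' \code{stats::chisq.test(correct = TRUE)}.
#'
#' @param tab 2 x 2 matrix of non-negative counts.
#' @return A \code{"comparison_result"}.
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  comparison_result("chi-squared (Yates)", unname(ct$statistic),
                    unname(ct$p.value), "two.sided", sum(tab),
                    "Yates continuity correction")
}
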