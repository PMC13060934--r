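# Supporting statistics implemented from first principles: exact and
# normal-approximation Mann-Whitney U, Benjamini-Hochberg (and Bonferroni)
# correction, hypergeometric enrichment, Spearman correlation, trapezoidal
# AUC, relative growth, and the prevalence pre-filter for differential
# abundance.

#' Mann-Whitney U test
#'
#' The statistic is \eqn{U = \sum_{i,j} [x_i > y_j] + 1/2 [x_i = y_j]}.
#' In exact mode the null distribution of U is built by counting, over all
#' \eqn{\binom{n+m}{n}} group labelings of the pooled sample, the subsets of
#' midrank sums (a dynamic program over the doubled midranks, so ties are
#' handled exactly); the two-sided p doubles the smaller tail and is capped
#' at 1. In normal mode the tie-corrected normal approximation with
#' continuity correction is used. `mode = "auto"` picks exact when
#' `length(x) + length(y) <= 12`.
#'
#' @param x,y Numeric vectors (nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list (`TestResult`): `statistic` (U for `x`), `p_value`,
#'   `mode` used.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value # 1/3
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  n <- length(x)
  m <- length(y)
  N <- n + m
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal"
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  if (mode == "exact") {
    # distribution of the x-group midrank sum via subset-sum counting on
    # doubled midranks (integers even with ties)
    r2 <- as.integer(round(2 * r))
    s_obs <- sum(r2[seq_len(n)])
    max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
    # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
    counts <- matrix(0, nrow = n + 1L, ncol = max_sum + 1L)
    counts[1L, 1L] <- 1
    for (v in r2) {
      kmax <- n
      for (k in kmax:1L) {
        nz <- which(counts[k, ] > 0)
        if (!length(nz)) next
        dest <- nz + v
        dest_ok <- dest <= max_sum + 1L
        counts[k + 1L, dest[dest_ok]] <-
          counts[k + 1L, dest[dest_ok]] + counts[k, nz[dest_ok]]
      }
    }
    dist <- counts[n + 1L, ]
    total <- sum(dist)
    p_le <- sum(dist[seq_len(s_obs + 1L)]) / total
    p_ge <- sum(dist[(s_obs + 1L):(max_sum + 1L)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = U, p_value = p, mode = mode)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clipped at 1, with the
#' original order restored.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, `q >= p` elementwise.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Bonferroni-adjusted p-values
#'
#' @inheritParams bh_fdr
#' @return `pmin(p * length(p), 1)`.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(p * length(p), 1)
}

#' Hypergeometric enrichment (over-representation) test
#'
#' Survival probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}: drawing `n` taxon-associated
#' metabolites from `N` annotated metabolites of which `K` belong to the
#' sub-pathway, the chance of seeing `k` or more pathway members.
#' Computed as \eqn{\sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#' \binom{N}{n}} in log space.
#'
#' @param N Total metabolites annotated.
#' @param K Metabolites in the sub-pathway.
#' @param n Metabolites associated with the taxon.
#' @param k Associated metabolites within the sub-pathway.
#' @return A list (`TestResult`): `statistic` (= k), `p_value`.
#' @examples
#' hypergeom_enrichment(10, 5, 4, 4)$p_value # 5/210
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("N, K, n, k must be nonnegative integers")
  }
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(n, K)) stop("k must not exceed min(n, K)")
  if (k == 0) {
    p <- 1
  } else {
    i <- k:min(n, K)
    log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(log_terms)
    p <- min(1, exp(mx) * sum(exp(log_terms - mx)))
  }
  list(statistic = k, p_value = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. For `n >= 10` the p-value uses the
#' t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}; for smaller
#' samples the exact permutation distribution over all `n!` orderings is
#' enumerated (two-sided: proportion of permutations with
#' \eqn{|\rho| \ge |\rho_{obs}|}).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A list (`TestResult`): `statistic` (rho), `p_value`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  rho <- sum(cx * cy) / denom
  if (n >= 10L) {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tval), df = n - 2))
    method <- "t-approximation"
  } else {
    # rho under all permutations of the x ranks against the fixed y ranks
    perms <- .permutations(n)
    rho_all <- as.numeric(matrix(cx[perms], nrow = nrow(perms)) %*% cy) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  }
  list(statistic = rho, p_value = p, method = method)
}

# All permutations of 1..n as a matrix (n! rows); n <= 9 in practice.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Trapezoidal area under the curve
#'
#' \eqn{\sum_i (v_i + v_{i+1})(t_{i+1} - t_i)/2}; the standard rule for
#' glucose-tolerance AUC over time points in minutes.
#'
#' @param times Strictly increasing numeric vector (length `>= 2`).
#' @param values Numeric vector of the same length.
#' @return The area.
#' @examples
#' trapezoid_auc(c(0, 15, 30), c(100, 150, 100)) # 3750
#' @export
trapezoid_auc <- function(times, values) {
  if (length(times) != length(values)) stop("times and values must match")
  if (length(times) < 2L) stop("need at least two time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum((values[-1] + values[-length(values)]) / 2 * diff(times))
}

#' Relative growth from optical densities
#'
#' Ratio of optical densities with versus without supplementation.
#' Replicate vectors are averaged first, so triplicates give
#' `mean(condition) / mean(reference)`.
#'
#' @param od_condition OD600 value(s) with supplementation.
#' @param od_reference OD600 value(s) without supplementation; mean must be
#'   positive.
#' @return The ratio.
#' @export
relative_growth <- function(od_condition, od_reference) {
  if (!length(od_reference) || mean(od_reference) <= 0) {
    stop("reference OD must be positive")
  }
  mean(od_condition) / mean(od_reference)
}

#' Prevalence pre-filter for differential abundance
#'
#' Drops features (rows) observed in fewer than `min_prevalence` of the
#' samples (columns); a feature present in exactly the threshold fraction
#' is retained.
#'
#' @param abundance Numeric matrix or data.frame, features x samples.
#' @param min_prevalence Minimum fraction of samples with nonzero abundance
#'   (default 0.20).
#' @return The filtered matrix/data.frame.
#' @export
prevalence_filter <- function(abundance, min_prevalence = 0.20) {
  prev <- rowMeans(abundance > 0)
  abundance[prev >= min_prevalence, , drop = FALSE]
}
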