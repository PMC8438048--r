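# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where possible, the stats functions) they check.

# Score binning via an explicit lookup table over the 16 bins.
oracle_score <- function(x) {
  breaks <- c(-Inf, seq(0, 70, by = 5), Inf)
  levels <- c(0, seq(0.1, 1.4, by = 0.1), 1.5, 1.5)
  vapply(x, function(v) levels[[findInterval(v, breaks)]], numeric(1))
}

# Two-sided minimum-likelihood Fisher p by direct enumeration with choose().
# Tables whose probability ties the observed one to within float fuzz may or
# may not be counted depending on rounding, so the oracle returns inclusion
# bounds: the true p must lie between "strictly smaller terms only" and
# "all terms up to a loose tie tolerance".
oracle_fisher_p_bounds <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  pr <- vapply(support, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  pobs <- pr[support == a]
  c(lo = sum(pr[pr <= pobs * (1 - 1e-6)]),
    hi = sum(pr[pr <= pobs * (1 + 1e-6)]))
}

expect_p_within_enumeration <- function(p, a, b, c, d) {
  bounds <- oracle_fisher_p_bounds(a, b, c, d)
  expect_gte(p, bounds[["lo"]] - 1e-10)
  expect_lte(p, bounds[["hi"]] + 1e-10)
}

# Central two-sided exact p by tail enumeration.
oracle_central_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  pr <- vapply(support, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  min(1, 2 * min(sum(pr[support <= a]), sum(pr[support >= a])))
}

# Conditional-MLE odds ratio: the psi making the conditional (noncentral
# hypergeometric) expectation of the a-cell equal its observed value.
oracle_cond_mle_or <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  if (a <= min(support)) return(if (a < min(support)) NA_real_ else 0)
  if (a >= max(support)) return(Inf)
  lw <- lchoose(m1, support) + lchoose(m2, k - support)
  f <- function(lpsi) {
    lp <- lw + support * lpsi
    p <- exp(lp - max(lp))
    sum(support * p) / sum(p) - a
  }
  exp(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root)
}

# Benjamini-Hochberg by explicit sort and cumulative minimum.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Complete-linkage agglomeration in O(n^3): repeatedly merge the cluster
# pair with the smallest maximum inter-point distance.
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in 2:length(clusters)) {
      for (j in 1:(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
    clusters[[bi]] <- NULL
  }
  heights
}

# A small cohort configuration most tests share: quick to generate but with
# every structural feature (planted pairs, undetected antigens, missingness).
small_config <- function(seed = 1, n_planted = 3, ...) {
  args <- list(
    n_individuals = 200, n_antigens = 80, n_symptoms = 40,
    n_planted = n_planted, spike_rate = 8 / 80, n_undetected = 10,
    planted_margins = list(n_pos = 20, prev_pos = 0.96, prev_neg = 0.40),
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}
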