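# Shared 2x2 exact-test machinery: tabulation, two-sided exact p, conditional
# MLE odds ratio with exact CI, and median dichotomization of continuous
# variables. All association and characterization modules route through here.

#' Cross-tabulate a seropositivity call vector against a dichotomous variable
#'
#' Builds the 2x2 table (pos & sx, pos & !sx; neg & sx, neg & !sx) with
#' pairwise-complete handling of missingness: individuals with a missing
#' value in either vector are dropped from this table only.
#'
#' @param calls Binary vector (0/1), seropositivity for one antigen.
#' @param sx Binary vector (0/1, NA allowed), symptom or clinical indicator.
#' @return 2x2 integer matrix, rows = call (pos, neg), cols = sx (yes, no).
#' @export
tabulate_pair <- function(calls, sx) {
  if (length(calls) != length(sx)) {
    stop("'calls' and 'sx' must have the same length", call. = FALSE)
  }
  keep <- !is.na(calls) & !is.na(sx)
  if (!any(keep)) stop("no pairwise-complete observations", call. = FALSE)
  calls <- calls[keep]; sx <- sx[keep]
  matrix(c(sum(calls == 1 & sx == 1), sum(calls == 1 & sx == 0),
           sum(calls == 0 & sx == 1), sum(calls == 0 & sx == 0)),
         nrow = 2, byrow = TRUE,
         dimnames = list(call = c("pos", "neg"), sx = c("yes", "no")))
}

# Two-sided exact p for a 2x2 table given as cells a,b,c,d (rows pos/neg,
# cols yes/no), conditioning on all margins.
#   minlike: sum of hypergeometric probabilities <= P(observed) — the
#            classical two-sided Fisher p (stats::fisher.test).
#   central: 2 * min(lower tail, upper tail), capped at 1.
# Vectorized over cells; used for the (antigen, symptom) screen where
# tens of thousands of tables are tested.
exact_p22 <- function(a, b, c, d, method = c("minlike", "central")) {
  method <- match.arg(method)
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]   # positives
    m2 <- c[i] + d[i]   # negatives
    k  <- a[i] + c[i]   # with symptom
    if (method == "central") {
      pl <- stats::phyper(a[i], m1, m2, k)
      pu <- stats::phyper(a[i] - 1, m1, m2, k, lower.tail = FALSE)
      out[i] <- min(1, 2 * min(pl, pu))
    } else {
      support <- max(0, k - m2):min(k, m1)
      probs <- stats::dhyper(support, m1, m2, k)
      pobs <- stats::dhyper(a[i], m1, m2, k)
      out[i] <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
    }
  }
  out
}

#' Exact test and odds ratio for a 2x2 table
#'
#' Two-sided exact test with the conditional maximum-likelihood odds ratio
#' and exact 95\% confidence interval, the procedure used throughout the
#' pipeline for dichotomous associations. `method = "minlike"` (default)
#' sums hypergeometric probabilities no larger than the observed table's —
#' the classical two-sided Fisher p reported by [stats::fisher.test()];
#' `method = "central"` doubles the smaller tail. Zero cells yield `0` or
#' `Inf` estimates and bounds.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows: pos/neg,
#'   cols: outcome yes/no), e.g. from [tabulate_pair()].
#' @param method Two-sided p-value construction; see Details.
#' @param conf_level Confidence level of the exact interval; default 0.95.
#' @return List: `p`, `or` (conditional MLE), `ci` (length-2 numeric, exact
#'   central interval; bounds may be 0 or Inf), `table`.
#' @examples
#' exact_or(matrix(c(21, 2, 241, 197), 2, byrow = TRUE))
#' @export
exact_or <- function(tab, method = c("minlike", "central"), conf_level = 0.95) {
  method <- match.arg(method)
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2))) {
    stop("'tab' must be a 2x2 matrix", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("'tab' must contain non-negative integer counts", call. = FALSE)
  }
  if (sum(tab) == 0) stop("'tab' must have a positive grand total", call. = FALSE)
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  p <- if (method == "minlike") {
    unname(ft$p.value)
  } else {
    exact_p22(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], method = "central")
  }
  list(p = p, or = unname(ft$estimate), ci = unname(ft$conf.int), table = tab)
}

#' Median-dichotomize a continuous variable
#'
#' Splits a continuous measurement (e.g. a cytokine concentration) at its
#' median, with the median itself included in the lower interval: values
#' strictly above the median are coded 1 ("above median"), values at or
#' below it 0. Missing values stay missing; the median is computed over
#' observed values.
#'
#' @param x Numeric vector.
#' @return Integer vector of 0/1/NA, attribute `median` holding the split.
#' @examples
#' median_dichotomize(c(1, 2, 3, 4)) # 0 0 1 1 (median 2.5)
#' median_dichotomize(c(1, 2, 3))    # 0 0 1 (median value itself goes low)
#' @export
median_dichotomize <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  med <- stats::median(x, na.rm = TRUE)
  out <- ifelse(is.na(x), NA_integer_, as.integer(x > med))
  attr(out, "median") <- med
  out
}
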