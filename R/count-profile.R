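#' Summarize the autoantibody count distribution
#'
#' Two marginal summaries of the binary call matrix: per individual (how
#' many antigens each person is seropositive for — the autoantibody count)
#' and per antigen (how many individuals carry each autoantibody, over
#' detected antigens). Normality of the per-individual counts is assessed
#' with the Shapiro-Wilk test.
#'
#' @param calls A `sero_calls` object from [call_seropositive()].
#' @return List with elements `individual` (median, mean, range, shapiro_w,
#'   shapiro_p, counts) and `antigen` (median, mean, range, n_detected,
#'   counts over detected antigens).
#' @export
count_distribution <- function(calls) {
  stopifnot(inherits(calls, "sero_calls"))
  ind <- calls$counts
  ant <- calls$n_positive[calls$detected]
  sw <- tryCatch(stats::shapiro.test(ind),
                 error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  list(
    individual = list(
      median = stats::median(ind), mean = mean(ind), range = range(ind),
      shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value, counts = ind
    ),
    antigen = list(
      median = if (length(ant)) stats::median(ant) else NA_real_,
      mean = if (length(ant)) mean(ant) else NA_real_,
      range = if (length(ant)) range(ant) else c(NA_real_, NA_real_),
      n_detected = sum(calls$detected), counts = ant
    )
  )
}

#' Stratify individuals into low/high autoantibody-count groups
#'
#' Thresholds are the `low_pct` and `high_pct` percentiles of the count
#' distribution (linear interpolation between order statistics, quantile
#' type 7). Membership is strict: the low stratum holds individuals with
#' counts strictly below the low threshold, the high stratum counts strictly
#' above the high threshold, so boundary values belong to neither.
#'
#' @param counts Named (or unnamed) integer vector of per-individual counts.
#' @param low_pct,high_pct Percentiles defining the strata; defaults 5, 95.
#' @param type Quantile type passed to [stats::quantile()]; default 7.
#' @return List of class `count_strata`: `low_threshold`, `high_threshold`,
#'   `low_ids`, `high_ids` (indices or names), `counts`, `percentiles`.
#' @export
stratify_counts <- function(counts, low_pct = 5, high_pct = 95, type = 7) {
  if (!is.numeric(counts) || !length(counts)) {
    stop("'counts' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop("need 0 <= low_pct < high_pct <= 100", call. = FALSE)
  }
  qs <- stats::quantile(counts, c(low_pct, high_pct) / 100, type = type, names = FALSE)
  ids <- names(counts) %||% seq_along(counts)
  low_ids <- ids[counts < qs[[1]]]
  high_ids <- ids[counts > qs[[2]]]
  if (!length(low_ids) && !length(high_ids)) {
    warning("empty strata: count distribution has no spread past the thresholds",
            call. = FALSE)
  }
  structure(
    list(low_threshold = qs[[1]], high_threshold = qs[[2]],
         low_ids = low_ids, high_ids = high_ids,
         counts = counts, percentiles = c(low = low_pct, high = high_pct)),
    class = "count_strata"
  )
}

#' @export
print.count_strata <- function(x, ...) {
  cat(sprintf(
    "Count strata (%g/%g pct): low < %g (n = %d), high > %g (n = %d)\n",
    x$percentiles[["low"]], x$percentiles[["high"]],
    x$low_threshold, length(x$low_ids), x$high_threshold, length(x$high_ids)
  ))
  invisible(x)
}

#' Exact-test characterization of a group against clinical variables
#'
#' For each targeted variable, members of `group_ids` are compared against
#' all remaining individuals with a two-sided exact test on the 2x2 table
#' (pairwise-complete on missingness). Continuous variables named in
#' `cytokines` are median-dichotomized first (median in the lower interval).
#' These analyses are explorative; no multiple-testing correction is
#' applied.
#'
#' @param group_ids Individual ids (matching `clinical`'s id column) in the
#'   group of interest.
#' @param clinical data.frame, one row per individual; first column (or the
#'   column named by `id_col`) holds ids.
#' @param variables Character vector of dichotomous variable names to test.
#' @param cytokines Character vector of continuous variable names to
#'   median-dichotomize and test; default none.
#' @param id_col Name of the id column; default first column.
#' @param method Two-sided exact p construction, see [exact_or()].
#' @return data.frame: variable, a, b, c, d (table cells: group & feature,
#'   group & !feature, rest & feature, rest & !feature), p, or, ci_low,
#'   ci_high, prevalence_group, prevalence_rest. Variables with fewer than
#'   two observed levels are skipped with a warning.
#' @export
characterize_group <- function(group_ids, clinical, variables,
                               cytokines = character(0),
                               id_col = names(clinical)[[1]],
                               method = c("minlike", "central")) {
  method <- match.arg(method)
  ids <- as.character(clinical[[id_col]])
  in_group <- as.integer(ids %in% as.character(group_ids))
  rows <- list()
  for (v in c(variables, cytokines)) {
    if (!v %in% names(clinical)) {
      warning(sprintf("variable '%s' not found; skipped", v), call. = FALSE)
      next
    }
    x <- clinical[[v]]
    if (v %in% cytokines) x <- median_dichotomize(x)
    x <- as.integer(x)
    if (length(unique(stats::na.omit(x))) < 2) {
      warning(sprintf("variable '%s' has < 2 observed levels; skipped", v),
              call. = FALSE)
      next
    }
    tab <- tabulate_pair(in_group, x)
    res <- exact_or(tab, method = method)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
      p = res$p, or = res$or, ci_low = res$ci[[1]], ci_high = res$ci[[2]],
      prevalence_group = tab[1, 1] / sum(tab[1, ]),
      prevalence_rest = tab[2, 1] / sum(tab[2, ]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(variable = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p = numeric(0),
                      or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
                      prevalence_group = numeric(0), prevalence_rest = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Characterize low/high count strata against clinical variables
#'
#' Runs [characterize_group()] once for each stratum of a
#' [stratify_counts()] result (stratum vs all remaining individuals).
#'
#' @param strata A `count_strata` object.
#' @inheritParams characterize_group
#' @return data.frame with a leading `stratum` column ("low"/"high").
#' @export
characterize_strata <- function(strata, clinical, variables,
                                cytokines = character(0),
                                id_col = names(clinical)[[1]],
                                method = c("minlike", "central")) {
  stopifnot(inherits(strata, "count_strata"))
  method <- match.arg(method)
  out <- list()
  for (s in c("low", "high")) {
    g <- if (s == "low") strata$low_ids else strata$high_ids
    if (!length(g)) next
    res <- characterize_group(g, clinical, variables, cytokines, id_col, method)
    if (nrow(res)) out[[s]] <- cbind(stratum = s, res, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(cbind(stratum = character(0),
                 characterize_group(character(0), clinical, character(0))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of autoantibody profiles
#'
#' Complete-linkage agglomerative clustering on the Euclidean distance
#' between individuals' profiles (rows), used to look for groups of
#' individuals with similar autoantibody repertoires.
#'
#' @param profiles Numeric matrix, individuals in rows (binary calls or
#'   xMAD/score profiles).
#' @return The [stats::hclust()] object (merge heights in `$height`, leaf
#'   order in `$order`).
#' @export
cluster_profiles <- function(profiles) {
  stop_if_not_matrix(profiles, "profiles")
  if (nrow(profiles) < 2) stop("need >= 2 individuals to cluster", call. = FALSE)
  stats::hclust(stats::dist(profiles, method = "euclidean"), method = "complete")
}
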