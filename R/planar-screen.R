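#' Standardize a planar-array signal vector to times-SD units
#'
#' Planar protein microarrays are screened at the group (pool) level: each
#' array's raw intensities are standardized so that antigens can be selected
#' by how many standard deviations they sit above the array mean,
#' `times_sd = (X - mean(X)) / SD(X)`. The mean and SD are computed over all
#' antigens on the array; SD uses the sample (n - 1) convention.
#'
#' @param signals Numeric vector of raw intensities, one per antigen on the
#'   array. Must be finite, length >= 2, and not constant.
#' @return Numeric vector of the same length (and names) with mean 0 and
#'   sample SD 1.
#' @examples
#' times_sd(c(1, 2, 3)) # -1, 0, 1
#' @export
times_sd <- function(signals) {
  if (!is.numeric(signals) || length(signals) < 2) {
    stop("'signals' must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(signals))) {
    stop("'signals' must be finite", call. = FALSE)
  }
  s <- stats::sd(signals)
  if (s == 0) {
    stop("zero-variance array: times-SD transform is undefined", call. = FALSE)
  }
  (signals - mean(signals)) / s
}

#' Select antigens exceeding a times-SD threshold in at least one pool
#'
#' Applies the panel-inclusion rule of the broad screen: an antigen is
#' selected when its standardized signal is at or above `threshold`
#' (inclusive) in at least one pool. The default threshold of 8 SD is the
#' screening rule used to nominate antigens for the targeted bead-array
#' panel.
#'
#' @param pools A named list of standardized signal vectors (as produced by
#'   [times_sd()]), one per pool, all sharing the same antigen names, or a
#'   matrix with pools in rows and antigens in columns.
#' @param threshold Times-SD selection threshold (> 0); default 8.
#' @return A list of class `sero_screen` with elements:
#'   \describe{
#'     \item{per_pool}{named list of character vectors, selected antigens per pool}
#'     \item{union}{character vector, union panel across pools}
#'     \item{max_times_sd}{named numeric, per-antigen maximum times-SD across pools}
#'     \item{n_unique}{number of union antigens selected in exactly one pool}
#'     \item{unique_fraction}{`n_unique / length(union)` (NA when union empty)}
#'     \item{threshold}{the threshold used}
#'   }
#' @export
select_antigens <- function(pools, threshold = 8) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("'threshold' must be a single positive number", call. = FALSE)
  }
  if (is.matrix(pools)) {
    pools <- stats::setNames(
      lapply(seq_len(nrow(pools)), function(i) pools[i, ]),
      rownames(pools) %||% paste0("pool", seq_len(nrow(pools)))
    )
  }
  if (length(pools) == 0) {
    return(structure(
      list(per_pool = list(), union = character(0),
           max_times_sd = numeric(0), n_unique = 0L,
           unique_fraction = NA_real_, threshold = threshold),
      class = "sero_screen"
    ))
  }
  if (is.null(names(pools))) names(pools) <- paste0("pool", seq_along(pools))
  per_pool <- lapply(pools, function(v) {
    ids <- names(v) %||% as.character(seq_along(v))
    ids[v >= threshold]
  })
  union_set <- unique(unlist(per_pool, use.names = FALSE))
  hits_per_antigen <- table(unlist(per_pool, use.names = FALSE))
  n_unique <- sum(hits_per_antigen == 1L)
  all_ids <- unique(unlist(lapply(pools, function(v) {
    names(v) %||% as.character(seq_along(v))
  }), use.names = FALSE))
  max_sd <- vapply(all_ids, function(id) {
    max(vapply(pools, function(v) {
      ids <- names(v) %||% as.character(seq_along(v))
      j <- match(id, ids)
      if (is.na(j)) -Inf else v[[j]]
    }, numeric(1)))
  }, numeric(1))
  structure(
    list(per_pool = per_pool,
         union = union_set,
         max_times_sd = max_sd,
         n_unique = as.integer(n_unique),
         unique_fraction = if (length(union_set)) n_unique / length(union_set) else NA_real_,
         threshold = threshold),
    class = "sero_screen"
  )
}

#' @export
print.sero_screen <- function(x, ...) {
  cat(sprintf(
    "Planar screen: %d pools, %d antigens selected at >= %g SD (%d pool-unique, %.0f%%)\n",
    length(x$per_pool), length(x$union), x$threshold, x$n_unique,
    100 * (x$unique_fraction %||% NA_real_)
  ))
  invisible(x)
}
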