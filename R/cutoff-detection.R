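#' Per-antigen seropositivity cutoff via kernel-density peak/slope walk
#'
#' For one antigen, the cohort's score vector (values on the 16-level scale)
#' is smoothed with a Gaussian kernel density estimate, and a detection
#' cutoff is chosen by walking away from the tallest density peak until the
#' curve's slope first drops below `slope_threshold`:
#' \enumerate{
#'   \item compute the kernel density curve of the scored data (Gaussian
#'     kernel, Silverman's rule-of-thumb bandwidth, 512-point grid spanning
#'     the data range plus 3 bandwidths on either side — the
#'     [stats::density()] defaults);
#'   \item locate the tallest peak;
#'   \item if the peak's x position is at most `peak_split` (default 0.75),
#'     walk up (increasing x) from the peak, otherwise walk down;
#'   \item at each grid step compute the directional slope — density change
#'     per unit score travelled along the walk — and stop at the first step
#'     where it falls strictly below `slope_threshold` (default -0.5);
#'   \item round the stopping position up to the nearest score step (0.1)
#'     and clamp into `[0, 1.5]`; this is the antigen's detection cutoff.
#' }
#' Individuals scoring at or above the cutoff are seropositive.
#'
#' Degenerate inputs: an all-identical score vector has no usable density
#' curve; the cutoff is placed one score step above the constant value (so
#' every individual is seronegative) with a warning. If the walk reaches the
#' end of the grid without the slope crossing the threshold, the grid-end
#' position is used (rounded up, clamped), with a warning.
#'
#' @param scores Numeric vector of scores for one antigen across the cohort
#'   (length >= 2), values in `{0, 0.1, ..., 1.5}`.
#' @param slope_threshold Directional slope at which the walk stops;
#'   default `-0.5`.
#' @param peak_split Peak x position separating up-walks from down-walks;
#'   default `0.75`.
#' @param antigen_id Optional label carried into the result.
#' @return A one-row data.frame (`antigen_id`, `peak_x`, `direction`,
#'   `cutoff`, `n_positive`).
#' @export
detect_cutoff <- function(scores, slope_threshold = -0.5, peak_split = 0.75,
                          antigen_id = NA_character_) {
  if (!is.numeric(scores) || length(scores) < 2) {
    stop("'scores' must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("'scores' must be finite", call. = FALSE)

  if (length(unique(score_tenths(scores))) == 1L) {
    # No density curve to walk: everything sits on one score level. Place the
    # cutoff one step above so all individuals are seronegative.
    cutoff <- round(scores[[1]], 1) + 0.1
    warning(sprintf(
      "antigen %s: constant score vector (%.1f); cutoff set to %.1f (all seronegative)",
      antigen_id, scores[[1]], cutoff
    ), call. = FALSE)
    return(data.frame(
      antigen_id = antigen_id, peak_x = round(scores[[1]], 1),
      direction = NA_character_, cutoff = cutoff,
      n_positive = sum(score_tenths(scores) >= score_tenths(cutoff)),
      stringsAsFactors = FALSE
    ))
  }

  d <- stats::density(scores)
  peak <- which.max(d$y)
  peak_x <- d$x[[peak]]
  up <- peak_x <= peak_split
  direction <- if (up) "up" else "down"

  # Indices visited along the walk, starting at the peak.
  idx <- if (up) seq(peak, length(d$x)) else seq(peak, 1L)
  found_x <- NA_real_
  if (length(idx) >= 2) {
    # Directional slope over each grid segment: density change per unit
    # score travelled (grid spacing is uniform and positive either way).
    step <- abs(d$x[[2]] - d$x[[1]])
    dy <- diff(d$y[idx]) / step
    hit <- which(dy < slope_threshold)
    if (length(hit)) {
      # The crossing segment runs from idx[hit] to idx[hit + 1]; the found
      # position is the segment's far endpoint — the first grid point at
      # which the slope has passed the threshold. Taking the near endpoint
      # instead would park the cutoff on the peak's own grid point, and the
      # subsequent round-up would then flip between including and excluding
      # the whole background population depending on which side of a score
      # step the discretized peak happens to fall.
      found_x <- d$x[[idx[[hit[[1]] + 1L]]]]
    }
  }
  if (is.na(found_x)) {
    found_x <- d$x[[idx[[length(idx)]]]]
    warning(sprintf(
      "antigen %s: slope never crossed %.2f along the %s walk; using grid end",
      antigen_id, slope_threshold, direction
    ), call. = FALSE)
  }
  cutoff <- min(max(ceiling_score_step(found_x), 0), 1.5)
  data.frame(
    antigen_id = antigen_id, peak_x = peak_x, direction = direction,
    cutoff = cutoff,
    n_positive = sum(score_tenths(scores) >= score_tenths(cutoff)),
    stringsAsFactors = FALSE
  )
}

#' Detect cutoffs for every antigen of a score matrix
#'
#' @param scores Samples x antigens score matrix.
#' @inheritParams detect_cutoff
#' @param quiet Suppress per-antigen degenerate-input warnings (they are
#'   collected into the returned table's `degenerate` column instead).
#' @return data.frame with one row per antigen: `antigen_id`, `peak_x`,
#'   `direction`, `cutoff`, `n_positive`, `degenerate`.
#' @export
detect_cutoffs <- function(scores, slope_threshold = -0.5, peak_split = 0.75,
                           quiet = FALSE) {
  stop_if_not_matrix(scores, "scores")
  ids <- colnames(scores) %||% paste0("antigen", seq_len(ncol(scores)))
  rows <- vector("list", ncol(scores))
  for (j in seq_len(ncol(scores))) {
    degenerate <- FALSE
    rec <- withCallingHandlers(
      detect_cutoff(scores[, j], slope_threshold, peak_split, antigen_id = ids[[j]]),
      warning = function(w) {
        degenerate <<- TRUE
        if (quiet) invokeRestart("muffleWarning")
      }
    )
    rec$degenerate <- degenerate
    rows[[j]] <- rec
  }
  do.call(rbind, rows)
}

#' Call per-individual seropositivity from scores and cutoffs
#'
#' An individual is seropositive for an antigen when their score is at or
#' above (inclusive) the antigen's detection cutoff.
#'
#' @param scores Samples x antigens score matrix.
#' @param cutoffs data.frame from [detect_cutoffs()] (or any data.frame with
#'   `antigen_id` and `cutoff`), or a numeric vector of cutoffs, one per
#'   antigen column.
#' @return A list of class `sero_calls`:
#'   \describe{
#'     \item{calls}{binary samples x antigens matrix}
#'     \item{counts}{per-individual autoantibody count (row sums)}
#'     \item{n_positive}{per-antigen seropositive count (column sums)}
#'     \item{detected}{logical, per antigen: any seropositive individual}
#'     \item{cutoffs}{the cutoff table used}
#'   }
#' @export
call_seropositive <- function(scores, cutoffs) {
  stop_if_not_matrix(scores, "scores")
  if (is.data.frame(cutoffs)) {
    ids <- colnames(scores) %||% paste0("antigen", seq_len(ncol(scores)))
    if (!all(ids %in% cutoffs$antigen_id)) {
      stop("every antigen column needs a cutoff", call. = FALSE)
    }
    cut_vec <- cutoffs$cutoff[match(ids, cutoffs$antigen_id)]
    cut_tab <- cutoffs
  } else {
    if (length(cutoffs) != ncol(scores)) {
      stop("length(cutoffs) must equal ncol(scores)", call. = FALSE)
    }
    cut_vec <- as.numeric(cutoffs)
    cut_tab <- data.frame(
      antigen_id = colnames(scores) %||% paste0("antigen", seq_len(ncol(scores))),
      cutoff = cut_vec, stringsAsFactors = FALSE
    )
  }
  st <- matrix(score_tenths(scores), nrow = nrow(scores), dimnames = dimnames(scores))
  ct <- score_tenths(cut_vec)
  calls <- 1L * (st >= matrix(ct, nrow(scores), ncol(scores), byrow = TRUE))
  structure(
    list(calls = calls,
         counts = rowSums(calls),
         n_positive = colSums(calls),
         detected = colSums(calls) > 0,
         cutoffs = cut_tab),
    class = "sero_calls"
  )
}

#' @export
print.sero_calls <- function(x, ...) {
  cat(sprintf(
    "Seropositivity calls: %d individuals x %d antigens; %d detected (%.0f%%); median count %g\n",
    nrow(x$calls), ncol(x$calls), sum(x$detected),
    100 * mean(x$detected), stats::median(x$counts)
  ))
  invisible(x)
}

#' Sparsity among detected autoantibodies
#'
#' Fraction of zero cells in the call matrix restricted to detected antigens
#' (those with at least one seropositive individual) — the cohort-level
#' sparsity statistic of the autoantibody landscape.
#'
#' @param calls A `sero_calls` object.
#' @return A single number in `[0, 1]` (NA when nothing is detected).
#' @export
call_sparsity <- function(calls) {
  stopifnot(inherits(calls, "sero_calls"))
  m <- calls$calls[, calls$detected, drop = FALSE]
  if (!length(m)) return(NA_real_)
  mean(m == 0)
}
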