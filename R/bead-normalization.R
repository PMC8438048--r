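#' Per-sample robust normalization of bead-array MFI (xMAD)
#'
#' Bead-array median fluorescence intensities (MFI) carry sample-specific
#' background level and spread. Each sample (row) is therefore normalized by
#' its own robust location and scale:
#' \deqn{xMAD = (MFI - median(MFI)) / mad(MFI)}
#' with the median and MAD taken over the sample's antigens. By default the
#' MAD carries the normal-consistency factor 1.4826 (the `stats::mad`
#' default), so xMAD reads as a robust z-score; `mad_constant = 1` gives the
#' unscaled MAD.
#'
#' @param mfi Numeric matrix of raw MFI, samples in rows, antigens in
#'   columns. Values must be finite and non-negative. Row and column names
#'   (sample and antigen ids) are preserved.
#' @param mad_constant Scale factor for the MAD; default `1.4826`
#'   (normal consistency).
#' @return Matrix of xMAD values, same shape and dimnames; every row has
#'   median 0.
#' @examples
#' m <- rbind(s1 = c(1, 2, 3, 4, 100))
#' xmad_normalize(m) # the outlier maps to 97/1.4826 = 65.4
#' @export
xmad_normalize <- function(mfi, mad_constant = 1.4826) {
  stop_if_not_matrix(mfi, "mfi")
  if (!all(is.finite(mfi))) stop("'mfi' must be finite", call. = FALSE)
  if (any(mfi < 0)) stop("'mfi' must be non-negative", call. = FALSE)
  meds <- apply(mfi, 1, stats::median)
  mads <- apply(mfi, 1, stats::mad, constant = mad_constant)
  bad <- which(mads == 0)
  if (length(bad)) {
    ids <- rownames(mfi)[bad] %||% as.character(bad)
    stop(sprintf("degenerate sample(s) with MAD = 0: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  sweep(sweep(mfi, 1, meds, "-"), 1, mads, "/")
}

#' Map xMAD values onto the 16-level score scale
#'
#' Discretizes normalized values onto the scores {0, 0.1, ..., 1.5} using
#' left-closed, right-open bins of width 5 xMAD:
#' score 0 for xMAD < 0; score 0.1 for 0 <= xMAD < 5; 0.2 for 5 <= xMAD < 10;
#' ... 1.4 for 65 <= xMAD < 70; and 1.5 for xMAD >= 70.
#'
#' @param xmad Numeric vector, matrix or array of finite normalized values.
#' @return Object of the same shape with entries in `{0, 0.1, ..., 1.5}`.
#'   Scores are exact tenths (computed as integer bin index / 10).
#' @examples
#' score_xmad(c(-3.2, 0, 5, 69.9, 70)) # 0 0.1 0.2 1.4 1.5
#' @export
score_xmad <- function(xmad) {
  if (!is.numeric(xmad)) stop("'xmad' must be numeric", call. = FALSE)
  if (!all(is.finite(xmad))) stop("'xmad' must be finite", call. = FALSE)
  k <- ifelse(xmad < 0, 0L, pmin(floor(xmad / 5) + 1, 15))
  out <- k / 10
  attributes(out) <- attributes(xmad)
  out
}

#' Normalize and score a raw MFI matrix
#'
#' Convenience wrapper chaining [xmad_normalize()] and [score_xmad()].
#'
#' @inheritParams xmad_normalize
#' @return List with components `xmad` and `scores`, both samples x antigens.
#' @export
score_matrix <- function(mfi, mad_constant = 1.4826) {
  x <- xmad_normalize(mfi, mad_constant = mad_constant)
  list(xmad = x, scores = score_xmad(x))
}
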