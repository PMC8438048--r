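#' One-at-a-time sensitivity grids for the pipeline's cutoffs and criteria
#'
#' Default grids vary each tunable cutoff one at a time around its baseline:
#' count-stratum percentiles, the three association selection criteria, and
#' a uniform shift of every antigen's detection cutoff by whole score steps.
#'
#' @param count_percentiles List of `c(low, high)` percentile pairs.
#' @param min_positives,min_prevalence_pos,min_prevalence_ratio Numeric
#'   grids for the selection criteria.
#' @param cutoff_offset Integer grid of score-step shifts applied to every
#'   antigen's detection cutoff.
#' @return Named list of class `sensitivity_grid`; each element carries the
#'   grid values for one parameter (a baseline entry is added at run time
#'   if missing).
#' @export
sensitivity_grid <- function(count_percentiles = list(c(2.5, 97.5), c(5, 95), c(10, 90)),
                             min_positives = c(5, 10, 15),
                             min_prevalence_pos = c(0.80, 0.85, 0.90),
                             min_prevalence_ratio = c(1.15, 1.25, 1.35),
                             cutoff_offset = c(-1L, 0L, 1L)) {
  structure(
    list(count_percentiles = count_percentiles,
         min_positives = min_positives,
         min_prevalence_pos = min_prevalence_pos,
         min_prevalence_ratio = min_prevalence_ratio,
         cutoff_offset = cutoff_offset),
    class = "sensitivity_grid"
  )
}

#' Sensitivity analysis: which baseline findings persist as cutoffs vary?
#'
#' Re-evaluates the pipeline's findings with each tunable parameter varied
#' one at a time over its grid, re-running only the stages downstream of the
#' varied parameter. Two families of findings are tracked: the selected
#' antibody-symptom associations (affected by the selection criteria and by
#' detection-cutoff shifts) and the significant stratum-characterization
#' results (affected by the count percentiles and cutoff shifts). A finding
#' is `retained` at a grid point when it is still selected / still
#' significant there; grid points that make a stage degenerate (e.g. an
#' empty stratum) are recorded as not evaluable (`retained = NA`).
#'
#' @param pipeline A `sero_pipeline` from [run_pipeline()].
#' @param grid A [sensitivity_grid()]. Only parameters present in the grid
#'   are varied; each grid is augmented with the baseline value if absent.
#' @param alpha Significance level used for characterization findings;
#'   default 0.05.
#' @return List of class `sensitivity_report`: `report` (data.frame with
#'   columns finding, parameter, value, retained, p, q), `baseline`
#'   (finding labels), `robust` (findings retained at every evaluable
#'   non-baseline grid point), `fragile` (the rest).
#' @export
run_sensitivity <- function(pipeline, grid = sensitivity_grid(), alpha = 0.05) {
  stopifnot(inherits(pipeline, "sero_pipeline"))
  crit0 <- do.call(selection_criteria, pipeline$params$criteria)
  pct0 <- c(pipeline$params$low_pct, pipeline$params$high_pct)

  assoc0 <- pipeline$associations
  assoc_findings <- if (nrow(assoc0)) {
    paste(assoc0$antigen_id, assoc0$symptom, sep = " ~ ")
  } else character(0)
  sc0 <- pipeline$strata_characterization
  sig0 <- sc0[!is.na(sc0$p) & sc0$p < alpha, , drop = FALSE]
  strata_findings <- if (nrow(sig0)) {
    paste(sig0$stratum, sig0$variable, sep = " ~ ")
  } else character(0)

  rows <- list()
  add <- function(finding, parameter, value, retained, p = NA_real_, q = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      finding = finding, parameter = parameter, value = value,
      retained = retained, p = p, q = q, stringsAsFactors = FALSE)
  }

  assoc_point <- function(assoc, parameter, value_label) {
    tested <- attr(assoc, "tested")
    for (i in seq_along(assoc_findings)) {
      f <- assoc_findings[[i]]
      hit <- assoc$antigen_id == assoc0$antigen_id[[i]] &
        assoc$symptom == assoc0$symptom[[i]]
      trow <- if (!is.null(tested)) {
        tested[tested$antigen_id == assoc0$antigen_id[[i]] &
                 tested$symptom == assoc0$symptom[[i]], , drop = FALSE]
      } else NULL
      p <- if (!is.null(trow) && nrow(trow)) trow$p[[1]] else NA_real_
      q <- if (!is.null(trow) && nrow(trow)) trow$q[[1]] else NA_real_
      add(f, parameter, value_label, any(hit), p, q)
    }
  }

  with_baseline <- function(values, baseline, same) {
    if (!any(vapply(values, same, logical(1), y = baseline))) c(values, list(baseline))
    else values
  }

  # Selection-criteria parameters: only the association screen re-runs.
  for (par in c("min_positives", "min_prevalence_pos", "min_prevalence_ratio")) {
    if (is.null(grid[[par]])) next
    vals <- with_baseline(as.list(grid[[par]]), crit0[[par]],
                          function(x, y) isTRUE(all.equal(x, y)))
    for (v in vals) {
      crit <- crit0; crit[[par]] <- v
      assoc <- select_associations(pipeline$calls, pipeline$clinical,
                                   pipeline$symptoms, crit,
                                   method = pipeline$params$method,
                                   all_tested = TRUE)
      assoc_point(assoc, par, as.character(v))
    }
  }

  # Detection-cutoff shift: re-call seropositivity, then both finding
  # families downstream.
  if (!is.null(grid$cutoff_offset)) {
    vals <- unique(c(grid$cutoff_offset, 0L))
    for (off in vals) {
      cuts <- pipeline$cutoffs
      cuts$cutoff <- pmin(pmax(cuts$cutoff + off * 0.1, 0), 1.6)
      calls <- call_seropositive(pipeline$scores$scores, cuts)
      assoc <- select_associations(calls, pipeline$clinical, pipeline$symptoms,
                                   crit0, method = pipeline$params$method,
                                   all_tested = TRUE)
      assoc_point(assoc, "cutoff_offset", as.character(off))
      strata_char_point(calls$counts, pct0, off, "cutoff_offset",
                        pipeline, strata_findings, sig0, alpha, add)
    }
  }

  # Count percentiles: only the stratification and its characterization.
  if (!is.null(grid$count_percentiles)) {
    vals <- with_baseline(grid$count_percentiles, pct0,
                          function(x, y) isTRUE(all.equal(as.numeric(x), as.numeric(y))))
    for (pct in vals) {
      strata_char_point(pipeline$calls$counts, pct, NULL, "count_percentiles",
                        pipeline, strata_findings, sig0, alpha, add)
    }
  }

  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(finding = character(0), parameter = character(0),
               value = character(0), retained = logical(0),
               p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
  nonbase <- report[!is_baseline_point(report, crit0, pct0), , drop = FALSE]
  by_f <- split(nonbase$retained, nonbase$finding)
  robust <- names(by_f)[vapply(by_f, function(r) all(r[!is.na(r)]), logical(1))]
  structure(
    list(report = report,
         baseline = c(assoc_findings, strata_findings),
         robust = robust,
         fragile = setdiff(c(assoc_findings, strata_findings), robust)),
    class = "sensitivity_report"
  )
}

# Re-stratify and re-characterize for one sensitivity grid point, recording
# retention of each baseline stratum finding.
strata_char_point <- function(counts, pct, offset, parameter, pipeline,
                              strata_findings, sig0, alpha, add) {
  if (!length(strata_findings)) return(invisible())
  label <- if (is.null(offset)) paste(pct, collapse = "/") else as.character(offset)
  strata <- withCallingHandlers(
    stratify_counts(counts, pct[[1]], pct[[2]]),
    warning = function(w) invokeRestart("muffleWarning")
  )
  sc <- suppressWarnings(
    characterize_strata(strata, pipeline$clinical, pipeline$variables,
                        pipeline$cytokines, method = pipeline$params$method)
  )
  for (i in seq_len(nrow(sig0))) {
    f <- paste(sig0$stratum[[i]], sig0$variable[[i]], sep = " ~ ")
    n_stratum <- if (sig0$stratum[[i]] == "low") length(strata$low_ids)
                 else length(strata$high_ids)
    if (n_stratum == 0) {                    # degenerate point: not evaluable
      add(f, parameter, label, NA)
      next
    }
    row <- sc[sc$stratum == sig0$stratum[[i]] & sc$variable == sig0$variable[[i]], ,
              drop = FALSE]
    if (!nrow(row)) add(f, parameter, label, NA)
    else add(f, parameter, label, !is.na(row$p[[1]]) && row$p[[1]] < alpha,
             row$p[[1]])
  }
  invisible()
}

is_baseline_point <- function(report, crit0, pct0) {
  base_val <- c(min_positives = as.character(crit0$min_positives),
                min_prevalence_pos = as.character(crit0$min_prevalence_pos),
                min_prevalence_ratio = as.character(crit0$min_prevalence_ratio),
                cutoff_offset = "0",
                count_percentiles = paste(pct0, collapse = "/"))
  report$value == unname(base_val[report$parameter])
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "Sensitivity report: %d baseline finding(s); %d robust, %d fragile across the grid\n",
    length(x$baseline), length(x$robust), length(x$fragile)))
  invisible(x)
}
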