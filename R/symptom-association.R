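#' Selection criteria for the antibody-symptom screen
#'
#' The screen retains an (antibody, symptom) pair only when all of the
#' following hold:
#' \describe{
#'   \item{group size}{the autoantibody is present in at least `min_positives`
#'     individuals (about 2\% of a ~460-person cohort at the default 10),
#'     for clinical applicability and to damp sporadic associations;}
#'   \item{symptom prevalence}{the symptom's prevalence among seropositive
#'     individuals is at least `min_prevalence_pos` (default 0.85), for a
#'     large effect size;}
#'   \item{prevalence ratio}{the symptom is at least 25\% more prevalent in
#'     the seropositive than the seronegative group. By default this is read
#'     as a ratio, `P(Sx|Pos)/P(Sx|Neg) >= min_prevalence_ratio` (1.25);
#'     `ratio_as_difference = TRUE` switches to the additive reading,
#'     `P(Sx|Pos) - P(Sx|Neg) >= min_prevalence_ratio - 1`;}
#'   \item{significance}{the exact test is significant after
#'     Benjamini-Hochberg FDR correction, `q < alpha_fdr` (default 0.05).}
#' }
#'
#' @param min_positives Minimum seropositive group size (antigen level).
#' @param min_prevalence_pos Minimum symptom prevalence among seropositives.
#' @param min_prevalence_ratio Minimum prevalence ratio (positive/negative).
#' @param alpha_fdr FDR level for the BH-adjusted q-value gate.
#' @param ratio_as_difference Use the percentage-point reading of the third
#'   criterion instead of the ratio reading.
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(min_positives = 10, min_prevalence_pos = 0.85,
                               min_prevalence_ratio = 1.25, alpha_fdr = 0.05,
                               ratio_as_difference = FALSE) {
  stopifnot(min_positives >= 1,
            min_prevalence_pos > 0, min_prevalence_pos <= 1,
            min_prevalence_ratio > 1, alpha_fdr > 0, alpha_fdr < 1)
  structure(
    list(min_positives = min_positives,
         min_prevalence_pos = min_prevalence_pos,
         min_prevalence_ratio = min_prevalence_ratio,
         alpha_fdr = alpha_fdr,
         ratio_as_difference = isTRUE(ratio_as_difference)),
    class = "selection_criteria"
  )
}

#' Three-criterion antibody-symptom association screen with FDR control
#'
#' Tests every (antigen, symptom) pair for association between
#' seropositivity and current-or-past symptom presence. Antigens failing
#' the group-size criterion are excluded up front; all remaining pairs form
#' the family over which Benjamini-Hochberg correction is applied (symptoms
#' that are constant or all-missing in the cohort are skipped as
#' untestable). A pair is reported when the symptom-prevalence and
#' prevalence-ratio criteria hold and its q-value is below `alpha_fdr`.
#' Tables are pairwise-complete: individuals missing a symptom are dropped
#' from that symptom's tables only.
#'
#' @param calls A `sero_calls` object.
#' @param clinical data.frame with one row per individual, id column first
#'   (or named by `id_col`), and the symptom indicator columns.
#' @param symptoms Character vector of symptom column names.
#' @param criteria A [selection_criteria()] object.
#' @param id_col Name of the id column; default first column.
#' @param method Two-sided exact p construction, see [exact_or()].
#' @param all_tested Also return the full tested family (for sensitivity
#'   re-analysis) as attribute `"tested"`.
#' @return data.frame, one row per selected association:
#'   `antigen_id`, `symptom`, `n_pos`, `p_sx_pos`, `p_sx_neg`, `pr`,
#'   `p`, `q`, `or`, `ci_low`, `ci_high`. Zero rows is a valid result.
#' @export
select_associations <- function(calls, clinical, symptoms,
                                criteria = selection_criteria(),
                                id_col = names(clinical)[[1]],
                                method = c("minlike", "central"),
                                all_tested = FALSE) {
  stopifnot(inherits(calls, "sero_calls"), inherits(criteria, "selection_criteria"))
  method <- match.arg(method)
  ids <- as.character(clinical[[id_col]])
  cm <- calls$calls
  rn <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  if (!all(ids %in% rn) || length(ids) != nrow(cm)) {
    stop("clinical ids must match the call matrix rows one-to-one", call. = FALSE)
  }
  cm <- cm[match(ids, rn), , drop = FALSE]

  # Group-size criterion is antigen-level: full-cohort seropositive count.
  keep <- which(calls$n_positive >= criteria$min_positives)
  if (!length(keep)) return(empty_association_table())
  ag_ids <- (colnames(cm) %||% paste0("antigen", seq_len(ncol(cm))))[keep]
  cm <- cm[, keep, drop = FALSE]

  res <- list()
  for (s in symptoms) {
    sx <- as.integer(clinical[[s]])
    obs <- !is.na(sx)
    if (!any(obs)) next
    lv <- unique(sx[obs])
    if (length(lv) < 2) next  # degenerate: prevalence 0 or 1 in the cohort
    cmo <- cm[obs, , drop = FALSE]
    sxo <- sx[obs]
    a <- as.numeric(crossprod(cmo, sxo))       # pos & sx
    pos_obs <- colSums(cmo)
    b <- pos_obs - a                           # pos & !sx
    csx <- sum(sxo) - a                        # neg & sx
    d <- (sum(obs) - pos_obs) - csx            # neg & !sx
    res[[s]] <- data.frame(
      antigen_id = ag_ids, symptom = s,
      n_pos = calls$n_positive[keep],
      a = a, b = b, c = csx, d = d,
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) return(empty_association_table())
  fam <- do.call(rbind, res)
  rownames(fam) <- NULL

  fam$p_sx_pos <- ifelse(fam$a + fam$b > 0, fam$a / (fam$a + fam$b), NA_real_)
  fam$p_sx_neg <- ifelse(fam$c + fam$d > 0, fam$c / (fam$c + fam$d), NA_real_)
  fam$pr <- ifelse(fam$p_sx_neg > 0, fam$p_sx_pos / fam$p_sx_neg, Inf)
  fam$p <- exact_p22(fam$a, fam$b, fam$c, fam$d, method = method)
  fam$q <- stats::p.adjust(fam$p, method = "BH")

  pass_prev <- !is.na(fam$p_sx_pos) & fam$p_sx_pos >= criteria$min_prevalence_pos
  pass_pr <- if (criteria$ratio_as_difference) {
    (fam$p_sx_pos - fam$p_sx_neg) >= (criteria$min_prevalence_ratio - 1)
  } else {
    fam$pr >= criteria$min_prevalence_ratio
  }
  sel <- fam[pass_prev & pass_pr & fam$q < criteria$alpha_fdr, , drop = FALSE]

  if (nrow(sel)) {
    est <- t(vapply(seq_len(nrow(sel)), function(i) {
      tab <- matrix(c(sel$a[i], sel$b[i], sel$c[i], sel$d[i]), 2, byrow = TRUE)
      r <- exact_or(tab, method = method)
      c(r$or, r$ci)
    }, numeric(3)))
    sel$or <- est[, 1]; sel$ci_low <- est[, 2]; sel$ci_high <- est[, 3]
  } else {
    sel$or <- numeric(0); sel$ci_low <- numeric(0); sel$ci_high <- numeric(0)
  }
  sel <- sel[order(sel$antigen_id, sel$p), , drop = FALSE]
  rownames(sel) <- NULL
  if (all_tested) attr(sel, "tested") <- fam
  sel
}

empty_association_table <- function() {
  data.frame(antigen_id = character(0), symptom = character(0),
             n_pos = integer(0), a = numeric(0), b = numeric(0),
             c = numeric(0), d = numeric(0),
             p_sx_pos = numeric(0), p_sx_neg = numeric(0), pr = numeric(0),
             p = numeric(0), q = numeric(0), or = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0),
             stringsAsFactors = FALSE)
}

#' Targeted characterization of a symptom-associated seropositive group
#'
#' For one selected autoantibody, compares its seropositive individuals
#' against seronegatives on a targeted set of clinical variables and
#' median-dichotomized cytokines (median in the lower interval), using the
#' same exact-test machinery. Explorative: no multiplicity correction.
#'
#' @param antigen_id The antigen whose seropositive group to characterize.
#' @param calls A `sero_calls` object.
#' @param clinical Clinical data.frame (id column first or named by `id_col`).
#' @param variables Dichotomous clinical variable names.
#' @param cytokines Continuous variable names to median-dichotomize.
#' @param id_col Name of the id column.
#' @param method Two-sided exact p construction.
#' @return data.frame as in [characterize_group()].
#' @export
characterize_positives <- function(antigen_id, calls, clinical, variables,
                                   cytokines = character(0),
                                   id_col = names(clinical)[[1]],
                                   method = c("minlike", "central")) {
  stopifnot(inherits(calls, "sero_calls"))
  method <- match.arg(method)
  j <- match(antigen_id, colnames(calls$calls))
  if (is.na(j)) stop(sprintf("antigen '%s' not in call matrix", antigen_id),
                     call. = FALSE)
  rn <- rownames(calls$calls) %||% as.character(seq_len(nrow(calls$calls)))
  pos_ids <- rn[calls$calls[, j] == 1]
  characterize_group(pos_ids, clinical, variables, cytokines, id_col, method)
}

#' Format an association table in the presentation schema
#'
#' Rounds prevalences to whole percent and the prevalence ratio to one
#' decimal, and renders 0/Inf odds-ratio estimates and bounds symbolically,
#' for reporting. All selection was done on the exact fractions.
#'
#' @param assoc data.frame from [select_associations()].
#' @return data.frame with columns antigen, symptom, n_pos, `P(Sx|Pos)` (%),
#'   `P(Sx|Neg)` (%), PR, p, q, OR, CI_low, CI_high (ORs/bounds as strings).
#' @export
format_associations <- function(assoc) {
  fmt_num <- function(x) ifelse(is.infinite(x), "Inf", signif(x, 2))
  data.frame(
    antigen = assoc$antigen_id, symptom = assoc$symptom, n_pos = assoc$n_pos,
    p_sx_pos_pct = round(100 * assoc$p_sx_pos),
    p_sx_neg_pct = round(100 * assoc$p_sx_neg),
    pr = round(assoc$pr, 1),
    p = signif(assoc$p, 2), q = signif(assoc$q, 2),
    or = fmt_num(assoc$or), ci_low = fmt_num(assoc$ci_low),
    ci_high = fmt_num(assoc$ci_high),
    stringsAsFactors = FALSE
  )
}
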