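#' Run the full bead-array profiling and association pipeline
#'
#' Orchestrates the targeted-profiling analysis end to end: per-sample xMAD
#' normalization and 16-level scoring of the raw MFI matrix, per-antigen
#' kernel-density cutoff detection, seropositivity calling, autoantibody
#' count summary and 5th/95th-percentile stratification with exact-test
#' characterization, and the three-criterion antibody-symptom association
#' screen with BH FDR control, followed by targeted characterization of
#' each selected seropositive group. Every stage result is kept in the
#' returned state so downstream re-analysis (sensitivity) can re-run only
#' what a parameter change touches.
#'
#' @param mfi Samples x antigens raw MFI matrix (rownames = individual ids),
#'   or a `sero_cohort` from [generate_cohort()] (its clinical table and
#'   symptom columns are then used unless overridden).
#' @param clinical Clinical data.frame, one row per individual, id column
#'   first.
#' @param symptoms Character vector of symptom column names.
#' @param variables Targeted dichotomous clinical variables for the
#'   stratum/group characterizations.
#' @param cytokines Continuous variables to median-dichotomize in the
#'   characterizations.
#' @param criteria [selection_criteria()] for the association screen.
#' @param low_pct,high_pct Count-stratum percentiles; defaults 5 and 95.
#' @param mad_constant MAD scaling for [xmad_normalize()].
#' @param slope_threshold,peak_split Cutoff-detection parameters.
#' @param method Two-sided exact p construction ("minlike" or "central").
#' @param output_dir Optional directory; when given, stage outputs are
#'   written as CSV plus a JSON run manifest.
#' @return List of class `sero_pipeline` with elements `scores` (xmad +
#'   scores), `cutoffs`, `calls`, `count_summary`, `strata`,
#'   `strata_characterization`, `associations`, `positive_characterization`
#'   (one data.frame per selected antigen), `params`, and `manifest`.
#' @export
run_pipeline <- function(mfi, clinical = NULL, symptoms = NULL,
                         variables = c("sex_female", "family_history_obesity",
                                       "family_history_psych_other",
                                       "family_history_heart_disease",
                                       "clozapine_use", "thought_disorder",
                                       "affective_diagnosis"),
                         cytokines = c("IL4", "IL6", "IL8", "IL10", "CuZn_SOD"),
                         criteria = selection_criteria(),
                         low_pct = 5, high_pct = 95,
                         mad_constant = 1.4826,
                         slope_threshold = -0.5, peak_split = 0.75,
                         method = c("minlike", "central"),
                         output_dir = NULL) {
  method <- match.arg(method)
  if (inherits(mfi, "sero_cohort")) {
    cohort <- mfi
    mfi <- cohort$mfi
    clinical <- clinical %||% cohort$clinical
    symptoms <- symptoms %||% cohort_symptoms(cohort)
  }
  if (is.null(clinical) || is.null(symptoms)) {
    stop("'clinical' and 'symptoms' are required unless a sero_cohort is given",
         call. = FALSE)
  }
  variables <- intersect(variables, names(clinical))
  cytokines <- intersect(cytokines, names(clinical))

  sm <- score_matrix(mfi, mad_constant = mad_constant)
  cutoffs <- detect_cutoffs(sm$scores, slope_threshold, peak_split, quiet = TRUE)
  calls <- call_seropositive(sm$scores, cutoffs)
  count_summary <- count_distribution(calls)
  strata <- stratify_counts(calls$counts, low_pct, high_pct)
  strata_char <- characterize_strata(strata, clinical, variables, cytokines,
                                     method = method)
  assoc <- select_associations(calls, clinical, symptoms, criteria,
                               method = method, all_tested = TRUE)
  pos_char <- lapply(stats::setNames(nm = unique(assoc$antigen_id)), function(ag) {
    characterize_positives(ag, calls, clinical, variables, cytokines,
                           method = method)
  })

  params <- list(
    n_individuals = nrow(mfi), n_antigens = ncol(mfi),
    n_symptoms = length(symptoms), variables = variables,
    cytokines = cytokines, criteria = unclass(criteria),
    low_pct = low_pct, high_pct = high_pct, mad_constant = mad_constant,
    slope_threshold = slope_threshold, peak_split = peak_split,
    method = method
  )
  manifest <- list(
    params = params,
    stages = list(
      normalize = list(n_samples = nrow(mfi), n_antigens = ncol(mfi)),
      cutoffs = list(table = table(cutoffs$cutoff)),
      calls = list(n_detected = sum(calls$detected),
                   sparsity_detected = call_sparsity(calls),
                   count_median = count_summary$individual$median,
                   count_mean = count_summary$individual$mean),
      strata = list(low_threshold = strata$low_threshold,
                    high_threshold = strata$high_threshold,
                    n_low = length(strata$low_ids),
                    n_high = length(strata$high_ids)),
      associations = list(n_selected = nrow(assoc),
                          n_tested = nrow(attr(assoc, "tested") %||% assoc))
    )
  )

  out <- structure(
    list(scores = sm, cutoffs = cutoffs, calls = calls,
         count_summary = count_summary, strata = strata,
         strata_characterization = strata_char, associations = assoc,
         positive_characterization = pos_char,
         clinical = clinical, symptoms = symptoms,
         variables = variables, cytokines = cytokines,
         params = params, manifest = manifest),
    class = "sero_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline(out, output_dir)
  out
}

#' @export
print.sero_pipeline <- function(x, ...) {
  m <- x$manifest$stages
  cat(sprintf(paste0(
    "Profiling pipeline: %d individuals x %d antigens\n",
    "  detected antigens: %d (sparsity among detected %.3f)\n",
    "  autoantibody count: median %g, mean %.1f; strata low < %g (n=%d), high > %g (n=%d)\n",
    "  associations: %d selected of %d tested pairs\n"),
    x$params$n_individuals, x$params$n_antigens,
    m$calls$n_detected, m$calls$sparsity_detected,
    m$calls$count_median, m$calls$count_mean,
    m$strata$low_threshold, m$strata$n_low,
    m$strata$high_threshold, m$strata$n_high,
    m$associations$n_selected, m$associations$n_tested))
  invisible(x)
}

#' Write pipeline stage outputs to a directory
#'
#' Writes the cutoff table, binary call matrix, per-individual counts,
#' stratum membership, stratum characterization, the association table in
#' both exact and presentation form, per-antigen positive-group
#' characterizations, and a JSON run manifest.
#'
#' @param pipeline A `sero_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "sero_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name, row_names = FALSE) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = row_names)
    paths <<- c(paths, p)
  }
  w(pipeline$cutoffs, "cutoffs.csv")
  w(as.data.frame(pipeline$calls$calls), "calls.csv", row_names = TRUE)
  w(data.frame(individual_id = names(pipeline$calls$counts) %||%
                 seq_along(pipeline$calls$counts),
               count = pipeline$calls$counts), "counts.csv")
  st <- pipeline$strata
  w(data.frame(individual_id = c(st$low_ids, st$high_ids),
               stratum = rep(c("low", "high"),
                             c(length(st$low_ids), length(st$high_ids)))),
    "strata.csv")
  w(pipeline$strata_characterization, "strata_characterization.csv")
  w(pipeline$associations, "associations.csv")
  w(format_associations(pipeline$associations), "associations_formatted.csv")
  for (ag in names(pipeline$positive_characterization)) {
    w(pipeline$positive_characterization[[ag]],
      sprintf("characterization_%s.csv", ag))
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(pipeline$manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}

#' Read a raw MFI matrix from CSV
#'
#' Expects a header row of antigen ids and individual ids in the first
#' column (the layout [write_cohort()] produces).
#'
#' @param path CSV file path.
#' @return Numeric matrix, samples in rows.
#' @export
read_mfi_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("MFI file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a clinical table from CSV
#'
#' @param path CSV file path; first column must hold individual ids.
#' @return data.frame.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("clinical file not found: %s", path), call. = FALSE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' MFI and clinical tables as CSV (ids in the first column), ground truth
#' (planted seropositivity matrix and planted pairs) as JSON.
#'
#' @param cohort A `sero_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sero_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mfi_p <- file.path(dir, "mfi.csv")
  utils::write.csv(data.frame(individual_id = rownames(cohort$mfi),
                              cohort$mfi, check.names = FALSE),
                   mfi_p, row.names = FALSE)
  clin_p <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, clin_p, row.names = FALSE)
  truth_p <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted = cohort$truth$planted,
         positives = apply(cohort$truth$matrix, 2, function(col) {
           rownames(cohort$truth$matrix)[col == 1L]
         }, simplify = FALSE)),
    truth_p, auto_unbox = TRUE, digits = NA)
  invisible(c(mfi_p, clin_p, truth_p))
}
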