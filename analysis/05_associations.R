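#!/usr/bin/env Rscript
# Stage 5: antibody-symptom association screen.
# Applies the three selection criteria (group size >= 10, symptom prevalence
# among seropositive >= 85%, prevalence ratio >= 1.25) with a two-sided
# exact test and Benjamini-Hochberg FDR over all pairs passing the
# group-size criterion, then characterizes each selected seropositive group
# against the targeted clinical variables and cytokines (uncorrected,
# explorative). Compares the selected set against the generator's planted
# ground truth.

suppressPackageStartupMessages(library(serosym))
calls_df <- utils::read.csv("results/calls.csv", row.names = 1, check.names = FALSE)
clinical <- read_clinical_csv("results/data/clinical.csv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)

calls_m <- as.matrix(calls_df)
# rebuild a sero_calls object from the stored binary matrix
calls <- call_seropositive(calls_m * 0.1, rep(0.1, ncol(calls_m)))
stopifnot(identical(unname(calls$calls), unname(calls_m)))
symptoms <- grep("^sx[0-9]+$", names(clinical), value = TRUE)

assoc <- select_associations(calls, clinical, symptoms, selection_criteria(),
                             all_tested = TRUE)
cat(sprintf("tested family: %d pairs (antigens with >= 10 positives x testable symptoms)\n",
            nrow(attr(assoc, "tested"))))
cat(sprintf("selected associations: %d\n", nrow(assoc)))
print(format_associations(assoc), row.names = FALSE)

planted <- paste(truth$planted$antigen_id, truth$planted$symptom)
got <- paste(assoc$antigen_id, assoc$symptom)
cat(sprintf("planted recovery: %d/%d recovered, %d false selections\n",
            sum(planted %in% got), length(planted), sum(!got %in% planted)))

dir.create("results", showWarnings = FALSE)
utils::write.csv(assoc, "results/associations.csv", row.names = FALSE)
utils::write.csv(format_associations(assoc), "results/associations_formatted.csv",
                 row.names = FALSE)
for (ag in unique(assoc$antigen_id)) {
  res <- characterize_positives(ag, calls, clinical,
                                variables = c("sex_female", "clozapine_use",
                                              "thought_disorder",
                                              "affective_diagnosis",
                                              "family_history_heart_disease"),
                                cytokines = c("IL4", "IL6", "IL8", "IL10",
                                              "CuZn_SOD"))
  utils::write.csv(res, sprintf("results/characterization_%s.csv", ag),
                   row.names = FALSE)
  sig <- res[res$p < 0.05, ]
  if (nrow(sig)) {
    cat(sprintf("%s positives differ on: %s\n", ag,
                paste(sprintf("%s (p=%.3g, OR=%.2g)", sig$variable, sig$p, sig$or),
                      collapse = "; ")))
  }
}
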