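#!/usr/bin/env Rscript
# Stage 4: autoantibody-count profile.
# Summarizes the per-individual and per-antigen count distributions (with a
# Shapiro-Wilk normality check of the former), stratifies individuals at
# the 5th/95th count percentiles into low/high groups, characterizes both
# strata against the targeted clinical variables and median-dichotomized
# cytokines, and clusters the binary profiles (complete linkage, Euclidean).

suppressPackageStartupMessages(library(serosym))
counts_df <- utils::read.csv("results/counts.csv")
calls_df <- utils::read.csv("results/calls.csv", row.names = 1, check.names = FALSE)
clinical <- read_clinical_csv("results/data/clinical.csv")

calls_m <- as.matrix(calls_df)
counts <- stats::setNames(counts_df$count, counts_df$individual_id)

cat(sprintf("per-individual count: median %g, mean %.1f, range %d-%d\n",
            median(counts), mean(counts), min(counts), max(counts)))
sw <- stats::shapiro.test(counts)
cat(sprintf("Shapiro-Wilk: W = %.3f, p = %.3g\n", sw$statistic, sw$p.value))
ant <- colSums(calls_m)[colSums(calls_m) > 0]
cat(sprintf("per detected antigen: median %g, mean %.1f, range %d-%d (%d detected)\n",
            median(ant), mean(ant), min(ant), max(ant), length(ant)))

strata <- stratify_counts(counts)
print(strata)
chars <- characterize_strata(strata, clinical,
                             variables = c("sex_female", "family_history_obesity",
                                           "family_history_psych_other",
                                           "family_history_heart_disease",
                                           "clozapine_use", "thought_disorder",
                                           "affective_diagnosis"),
                             cytokines = c("IL4", "IL6", "IL8", "IL10", "CuZn_SOD"))
sig <- chars[chars$p < 0.05, c("stratum", "variable", "p", "or", "ci_low", "ci_high")]
cat("stratum features at p < 0.05 (explorative, uncorrected):\n")
print(sig, row.names = FALSE, digits = 3)

hc <- cluster_profiles(calls_m)
utils::write.csv(data.frame(individual_id = c(strata$low_ids, strata$high_ids),
                            stratum = rep(c("low", "high"),
                                          c(length(strata$low_ids),
                                            length(strata$high_ids)))),
                 "results/strata.csv", row.names = FALSE)
utils::write.csv(chars, "results/strata_characterization.csv", row.names = FALSE)
jsonlite::write_json(list(merge = hc$merge, height = hc$height, order = hc$order,
                          labels = hc$labels),
                     "results/profile_dendrogram.json", digits = NA)
cat(sprintf("clustering: %d leaves, first merge height %.2f, last %.2f\n",
            length(hc$order), min(hc$height), max(hc$height)))
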