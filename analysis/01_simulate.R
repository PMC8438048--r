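#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
# Generates (a) eight planar-array plasma pools with planted hits for the
# broad screen, and (b) a full synthetic bead-array cohort — 461 individuals
# x 380 antigens, 205 symptom columns, six planted antibody-symptom
# associations — and writes both under results/data/.

suppressPackageStartupMessages(library(serosym))
seed <- 20260924L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pools <- generate_planar_pools(n_pools = 8, n_antigens = 4000,
                               n_hits_per_pool = 18, seed = seed)
saveRDS_path <- NULL # all hand-offs are plain text
utils::write.csv(data.frame(antigen_id = colnames(pools$signals),
                            t(pools$signals)),
                 file.path(out, "planar_pools.csv"), row.names = FALSE)
jsonlite::write_json(pools$truth, file.path(out, "planar_truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("planar pools: %d pools x %d antigens, %d planted hits in the union\n",
            nrow(pools$signals), ncol(pools$signals), length(pools$truth$union)))

cohort <- generate_cohort(cohort_config(seed = seed))
write_cohort(cohort, out)
cat(sprintf("cohort: %d x %d MFI matrix, %d planted associations, %.1f%% truth cells seropositive\n",
            nrow(cohort$mfi), ncol(cohort$mfi), nrow(cohort$truth$planted),
            100 * mean(cohort$truth$matrix)))
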