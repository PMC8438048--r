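#!/usr/bin/env Rscript
# Stage 3: bead-array normalization, scoring, and seropositivity calling.
# xMAD-normalizes the raw MFI per sample, bins onto the 16-level score
# scale, sets a per-antigen detection cutoff with the kernel-density
# peak/slope algorithm, and calls seropositivity. Writes the cutoff table,
# the binary call matrix, and per-individual counts under results/.

suppressPackageStartupMessages(library(serosym))
mfi <- read_mfi_csv("results/data/mfi.csv")

sm <- score_matrix(mfi)
cutoffs <- detect_cutoffs(sm$scores, quiet = TRUE)
calls <- call_seropositive(sm$scores, cutoffs)
print(calls)
cat(sprintf("cutoff levels used: %s\n",
            paste(sprintf("%.1f (n=%d)", as.numeric(names(table(cutoffs$cutoff))),
                          as.vector(table(cutoffs$cutoff))), collapse = ", ")))
cat(sprintf("sparsity among detected autoantibodies: %.1f%%\n",
            100 * call_sparsity(calls)))

dir.create("results", showWarnings = FALSE)
utils::write.csv(cutoffs, "results/cutoffs.csv", row.names = FALSE)
utils::write.csv(as.data.frame(calls$calls), "results/calls.csv", row.names = TRUE)
utils::write.csv(data.frame(individual_id = names(calls$counts),
                            count = calls$counts),
                 "results/counts.csv", row.names = FALSE)
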