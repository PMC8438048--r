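Package: serosym
Title: Autoantibody Profiling and Symptom Association Analysis for Serology Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antigen-array autoantibody profiling of
    clinical cohorts. Implements per-array standardization and 8-SD selection
    for planar protein microarray screening; per-sample robust normalization
    (xMAD = (MFI - median)/MAD) and 16-level scoring of bead-array median
    fluorescence intensities; a kernel-density peak/slope algorithm that sets
    per-antigen seropositivity cutoffs; per-individual autoantibody-count
    stratification with exact-test characterization; a three-criterion
    antibody-symptom association screen (group size, symptom prevalence,
    prevalence ratio) with exact tests and Benjamini-Hochberg FDR control;
    one-at-a-time sensitivity analysis of cutoffs and criteria; and a
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
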