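# Build a tiny sero_calls + clinical pair by hand for focused screen tests.
mini_cohort <- function() {
  n <- 60
  calls <- matrix(0L, n, 2, dimnames = list(paste0("i", 1:n), c("agA", "agB")))
  calls[1:9, "agA"] <- 1L      # below the group-size criterion
  calls[1:12, "agB"] <- 1L     # above it
  scores <- calls * 0.5        # any scores consistent with the calls
  sc <- call_seropositive(scores, c(0.2, 0.2))
  stopifnot(identical(unname(sc$calls), unname(calls)))
  clin <- data.frame(individual_id = paste0("i", 1:n),
                     sxPerfect = as.integer(seq_len(n) <= 12),
                     sxNoise = rep(c(0L, 1L), n / 2))
  list(calls = sc, clinical = clin)
}

test_that("the group-size criterion excludes small groups regardless of effect", {
  mc <- mini_cohort()
  # agA: 9 positives, all with the symptom -> excluded by group size alone
  res <- select_associations(mc$calls, mc$clinical, c("sxPerfect", "sxNoise"),
                             selection_criteria(min_positives = 10))
  expect_false("agA" %in% res$antigen_id)
  expect_true(all(res$n_pos >= 10))
  # agB's 12 positives coincide exactly with sxPerfect -> selected
  expect_true(any(res$antigen_id == "agB" & res$symptom == "sxPerfect"))
  row <- res[res$antigen_id == "agB" & res$symptom == "sxPerfect", ]
  expect_equal(row$p_sx_pos, 1)
  expect_equal(row$p_sx_neg, 0)
  expect_identical(row$pr, Inf)
  expect_identical(row$or, Inf)
})

test_that("q-values equal a brute-force BH over the tested family", {
  coh <- generate_cohort(small_config(seed = 4))
  pl <- run_pipeline(coh)
  fam <- attr(pl$associations, "tested")
  expect_gt(nrow(fam), 100)
  expect_equal(fam$q, oracle_bh(fam$p))
  expect_true(all(fam$q >= fam$p))
})

test_that("planted associations are recovered exactly, and a null cohort yields none", {
  coh <- generate_cohort(small_config(seed = 5))
  pl <- run_pipeline(coh)
  expect_equal(nrow(pl$associations), 3L)
  got <- paste(pl$associations$antigen_id, pl$associations$symptom)
  want <- paste(coh$truth$planted$antigen_id, coh$truth$planted$symptom)
  expect_setequal(got, want)

  null_coh <- generate_cohort(small_config(seed = 6, n_planted = 0))
  null_pl <- run_pipeline(null_coh)
  expect_equal(nrow(null_pl$associations), 0L)
})

test_that("tightening any criterion never adds associations", {
  coh <- generate_cohort(small_config(seed = 7))
  pl <- run_pipeline(coh)
  base <- select_associations(pl$calls, coh$clinical, cohort_symptoms(coh),
                              selection_criteria())
  key <- function(df) paste(df$antigen_id, df$symptom)
  tighter <- list(
    selection_criteria(min_positives = 25),
    selection_criteria(min_prevalence_pos = 0.95),
    selection_criteria(min_prevalence_ratio = 2.0),
    selection_criteria(alpha_fdr = 0.01)
  )
  for (crit in tighter) {
    res <- select_associations(pl$calls, coh$clinical, cohort_symptoms(coh), crit)
    expect_true(all(key(res) %in% key(base)))
  }
  # and every emitted record satisfies PR > 1 <=> OR > 1
  expect_true(all((base$pr > 1) == (base$or > 1)))
})

test_that("the percentage-point reading of the third criterion is available", {
  mc <- mini_cohort()
  # sxNoise has ~50% prevalence in both groups: fails either reading
  ratio <- select_associations(mc$calls, mc$clinical, c("sxPerfect", "sxNoise"),
                               selection_criteria())
  diff <- select_associations(mc$calls, mc$clinical, c("sxPerfect", "sxNoise"),
                              selection_criteria(ratio_as_difference = TRUE))
  expect_false("sxNoise" %in% ratio$symptom)
  expect_false("sxNoise" %in% diff$symptom)
  expect_true("sxPerfect" %in% diff$symptom)
})

test_that("positive-group characterization behaves under planted and null signal", {
  coh <- generate_cohort(small_config(seed = 8))
  pl <- run_pipeline(coh)
  ag <- coh$truth$planted$antigen_id[[1]]
  res <- characterize_positives(ag, pl$calls, coh$clinical,
                                c("sex_female", "thought_disorder"),
                                cytokines = "IL6")
  expect_setequal(res$variable, c("sex_female", "thought_disorder", "IL6"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_error(characterize_positives("nope", pl$calls, coh$clinical, "sex_female"),
               "not in call matrix")

  # permuted (independent) variables: no systematic signal
  set.seed(61)
  clin <- coh$clinical
  pvals <- replicate(100, {
    clin$perm <- sample(clin$sex_female)
    characterize_positives(ag, pl$calls, clin, "perm")$p
  })
  expect_lte(mean(pvals < 0.05), 0.1)
})

test_that("presentation formatting renders infinities and rounded prevalences", {
  assoc <- data.frame(antigen_id = "ag", symptom = "sx", n_pos = 23,
                      a = 21, b = 2, c = 241, d = 197,
                      p_sx_pos = 21 / 23, p_sx_neg = 241 / 438,
                      pr = (21 / 23) / (241 / 438),
                      p = 0.00037, q = 0.01, or = Inf, ci_low = 2.3, ci_high = Inf)
  fm <- format_associations(assoc)
  expect_equal(fm$p_sx_pos_pct, 91)
  expect_equal(fm$p_sx_neg_pct, 55)
  expect_equal(fm$pr, 1.7)
  expect_identical(fm$or, "Inf")
  expect_identical(fm$ci_high, "Inf")
})
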