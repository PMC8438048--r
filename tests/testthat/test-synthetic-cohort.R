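test_that("the generator is deterministic in config and seed", {
  c1 <- generate_cohort(small_config(seed = 9))
  c2 <- generate_cohort(small_config(seed = 9))
  expect_identical(c1$mfi, c2$mfi)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(small_config(seed = 10))
  expect_false(identical(c1$mfi, c3$mfi))
})

test_that("zero spike rate yields an all-zero truth matrix", {
  coh <- generate_cohort(small_config(seed = 11, n_planted = 0, spike_rate = 0))
  expect_equal(sum(coh$truth$matrix), 0)
  expect_warning(
    generate_cohort(small_config(seed = 11, n_planted = 2, spike_rate = 0)),
    "n_planted ignored"
  )
})

test_that("the realized spike fraction matches the configured rate", {
  coh <- generate_cohort(cohort_config(seed = 12))
  p <- coh$config$spike_rate
  n_cells <- length(coh$truth$matrix)
  sd_binom <- sqrt(p * (1 - p) / n_cells)
  expect_lt(abs(mean(coh$truth$matrix) - p), 3 * sd_binom)
  expect_identical(dim(coh$truth$matrix), dim(coh$mfi))
})

test_that("every planted pair passes all three selection criteria in the truth", {
  coh <- generate_cohort(small_config(seed = 13))
  crit <- selection_criteria()
  for (k in seq_len(nrow(coh$truth$planted))) {
    pl <- coh$truth$planted[k, ]
    pos <- coh$truth$matrix[, pl$antigen_id]
    sx <- coh$clinical[[pl$symptom]]
    tab <- tabulate_pair(pos, sx)
    n_pos <- sum(tab[1, ])
    prev_pos <- tab[1, 1] / sum(tab[1, ])
    prev_neg <- tab[2, 1] / sum(tab[2, ])
    expect_gte(n_pos, crit$min_positives)
    expect_gte(prev_pos, crit$min_prevalence_pos)
    expect_gte(prev_pos / prev_neg, crit$min_prevalence_ratio)
  }
})

test_that("infeasible planted margins fail loudly", {
  cfg <- small_config(seed = 14)
  cfg$planted_margins$n_pos <- 5          # below the group-size criterion
  expect_error(generate_cohort(cfg), "infeasible planted margins")
  cfg2 <- small_config(seed = 14)
  cfg2$planted_margins$prev_pos <- 0.5    # below the prevalence criterion
  expect_error(generate_cohort(cfg2), "infeasible planted margins")
  cfg3 <- small_config(seed = 14)
  cfg3$planted_margins$n_pos <- 10 * cfg3$n_individuals
  expect_error(generate_cohort(cfg3), "cohort size")
})

test_that("the high-count-female switch plants a sex effect in the strata", {
  coh <- generate_cohort(small_config(seed = 15, n_planted = 0,
                                      high_count_female_effect = 2))
  counts <- rowSums(coh$truth$matrix)
  st <- stratify_counts(setNames(counts, coh$clinical$individual_id))
  res <- characterize_strata(st, coh$clinical, "sex_female")
  high <- res[res$stratum == "high" & res$variable == "sex_female", ]
  expect_gt(high$or, 1)

  # default: sex independent of the profile (no systematic enrichment)
  coh0 <- generate_cohort(small_config(seed = 15, n_planted = 0))
  expect_equal(coh0$config$high_count_female_effect, 0)
})

test_that("planar pool generation is deterministic and respects its guards", {
  p1 <- generate_planar_pools(4, 1000, 8, seed = 16)
  p2 <- generate_planar_pools(4, 1000, 8, seed = 16)
  expect_identical(p1$signals, p2$signals)
  expect_identical(p1$truth, p2$truth)
  expect_error(generate_planar_pools(4, 100, 100, seed = 1), "smaller")
  expect_error(generate_planar_pools(4, 1000, 50, seed = 1), "unstable")
  # planted hits sit at or beyond 8 SD of their own array
  z <- times_sd(p1$signals[1, ])
  expect_true(all(z[p1$truth$per_pool[[1]]] >= 8))
})
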