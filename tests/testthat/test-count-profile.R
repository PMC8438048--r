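test_that("count summaries follow the call matrix margins", {
  scores <- diag(5) * 0.5
  calls <- call_seropositive(scores, rep(0.2, 5))
  cd <- count_distribution(calls)
  expect_equal(unname(calls$counts), rep(1, 5))
  expect_equal(unname(calls$n_positive), rep(1, 5))
  expect_equal(cd$individual$median, 1)
  expect_equal(cd$antigen$n_detected, 5L)

  # an all-positive antigen column counts every individual
  scores2 <- cbind(rep(0.5, 8), rep(0, 8))
  calls2 <- call_seropositive(scores2, c(0.2, 0.2))
  expect_equal(unname(calls2$n_positive), c(8, 0))
})

test_that("per-individual true counts center on the configured value", {
  coh <- generate_cohort(small_config(seed = 2))
  counts <- rowSums(coh$truth$matrix)
  center <- coh$config$spike_rate * coh$config$n_antigens
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - center), 3 * se)
})

test_that("percentile stratification uses strict inequalities", {
  st <- stratify_counts(setNames(1:100, paste0("i", 1:100)))
  expect_equal(st$low_threshold, quantile(1:100, 0.05, names = FALSE))
  expect_lte(length(st$low_ids), 5)
  expect_lte(length(st$high_ids), 5)
  expect_true(all(st$counts[st$low_ids] < st$low_threshold))
  expect_true(all(st$counts[st$high_ids] > st$high_threshold))
  expect_length(intersect(st$low_ids, st$high_ids), 0)

  # low_pct = 0 gives an empty low stratum (nothing below the minimum)
  expect_length(stratify_counts(1:100, low_pct = 0)$low_ids, 0)

  # values tied with the threshold belong to neither stratum
  tied <- rep(c(10, 20, 30), c(10, 80, 10))   # 5th/95th pct land on 10 and 30
  expect_warning(st2 <- stratify_counts(tied), "empty")
  expect_length(st2$low_ids, 0)
  expect_length(st2$high_ids, 0)
})

test_that("widening the percentile window never shrinks the strata", {
  set.seed(51)
  counts <- rpois(300, 25)
  prev <- NULL
  for (w in c(2.5, 5, 10, 20)) {
    st <- stratify_counts(counts, w, 100 - w)
    if (!is.null(prev)) {
      expect_true(all(prev$low_ids %in% st$low_ids))
      expect_true(all(prev$high_ids %in% st$high_ids))
    }
    prev <- st
  }
})

test_that("group characterization flags perfect association and skips degenerates", {
  clin <- data.frame(individual_id = paste0("i", 1:40),
                     marker = rep(c(1L, 0L), c(10, 30)),
                     flat = rep(1L, 40))
  res <- suppressWarnings(
    characterize_group(paste0("i", 1:10), clin, c("marker", "flat"))
  )
  expect_equal(res$variable, "marker")      # constant variable skipped
  expect_identical(res$or, Inf)
  expect_lt(res$p, 1e-6)
  expect_warning(characterize_group(paste0("i", 1:10), clin, "flat"), "levels")
})

test_that("characterization is valid under the null (permutation battery)", {
  set.seed(52)
  n <- 300
  group <- paste0("i", sample(n, 30))
  clin0 <- data.frame(individual_id = paste0("i", 1:n))
  pvals <- replicate(200, {
    clin0$v <- rbinom(n, 1, 0.5)
    characterize_group(group, clin0, "v")$p
  })
  expect_lte(mean(pvals < 0.05), 0.08)      # type-I error held at/below nominal
  expect_gt(mean(pvals), 0.4)               # p's roughly uniform (exact-test conservative)
})

test_that("complete-linkage clustering matches hand and brute-force oracles", {
  # two identical profiles merge first at height zero
  x <- rbind(c(0, 0), c(0, 0), c(3, 4))
  expect_equal(cluster_profiles(x)$height[[1]], 0)

  # collinear points at distances 1, 1, 2: merge the close pair, then join at 2
  y <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(cluster_profiles(y)$height, c(1, 2))

  set.seed(53)
  for (i in 1:5) {
    z <- matrix(rnorm(sample(5:20, 1) * 4), ncol = 4)
    expect_equal(sort(cluster_profiles(z)$height),
                 sort(oracle_complete_linkage_heights(z)))
  }

  # permuting the input leaves the merge heights unchanged
  z <- matrix(rnorm(12 * 3), ncol = 3)
  perm <- sample(nrow(z))
  expect_equal(sort(cluster_profiles(z)$height),
               sort(cluster_profiles(z[perm, ])$height))
})
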