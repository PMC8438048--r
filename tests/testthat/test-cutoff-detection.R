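test_that("a sparse antigen gets a cutoff just above background and exact calls", {
  scores <- c(rep(0, 450), rep(0.4, 11))
  rec <- detect_cutoff(scores)
  expect_equal(rec$direction, "up")
  expect_lt(abs(rec$peak_x), 0.05)
  expect_true(rec$cutoff %in% c(0.1, 0.2))
  expect_equal(rec$n_positive, 11L)
})

test_that("a highly reactive antigen is walked downward from its peak", {
  scores <- rep(c(1.0, 1.1, 1.2, 1.3, 1.4), c(30, 100, 200, 100, 30))
  rec <- detect_cutoff(scores)
  expect_gt(rec$peak_x, 0.75)
  expect_equal(rec$direction, "down")
  # the down-walk with round-up keeps the peak population seropositive
  expect_gte(rec$n_positive, 200L)
})

test_that("cutoffs land on score steps via round-up", {
  expect_equal(serosym:::ceiling_score_step(0.13), 0.2)
  expect_equal(serosym:::ceiling_score_step(0.2), 0.2)
  expect_equal(serosym:::ceiling_score_step(0.101), 0.2)
  set.seed(31)
  scores <- matrix(sample(seq(0, 1.5, 0.1), 200 * 12, TRUE,
                          prob = c(8, 8, rep(1, 14))), 200, 12)
  cuts <- detect_cutoffs(scores, quiet = TRUE)
  expect_true(all(serosym:::score_tenths(cuts$cutoff) %in% 0:16))
  expect_equal(cuts$cutoff, round(cuts$cutoff, 1))
})

test_that("a constant score vector yields an all-seronegative antigen with a warning", {
  expect_warning(rec <- detect_cutoff(rep(0.1, 100), antigen_id = "flat"),
                 "constant")
  expect_equal(rec$n_positive, 0L)
  expect_gt(rec$cutoff, 0.1)
})

test_that("cutoff detection separates background from spikes on a seeded battery", {
  # >= 100 well-separated antigens: background concentrated at score 0, or
  # majority 0.1 with a substantial (>= 30%) minority at 0 so the bandwidth
  # rule keeps the two background modes resolved; spikes at 0.4+.
  set.seed(32)
  n <- 461
  wrong <- 0L
  for (i in 1:120) {
    n_spike <- sample(10:40, 1)
    spikes <- sample(seq(0.4, 1.5, 0.1), n_spike, replace = TRUE)
    bg <- if (i %% 2 == 0) {
      rep(0, n - n_spike)
    } else {
      k0 <- round(runif(1, 0.3, 0.45) * (n - n_spike))
      rep(c(0, 0.1), c(k0, n - n_spike - k0))
    }
    scores <- c(bg, spikes)
    truth <- c(rep(0L, length(bg)), rep(1L, n_spike))
    rec <- detect_cutoff(scores)
    called <- as.integer(serosym:::score_tenths(scores) >=
                           serosym:::score_tenths(rec$cutoff))
    if (!identical(called, truth)) wrong <- wrong + 1L
  }
  expect_equal(wrong, 0L)   # sensitivity and specificity both 1 throughout
})

test_that("cutoff detection is deterministic", {
  set.seed(33)
  scores <- sample(seq(0, 1.5, 0.1), 300, TRUE, prob = c(10, 6, rep(0.5, 14)))
  expect_identical(detect_cutoff(scores), detect_cutoff(scores))
})

test_that("raising a cutoff never increases the positive count", {
  set.seed(34)
  scores <- matrix(sample(seq(0, 1.5, 0.1), 100 * 5, TRUE), 100, 5)
  prev <- NULL
  for (cut in seq(0, 1.6, 0.1)) {
    n_pos <- call_seropositive(scores, rep(cut, 5))$n_positive
    if (!is.null(prev)) expect_true(all(n_pos <= prev))
    prev <- n_pos
  }
})

test_that("seropositivity calling is inclusive, shape-checked, and null-safe", {
  scores <- matrix(c(0.3, 0.2, 0.4, 0.0), 2, 2,
                   dimnames = list(c("i1", "i2"), c("a1", "a2")))
  calls <- call_seropositive(scores, c(0.3, 0.4))
  expect_equal(calls$calls["i1", "a1"], 1L)   # equality counts as positive
  expect_equal(calls$calls["i2", "a1"], 0L)
  expect_equal(calls$counts, c(i1 = 2, i2 = 0))

  expect_error(call_seropositive(scores, c(0.1, 0.2, 0.3)), "length")

  zero <- matrix(0, 5, 3)
  cz <- call_seropositive(zero, rep(0.1, 3))
  expect_equal(sum(cz$counts), 0)
  expect_false(any(cz$detected))
  expect_true(is.na(call_sparsity(cz)))
})
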