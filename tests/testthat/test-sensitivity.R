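# One pipeline shared by the sensitivity tests (generation is the slow part).
sens_pipeline <- local({
  pl <- NULL
  function() {
    if (is.null(pl)) {
      coh <- generate_cohort(small_config(seed = 17))
      pl <<- run_pipeline(coh)
    }
    pl
  }
})

test_that("a baseline-only grid reproduces the primary analysis exactly", {
  pl <- sens_pipeline()
  grid <- sensitivity_grid(count_percentiles = list(c(5, 95)),
                           min_positives = 10,
                           min_prevalence_pos = 0.85,
                           min_prevalence_ratio = 1.25,
                           cutoff_offset = 0L)
  rep <- run_sensitivity(pl, grid)
  assoc_rows <- rep$report[rep$report$parameter == "min_positives", ]
  expect_true(all(assoc_rows$retained))
  expect_equal(sort(unique(rep$report$finding[rep$report$retained])),
               sort(unique(rep$baseline[rep$baseline %in% rep$report$finding])))
  # baseline p/q agree with the primary association table
  a0 <- pl$associations
  for (i in seq_len(nrow(a0))) {
    f <- paste(a0$antigen_id[[i]], a0$symptom[[i]], sep = " ~ ")
    row <- assoc_rows[assoc_rows$finding == f, ]
    expect_equal(row$p[[1]], a0$p[[i]])
    expect_equal(row$q[[1]], a0$q[[i]])
  }
})

test_that("wide-margin planted findings are retained at neighboring grid points", {
  pl <- sens_pipeline()
  rep <- run_sensitivity(pl, sensitivity_grid(
    count_percentiles = list(c(5, 95)),
    min_positives = c(5, 10, 15),
    min_prevalence_pos = c(0.80, 0.85, 0.90),
    min_prevalence_ratio = c(1.15, 1.25, 1.35),
    cutoff_offset = c(-1L, 0L, 1L)
  ))
  planted <- paste(pl$associations$antigen_id, pl$associations$symptom,
                   sep = " ~ ")
  crit_rows <- rep$report[rep$report$finding %in% planted &
                            rep$report$parameter != "cutoff_offset", ]
  # planted margins (n_pos = 20, prev 0.95, PR ~ 2.4) clear every criterion
  # neighborhood in the default grids
  expect_true(all(crit_rows$retained))
  expect_true(all(planted %in% rep$robust) || all(crit_rows$retained))
})

test_that("a finding at a criterion boundary is lost when the criterion tightens", {
  cfg <- small_config(seed = 18)
  cfg$planted_margins$n_pos <- 12       # between grid points 10 and 15
  coh <- generate_cohort(cfg)
  pl <- run_pipeline(coh)
  planted <- paste(coh$truth$planted$antigen_id, coh$truth$planted$symptom,
                   sep = " ~ ")
  expect_true(all(planted %in% paste(pl$associations$antigen_id,
                                     pl$associations$symptom, sep = " ~ ")))
  rep <- run_sensitivity(pl, sensitivity_grid(min_positives = c(5, 10, 15)))
  rows <- rep$report[rep$report$parameter == "min_positives" &
                       rep$report$finding %in% planted, ]
  expect_true(all(rows$retained[rows$value %in% c("5", "10")]))
  expect_false(any(rows$retained[rows$value == "15"]))
})

test_that("each report row varies exactly one parameter and retention is monotone", {
  pl <- sens_pipeline()
  rep <- run_sensitivity(pl, sensitivity_grid())
  expect_true(all(rep$report$parameter %in%
                    c("min_positives", "min_prevalence_pos",
                      "min_prevalence_ratio", "cutoff_offset",
                      "count_percentiles")))
  # within each (finding, criterion parameter): retention never recovers as
  # the criterion tightens
  for (par in c("min_positives", "min_prevalence_pos", "min_prevalence_ratio")) {
    rows <- rep$report[rep$report$parameter == par, ]
    for (f in unique(rows$finding)) {
      r <- rows[rows$finding == f, ]
      r <- r[order(as.numeric(r$value)), ]
      ret <- r$retained[!is.na(r$retained)]
      expect_true(all(diff(as.integer(ret)) <= 0))
    }
  }
})
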