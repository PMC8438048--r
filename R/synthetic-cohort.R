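#' Configuration for the synthetic serology cohort generator
#'
#' Describes a synthetic cohort shaped like a targeted bead-array
#' autoantibody study: per-sample background location and scale (lognormal
#' across samples, Gaussian within), per-antigen background offsets
#' (bimodal on the sample scale, so that after per-sample median/MAD
#' normalization roughly half the antigens sit just below the sample median
#' and half just above), sparse heavy-tailed seropositive spikes with known
#' ground truth, an approximately normal per-individual autoantibody count,
#' and a clinical table with planted antibody-symptom associations among
#' independent distractor symptoms.
#'
#' @param n_individuals Cohort size; default 461.
#' @param n_antigens Bead-array panel size; default 380.
#' @param n_symptoms Number of dichotomous psychopathology symptom columns;
#'   default 205.
#' @param n_planted Number of planted antibody-symptom associations;
#'   default 6.
#' @param spike_rate Expected fraction of seropositive (sample, antigen)
#'   cells over the whole matrix; default 25/380, i.e. an expected
#'   autoantibody count of 25 per individual.
#' @param n_undetected Number of antigens with no seropositive individuals
#'   at all; default 68.
#' @param planted_margins List with `n_pos` (seropositive group size of each
#'   planted antigen), `prev_pos` (symptom prevalence among positives) and
#'   `prev_neg` (prevalence among negatives). Realized tables use
#'   deterministic counts (`round(prev * group size)`), so the margins hold
#'   exactly. Defaults: 25, 0.96, 0.40.
#' @param background_location Lognormal (meanlog, sdlog) of per-sample MFI
#'   background level; default `log(2000)`, 0.3.
#' @param background_scale Lognormal (meanlog, sdlog) of per-sample MFI
#'   background spread; default `log(100)`, 0.3.
#' @param antigen_offset List: `modes` (background offset of the low/high
#'   antigen groups, sample-scale units; default -2, 2) and `sd` (spread
#'   around the modes; default 0.7).
#' @param noise_sd Within-sample Gaussian noise, sample-scale units;
#'   default 0.55.
#' @param spike_effect List: `min` (smallest spike displacement, sample-scale
#'   units; default 20), `meanlog`, `sdlog` (lognormal heavy tail added on
#'   top; defaults `log(30)`, 0.9).
#' @param rate_sdlog Lognormal spread of per-antigen seroprevalence rates
#'   (left-skewed per-antigen counts); default 1.1.
#' @param missing_rate MCAR missingness applied to distractor symptoms and
#'   clinical variables; default 0.02. Planted symptom columns stay complete
#'   so the planted margins are exact.
#' @param female_rate Marginal probability of being female; default 0.39.
#' @param high_count_female_effect Logistic effect (per SD of true count) of
#'   autoantibody count on the odds of being female; default 0 (sex
#'   independent of the profile). Set to e.g. 1.5 to plant a "high count is
#'   associated with female sex" signal for stratum characterization tests.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   configuration including the seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 461,
                          n_antigens = 380,
                          n_symptoms = 205,
                          n_planted = 6,
                          spike_rate = 25 / 380,
                          n_undetected = 68,
                          planted_margins = list(n_pos = 25, prev_pos = 0.96,
                                                 prev_neg = 0.40),
                          background_location = list(meanlog = log(2000), sdlog = 0.3),
                          background_scale = list(meanlog = log(100), sdlog = 0.3),
                          antigen_offset = list(modes = c(-2, 2), sd = 0.7),
                          noise_sd = 0.55,
                          spike_effect = list(min = 20, meanlog = log(30), sdlog = 0.9),
                          rate_sdlog = 1.1,
                          missing_rate = 0.02,
                          female_rate = 0.39,
                          high_count_female_effect = 0,
                          seed = 1) {
  stopifnot(n_individuals > 0, n_antigens > 0, n_symptoms > 0, n_planted >= 0,
            spike_rate >= 0, spike_rate < 1,
            n_undetected >= 0, n_undetected <= n_antigens,
            missing_rate >= 0, missing_rate < 1,
            female_rate > 0, female_rate < 1)
  structure(
    list(n_individuals = n_individuals, n_antigens = n_antigens,
         n_symptoms = n_symptoms, n_planted = n_planted,
         spike_rate = spike_rate, n_undetected = n_undetected,
         planted_margins = planted_margins,
         background_location = background_location,
         background_scale = background_scale,
         antigen_offset = antigen_offset, noise_sd = noise_sd,
         spike_effect = spike_effect, rate_sdlog = rate_sdlog,
         missing_rate = missing_rate, female_rate = female_rate,
         high_count_female_effect = high_count_female_effect,
         seed = seed),
    class = "cohort_config"
  )
}

# Validate that the planted margins, as they will be realized with
# deterministic counts, strictly exceed the selection criteria they are
# planted against. Fails loudly rather than generating an untestable cohort.
check_planted_feasible <- function(config, criteria) {
  pm <- config$planted_margins
  n <- config$n_individuals
  if (pm$n_pos > n) {
    stop("infeasible planted margins: n_pos exceeds cohort size", call. = FALSE)
  }
  k_pos <- round(pm$prev_pos * pm$n_pos)
  k_neg <- round(pm$prev_neg * (n - pm$n_pos))
  prev_pos <- k_pos / pm$n_pos
  prev_neg <- k_neg / (n - pm$n_pos)
  if (pm$n_pos < criteria$min_positives ||
      prev_pos < criteria$min_prevalence_pos ||
      prev_neg == 0 || prev_pos / prev_neg < criteria$min_prevalence_ratio) {
    stop(sprintf(
      paste0("infeasible planted margins: realized (n_pos = %d, prev_pos = %.3f, ",
             "PR = %.2f) do not exceed the selection criteria"),
      pm$n_pos, prev_pos,
      if (prev_neg > 0) prev_pos / prev_neg else Inf), call. = FALSE)
  }
  list(k_pos = k_pos, k_neg = k_neg)
}

#' Generate a synthetic bead-array cohort with known ground truth
#'
#' Simulates raw MFI, the true seropositivity matrix, and a clinical table
#' (sex, clinical variables, cytokines, symptom indicators) according to a
#' [cohort_config()]. Planted antibody-symptom associations use
#' deterministic contingency counts so that every planted pair passes the
#' three selection criteria by construction; all other symptoms are
#' independent distractors.
#'
#' @param config A [cohort_config()].
#' @param criteria The [selection_criteria()] the planted margins must
#'   exceed (used only for the feasibility check).
#' @return List of class `sero_cohort`:
#'   \describe{
#'     \item{mfi}{samples x antigens raw MFI matrix}
#'     \item{clinical}{data.frame: individual_id, sex_female, clinical
#'       variables, cytokines, symptom columns}
#'     \item{truth}{list: `matrix` (binary planted seropositivity),
#'       `planted` (data.frame antigen_id/symptom/k_pos/k_neg),
#'       `rates` (per-antigen seroprevalence rates), `offsets`
#'       (per-antigen background offsets)}
#'     \item{config}{the configuration used}
#'   }
#' @export
generate_cohort <- function(config = cohort_config(),
                            criteria = selection_criteria()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_individuals
  A <- config$n_antigens
  set.seed(config$seed)

  ind_ids <- sprintf("ind%04d", seq_len(n))
  ag_ids <- sprintf("AG%04d", seq_len(A))
  sx_ids <- sprintf("sx%03d", seq_len(config$n_symptoms))

  # Antigen background offsets: bimodal on the sample scale so that the
  # score background of each antigen is concentrated on a single score level
  # (0 for the low group, 0.1 for the high group).
  mode_pick <- sample(config$antigen_offset$modes, A, replace = TRUE)
  offsets <- stats::rnorm(A, mode_pick, config$antigen_offset$sd)

  planting <- NULL
  planted_idx <- integer(0)
  n_planted <- config$n_planted
  if (n_planted > 0 && config$spike_rate == 0) {
    warning("spike_rate = 0: no seropositivity to plant; n_planted ignored",
            call. = FALSE)
    n_planted <- 0L
  }
  if (n_planted > 0) {
    planting <- check_planted_feasible(config, criteria)
    # Plant only into antigens whose background sits safely below the sample
    # median (offset <= low mode + 0.2 scale units); antigens in the upper
    # tail of the low group leak background positives into the seropositive
    # set, diluting the planted symptom prevalence below its margin.
    low_mode <- min(config$antigen_offset$modes)
    low_idx <- which(mode_pick == low_mode & offsets <= low_mode + 0.2)
    if (length(low_idx) < n_planted) {
      stop("too few low-offset antigens to plant into", call. = FALSE)
    }
    planted_idx <- sort(sample(low_idx, n_planted))
  }

  # Undetected antigens (rate 0), never overlapping planted ones.
  free_idx <- setdiff(seq_len(A), planted_idx)
  undet_idx <- sort(sample(free_idx, min(config$n_undetected, length(free_idx))))

  # Per-antigen seroprevalence rates: lognormal (left-skewed counts), scaled
  # so the expected fraction of seropositive cells over the whole matrix is
  # exactly spike_rate. Planted antigens contribute their fixed group size.
  rates <- numeric(A)
  rates[planted_idx] <- config$planted_margins$n_pos / n
  open_idx <- setdiff(seq_len(A), c(planted_idx, undet_idx))
  target_total <- config$spike_rate * A - sum(rates[planted_idx])
  if (length(open_idx) && target_total > 0) {
    raw <- stats::rlnorm(length(open_idx), meanlog = 0, sdlog = config$rate_sdlog)
    r <- raw * target_total / sum(raw)
    for (i in seq_len(20)) {           # cap and redistribute the excess
      over <- r > 0.75
      if (!any(over)) break
      excess <- sum(r[over] - 0.75)
      r[over] <- 0.75
      r[!over] <- r[!over] * (1 + excess / sum(r[!over]))
    }
    rates[open_idx] <- pmin(r, 0.75)
  }

  # Ground-truth seropositivity.
  truth <- matrix(0L, n, A, dimnames = list(ind_ids, ag_ids))
  if (config$spike_rate > 0) {
    for (j in open_idx) {
      if (rates[j] > 0) truth[, j] <- stats::rbinom(n, 1L, rates[j])
    }
    for (j in planted_idx) {
      truth[sample(n, config$planted_margins$n_pos), j] <- 1L
    }
  }

  # Raw MFI: sample background (location + scale) with antigen offsets,
  # Gaussian within-sample noise, and heavy-tailed spikes on truth cells,
  # all expressed in units of the sample's own scale.
  loc <- stats::rlnorm(n, config$background_location$meanlog,
                       config$background_location$sdlog)
  scl <- stats::rlnorm(n, config$background_scale$meanlog,
                       config$background_scale$sdlog)
  z <- matrix(stats::rnorm(n * A, 0, config$noise_sd), n, A)
  z <- sweep(z, 2, offsets, "+")
  n_spk <- sum(truth)
  if (n_spk > 0) {
    disp <- config$spike_effect$min +
      stats::rlnorm(n_spk, config$spike_effect$meanlog, config$spike_effect$sdlog)
    z[truth == 1L] <- z[truth == 1L] + disp
  }
  mfi <- pmax(loc + scl * z, 0)
  dimnames(mfi) <- list(ind_ids, ag_ids)

  # Clinical table: sex (optionally tied to the true count), dichotomous
  # clinical variables, cytokines, and symptoms.
  count <- rowSums(truth)
  p_fem <- if (config$high_count_female_effect != 0 && stats::sd(count) > 0) {
    stats::plogis(stats::qlogis(config$female_rate) +
                    config$high_count_female_effect *
                    (count - mean(count)) / stats::sd(count))
  } else rep(config$female_rate, n)
  clinical <- data.frame(
    individual_id = ind_ids,
    sex_female = stats::rbinom(n, 1L, p_fem),
    family_history_obesity = stats::rbinom(n, 1L, 0.15),
    family_history_psych_other = stats::rbinom(n, 1L, 0.25),
    family_history_heart_disease = stats::rbinom(n, 1L, 0.3),
    clozapine_use = stats::rbinom(n, 1L, 0.2),
    thought_disorder = stats::rbinom(n, 1L, 0.35),
    affective_diagnosis = stats::rbinom(n, 1L, 0.3),
    IL4 = stats::rlnorm(n, log(1), 0.8),
    IL6 = stats::rlnorm(n, log(1), 0.8),
    IL8 = stats::rlnorm(n, log(3.6), 0.6),
    IL10 = stats::rlnorm(n, log(2), 0.7),
    CuZn_SOD = stats::rlnorm(n, log(333), 0.4),
    stringsAsFactors = FALSE
  )

  planted_sx <- if (n_planted > 0) sort(sample(config$n_symptoms, n_planted)) else integer(0)
  sx <- matrix(NA_integer_, n, config$n_symptoms, dimnames = list(NULL, sx_ids))
  distractor_prev <- stats::runif(config$n_symptoms, 0.1, 0.7)
  for (s in seq_len(config$n_symptoms)) {
    sx[, s] <- stats::rbinom(n, 1L, distractor_prev[[s]])
  }
  planted_tab <- NULL
  if (n_planted > 0) {
    rows <- vector("list", n_planted)
    for (k in seq_len(n_planted)) {
      j <- planted_idx[[k]]; s <- planted_sx[[k]]
      pos <- which(truth[, j] == 1L)
      neg <- setdiff(seq_len(n), pos)
      col <- integer(n)
      col[sample(pos, planting$k_pos)] <- 1L
      col[sample(neg, planting$k_neg)] <- 1L
      sx[, s] <- col
      rows[[k]] <- data.frame(antigen_id = ag_ids[[j]], symptom = sx_ids[[s]],
                              n_pos = length(pos), k_pos = planting$k_pos,
                              k_neg = planting$k_neg, stringsAsFactors = FALSE)
    }
    planted_tab <- do.call(rbind, rows)
  }

  # MCAR missingness; planted symptom columns and the id stay complete.
  if (config$missing_rate > 0) {
    miss_cols <- setdiff(seq_len(config$n_symptoms), planted_sx)
    for (s in miss_cols) {
      hit <- stats::runif(n) < config$missing_rate
      sx[hit, s] <- NA_integer_
    }
    for (v in setdiff(names(clinical), "individual_id")) {
      hit <- stats::runif(n) < config$missing_rate
      clinical[[v]][hit] <- NA
    }
  }
  clinical <- cbind(clinical, as.data.frame(sx))

  structure(
    list(mfi = mfi, clinical = clinical,
         truth = list(matrix = truth, planted = planted_tab, rates = rates,
                      offsets = offsets),
         config = config),
    class = "sero_cohort"
  )
}

#' @export
print.sero_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d individuals x %d antigens, %d symptoms, %d planted association(s)\n",
    nrow(x$mfi), ncol(x$mfi), x$config$n_symptoms,
    if (is.null(x$truth$planted)) 0L else nrow(x$truth$planted)
  ))
  invisible(x)
}

#' Symptom column names of a synthetic cohort's clinical table
#'
#' @param cohort A `sero_cohort`.
#' @return Character vector of symptom column names.
#' @export
cohort_symptoms <- function(cohort) {
  stopifnot(inherits(cohort, "sero_cohort"))
  grep("^sx[0-9]+$", names(cohort$clinical), value = TRUE)
}

#' Generate planar-array pool signals with planted hits
#'
#' Emulates group-level broad screening: each pool's antigen signals are
#' Gaussian around a common bulk, with `n_hits_per_pool` planted hits well
#' above the 8-SD selection threshold. A configurable fraction of each
#' pool's hits is unique to that pool; the rest are shared between pool
#' pairs, mirroring the highly group-specific profiles such screens produce.
#'
#' @param n_pools Number of pools; default 8.
#' @param n_antigens Antigens per array.
#' @param n_hits_per_pool Planted hits per pool. Must stay below 1\% of
#'   `n_antigens` so the planted mass cannot destabilize the bulk mean/SD.
#' @param seed RNG seed.
#' @param frac_unique Target fraction of the union panel detected in exactly
#'   one pool; default 0.89.
#' @param bulk_mean,bulk_sd Bulk signal distribution; defaults 1000, 100.
#' @param hit_sd_range Planted displacement range in bulk-SD units;
#'   default c(12, 25).
#' @return List of class `planar_pools`: `signals` (pools x antigens matrix),
#'   `truth` (list: per-pool hit ids, union, unique fraction planted).
#' @export
generate_planar_pools <- function(n_pools = 8, n_antigens = 2000,
                                  n_hits_per_pool = 10, seed = 1,
                                  frac_unique = 0.89,
                                  bulk_mean = 1000, bulk_sd = 100,
                                  hit_sd_range = c(12, 25)) {
  stopifnot(n_pools >= 1, n_antigens >= 2, n_hits_per_pool >= 0,
            frac_unique >= 0, frac_unique <= 1)
  if (n_hits_per_pool >= n_antigens) {
    stop("n_hits_per_pool must be smaller than n_antigens", call. = FALSE)
  }
  if (n_hits_per_pool > 0.01 * n_antigens) {
    stop("too many hits per pool: bulk statistics would be unstable", call. = FALSE)
  }
  set.seed(seed)
  ag_ids <- sprintf("PA%05d", seq_len(n_antigens))
  pool_ids <- sprintf("pool%d", seq_len(n_pools))

  # Hit allocation: with shared hits appearing in exactly two pools, a union
  # uniqueness fraction f needs f*h/(2-f) unique hits per pool.
  h <- n_hits_per_pool
  hits <- stats::setNames(vector("list", n_pools), pool_ids)
  if (h > 0) {
    n_unique <- if (n_pools > 1) round(frac_unique * h / (2 - frac_unique)) else h
    n_shared <- h - n_unique
    slots <- rep(n_shared, n_pools)
    pool_of <- rep(list(character(0)), n_pools)
    avail <- sample(ag_ids)                       # draw antigens without reuse
    take <- function(k) { out <- avail[seq_len(k)]; avail <<- avail[-seq_len(k)]; out }
    while (sum(slots) >= 2 && sum(slots > 0) >= 2) {
      pr <- order(slots, decreasing = TRUE)[1:2]  # pair the two fullest pools
      a <- take(1)
      pool_of[[pr[1]]] <- c(pool_of[[pr[1]]], a)
      pool_of[[pr[2]]] <- c(pool_of[[pr[2]]], a)
      slots[pr] <- slots[pr] - 1L
    }
    for (p in seq_len(n_pools)) {
      extra <- n_unique + slots[[p]]              # any unpaired slot stays unique
      hits[[p]] <- c(pool_of[[p]], take(extra))
    }
  }

  signals <- matrix(stats::rnorm(n_pools * n_antigens, bulk_mean, bulk_sd),
                    n_pools, n_antigens, dimnames = list(pool_ids, ag_ids))
  for (p in seq_len(n_pools)) {
    idx <- match(hits[[p]], ag_ids)
    if (length(idx)) {
      disp <- stats::runif(length(idx), hit_sd_range[[1]], hit_sd_range[[2]]) * bulk_sd
      # The hits themselves inflate the array SD, so displacements drawn in
      # bulk-SD units can fall short after standardization; boost any hit
      # below 8.5 realized SD until the planted set clears the 8-SD
      # selection threshold with margin.
      for (iter in 1:30) {
        signals[p, idx] <- bulk_mean + disp
        z <- (signals[p, ] - mean(signals[p, ])) / stats::sd(signals[p, ])
        low <- z[idx] < 8.5
        if (!any(low)) break
        disp[low] <- disp[low] * 1.4
      }
    }
  }
  union_set <- unique(unlist(hits, use.names = FALSE))
  structure(
    list(signals = signals,
         truth = list(per_pool = hits, union = union_set,
                      frac_unique_planted = if (length(union_set)) {
                        sum(table(unlist(hits, use.names = FALSE)) == 1L) / length(union_set)
                      } else NA_real_)),
    class = "planar_pools"
  )
}
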