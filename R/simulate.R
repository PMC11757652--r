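#' Simulate a measurement campaign
#'
#' Generates a synthetic campaign table with the statistical structure the
#' analysis assumes, so every pipeline stage can be exercised against a
#' known truth. For each session a true exhaled Rn-219 concentration is
#' drawn from a lognormal distribution (`true_gm`, `true_gsd`); the
#' inverse physics chain (divide by the in-tube decay factor of the
#' session's flow rate and by the calibration factor, convert kBq/l to
#' kBq/m3) maps it to an ideal instrument reading; two recordings are
#' drawn around that reading with independent multiplicative lognormal
#' noise (`reading_noise_gsd`); readings above the range limit are range
#' censored; and with probability `below_evaluability_prob` the second
#' recording is replaced by a sampling failure (a sub-evaluability
#' reading, e.g. fresh air aspirated past the mouthpiece), which is
#' flagged as an outlier the way a field protocol would flag it.
#'
#' Defaults mirror the measurement campaign: 17 sessions at the late time
#' point, GM 4.4 kBq/l and GSD 1.67, an even mix of the two pump flow
#' rates, ~5% spread between paired recordings, and rare sampling
#' failures.
#'
#' @param n_sessions number of sessions (>= 1).
#' @param timepoint label for every generated session.
#' @param true_gm,true_gsd lognormal population parameters of the true
#'   exhaled concentration (kBq/l; `true_gsd >= 1`).
#' @param flow_mix named proportions over the pump flow rates, e.g.
#'   `c("1" = 0.5, "4" = 0.5)` (l/min).
#' @param reading_noise_gsd multiplicative noise GSD between the two
#'   recordings (>= 1).
#' @param below_evaluability_prob probability that the second recording is
#'   a below-evaluability sampling failure.
#' @param activity_range_MBq range the applied activity is drawn from
#'   (uniform), MBq.
#' @param config an [actinon_config()] supplying the physics constants.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a campaign tibble in the parsed format of [read_campaign()],
#'   with the generating truth attached as attribute `"truth"` (a list
#'   with the parameters and a per-session tibble of true concentrations);
#'   retrieve it with [campaign_truth()].
#' @examples
#' sim <- simulate_campaign(n_sessions = 10, seed = 1)
#' campaign_truth(sim)$params$true_gm
#' @export
simulate_campaign <- function(n_sessions = 17,
                              timepoint = "late",
                              true_gm = 4.4,
                              true_gsd = 1.67,
                              flow_mix = c("1" = 0.5, "4" = 0.5),
                              reading_noise_gsd = 1.05,
                              below_evaluability_prob = 0.02,
                              activity_range_MBq = c(3.1, 5.5),
                              config = actinon_config(),
                              seed = NULL) {
  if (n_sessions < 1) abort("n_sessions must be at least 1")
  if (true_gm <= 0 || true_gsd < 1) {
    abort("need true_gm > 0 and true_gsd >= 1")
  }
  if (reading_noise_gsd < 1) abort("reading_noise_gsd must be >= 1")
  if (below_evaluability_prob < 0 || below_evaluability_prob > 1) {
    abort("below_evaluability_prob must be in [0, 1]")
  }
  if (is.null(names(flow_mix)) ||
      any(is.na(suppressWarnings(as.numeric(names(flow_mix)))))) {
    abort("flow_mix must be named by flow rates in l/min")
  }
  flow_levels <- as.numeric(names(flow_mix))
  instrument <- config_instrument(config)
  nuclide <- nuclide_spec("Rn-219", config$half_life_s)

  with_seed(seed, {
    flow <- flow_levels[sample.int(length(flow_levels), n_sessions,
                                   replace = TRUE,
                                   prob = flow_mix / sum(flow_mix))]
    true_conc <- rlnorm(n_sessions, meanlog = log(true_gm),
                        sdlog = log(true_gsd))
    dfac <- decay_correction_factor(travel_time(config$tube_volume_ml, flow),
                                    nuclide)
    ideal_reading <- true_conc / dfac / config$calibration_factor * 1000
    noise <- function() {
      rlnorm(n_sessions, meanlog = 0, sdlog = log(reading_noise_gsd))
    }
    reading_1 <- ideal_reading * noise()
    reading_2 <- ideal_reading * noise()
    failure_2 <- runif(n_sessions) < below_evaluability_prob
    reading_2[failure_2] <- runif(sum(failure_2),
                                  0.1 * config$evaluability_limit_kbq_m3,
                                  0.9 * config$evaluability_limit_kbq_m3)
    flag_1 <- ifelse(reading_1 > config$range_limit_kbq_m3,
                     "above_range", "ok")
    flag_2 <- ifelse(reading_2 > config$range_limit_kbq_m3,
                     "above_range", "ok")
    activity <- runif(n_sessions, activity_range_MBq[1],
                      activity_range_MBq[2])

    r1 <- evaluate_recording(reading_1, flag_1, flow, instrument,
                             config$tube_volume_ml, nuclide)
    r2 <- evaluate_recording(reading_2, flag_2, flow, instrument,
                             config$tube_volume_ml, nuclide)

    out <- tibble::tibble(
      admin_id = sprintf("S%03d", seq_len(n_sessions)),
      patient_id = NA_character_,
      activity_MBq = activity,
      flow_l_min = flow,
      instrument = instrument$model,
      timepoint = timepoint,
      r1_value = r1$value,
      r1_status = r1$status,
      r2_value = r2$value,
      r2_status = r2$status,
      outlier_2 = failure_2
    )
    truth <- list(
      params = list(
        n_sessions = n_sessions, timepoint = timepoint,
        true_gm = true_gm, true_gsd = true_gsd,
        flow_mix = flow_mix, reading_noise_gsd = reading_noise_gsd,
        below_evaluability_prob = below_evaluability_prob,
        seed = seed
      ),
      sessions = tibble::tibble(
        admin_id = out$admin_id,
        true_concentration = true_conc,
        flow_l_min = flow,
        failure_2 = failure_2
      )
    )
    structure(out, truth = truth)
  })
}

#' @rdname simulate_campaign
#' @param x a tibble returned by [simulate_campaign()].
#' @export
campaign_truth <- function(x) attr(x, "truth")

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a campaign, runs it through the full pipeline
#' (filter, combine — with the outlier heuristic enabled, since simulated
#' sampling failures are flagged the way the generator flags them —,
#' rank, q-q fit, imputation, summary) and compares the estimated
#' geometric mean and geometric SD against the generating truth.
#'
#' @param n_replicates number of simulated campaigns.
#' @param seed integer; replicate `r` uses `seed + r`.
#' @param ... passed to [simulate_campaign()] (e.g. `n_sessions`,
#'   `true_gm`, `true_gsd`).
#' @param config an [actinon_config()].
#' @return a tibble with one row per quantity (`geometric_mean`,
#'   `geometric_sd`): true value, mean estimate, bias, relative bias and
#'   RMSE over replicates. Per-replicate estimates are attached as
#'   attribute `"replicates"`.
#' @examples
#' recovery_experiment(n_replicates = 3, n_sessions = 50, seed = 7)
#' @export
recovery_experiment <- function(n_replicates = 100, seed = 1, ...,
                                config = actinon_config()) {
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  dots <- list(...)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- do.call(simulate_campaign,
                   c(dots, list(config = config, seed = seed + r)))
    est <- suppressWarnings(estimate_campaign(sim, config))
    truth <- campaign_truth(sim)$params
    tibble::tibble(
      replicate = r,
      true_gm = truth$true_gm, est_gm = est$geometric_mean,
      true_gsd = truth$true_gsd, est_gsd = est$geometric_sd
    )
  })
  summarise_quantity <- function(truth, est, name) {
    tibble::tibble(
      quantity = name,
      true = truth[1],
      mean_estimate = mean(est),
      bias = mean(est - truth),
      relative_bias = mean(est - truth) / truth[1],
      rmse = sqrt(mean((est - truth)^2)),
      n_replicates = n_replicates
    )
  }
  out <- dplyr::bind_rows(
    summarise_quantity(reps$true_gm, reps$est_gm, "geometric_mean"),
    summarise_quantity(reps$true_gsd, reps$est_gsd, "geometric_sd")
  )
  structure(out, replicates = reps)
}

# one simulated campaign through the estimation pipeline
estimate_campaign <- function(sim, config = actinon_config()) {
  kept <- filter_campaign(sim, config)
  combined <- combine_recordings(kept, use_printed = FALSE,
                                 outlier_heuristic = TRUE)
  ranked <- rank_dataset(combined, convention = config$plotting_convention)
  fit <- qq_fit(ranked,
                include_less_than = config$include_less_than_in_fit)
  summarize_lognormal(ranked, fit, method = config$percentile_method)
}
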