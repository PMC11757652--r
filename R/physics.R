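#' Nuclide and instrument descriptions
#'
#' `rn219()` describes the measured nuclide: Rn-219 (actinon), the direct
#' progeny of Ra-223, with a half-life of 3.98 s. The decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} used by the in-tube decay correction is
#' derived from this half-life.
#'
#' `instrument_spec()` describes a flow-through radon monitor: the
#' calibration factor converting an instrument reading into an Rn-219
#' activity concentration, the reading below which results cannot be
#' evaluated, the upper range limit above which the display saturates, and
#' whether datasets from the model enter the analysis at all.
#' `alphaguard_pq2000()` is the evaluable instrument used for the
#' measurement campaign (factor 2.3, limits 600 and 2000 kBq/m3);
#' `alphaguard_p30f()` is the early model whose range proved insufficient,
#' so its datasets are discarded by [filter_campaign()].
#'
#' @param name nuclide label.
#' @param half_life_s half-life in seconds; must be positive.
#' @param model instrument model label.
#' @param calibration_factor dimensionless reading-to-concentration factor.
#' @param evaluability_limit_kbq_m3 reading (kBq/m3) below which results are
#'   reported as less-than values.
#' @param range_limit_kbq_m3 reading (kBq/m3) above which the display
#'   saturates and results are reported as greater-than values.
#' @param evaluable logical; do datasets from this model enter the analysis?
#' @return a one-row tibble.
#' @examples
#' rn219()
#' alphaguard_pq2000()
#' @export
nuclide_spec <- function(name, half_life_s) {
  if (!is.numeric(half_life_s) || length(half_life_s) != 1 ||
      is.na(half_life_s) || half_life_s <= 0) {
    abort("half_life_s must be a single positive number")
  }
  tibble::tibble(name = name, half_life_s = half_life_s)
}

#' @rdname nuclide_spec
#' @export
rn219 <- function() nuclide_spec("Rn-219", 3.98)

#' @rdname nuclide_spec
#' @export
instrument_spec <- function(model,
                            calibration_factor = 2.3,
                            evaluability_limit_kbq_m3 = 600,
                            range_limit_kbq_m3 = 2000,
                            evaluable = TRUE) {
  if (calibration_factor <= 0) abort("calibration_factor must be positive")
  if (!(evaluability_limit_kbq_m3 > 0 &&
        evaluability_limit_kbq_m3 < range_limit_kbq_m3)) {
    abort("need 0 < evaluability limit < range limit")
  }
  tibble::tibble(
    model = model,
    calibration_factor = calibration_factor,
    evaluability_limit_kbq_m3 = evaluability_limit_kbq_m3,
    range_limit_kbq_m3 = range_limit_kbq_m3,
    evaluable = evaluable
  )
}

#' @rdname nuclide_spec
#' @export
alphaguard_pq2000 <- function() instrument_spec("PQ2000")

#' @rdname nuclide_spec
#' @export
alphaguard_p30f <- function() {
  # range limit 30 kBq/m3 sits below the evaluability threshold of the
  # Rn-219 calibration, so the model is flagged non-evaluable outright
  instrument_spec("P30F", range_limit_kbq_m3 = 2000, evaluable = FALSE)
}

#' Gas travel time through the sampling tube
#'
#' The exhaled air is pumped from the reservoir through a tube into the
#' monitor's measurement chamber. With tube volume \eqn{V} and pump flow
#' rate \eqn{Q}, the transit time is \eqn{t = V / Q}. For the campaign
#' setup (20 ml tube) this gives 1.2 s at 1 l/min and 0.3 s at 4 l/min.
#'
#' @param tube_volume_ml tube volume in millilitres (>= 0).
#' @param flow_l_min pump flow rate in litres per minute (> 0).
#' @return transit time in seconds.
#' @examples
#' travel_time(20, c(1, 4))
#' @export
travel_time <- function(tube_volume_ml = 20, flow_l_min) {
  if (any(is.na(flow_l_min)) || any(flow_l_min <= 0)) {
    abort("flow_l_min must be positive")
  }
  if (any(tube_volume_ml < 0)) abort("tube_volume_ml must be non-negative")
  (tube_volume_ml / 1000) / flow_l_min * 60
}

#' In-tube radioactive decay correction
#'
#' Rn-219 decays during transit through the sampling tube, so the
#' concentration arriving in the measurement chamber underestimates the
#' concentration at the tube entrance (the exhaled concentration). The
#' multiplicative correction recovering the entrance concentration after a
#' transit time \eqn{t} is \eqn{\exp(\ln 2 \cdot t / T_{1/2})}. With the
#' 3.98 s half-life, 23.4% of the Rn-219 decays during the 1.2 s transit at
#' 1 l/min and 5.4% during the 0.3 s transit at 4 l/min.
#'
#' @param t_s transit time in seconds (>= 0).
#' @param nuclide a [nuclide_spec()]; defaults to [rn219()].
#' @return dimensionless decay-correction factor, >= 1.
#' @examples
#' decay_correction_factor(c(0.3, 1.2))
#' @export
decay_correction_factor <- function(t_s, nuclide = rn219()) {
  if (any(is.na(t_s)) || any(t_s < 0)) abort("t_s must be non-negative")
  exp(log(2) * t_s / nuclide$half_life_s)
}

#' Convert an instrument reading to the chamber concentration
#'
#' Applies the calibration factor (2.3 for the campaign instruments) and
#' changes units from the display's kBq/m3 to kBq/l. The range limit of
#' 2000 kBq/m3 thus corresponds to 4.6 kBq/l in the chamber and the
#' 600 kBq/m3 evaluability limit to 1.38 kBq/l.
#'
#' @param reading_kbq_m3 instrument reading in kBq/m3 (>= 0).
#' @param calibration_factor dimensionless conversion factor.
#' @return Rn-219 activity concentration in the chamber, kBq/l.
#' @examples
#' reading_to_chamber(c(600, 2000))
#' @export
reading_to_chamber <- function(reading_kbq_m3, calibration_factor = 2.3) {
  if (any(!is.na(reading_kbq_m3) & reading_kbq_m3 < 0)) {
    abort("reading_kbq_m3 must be non-negative")
  }
  calibration_factor * reading_kbq_m3 / 1000
}

#' Correct a chamber concentration for in-tube decay
#'
#' Multiplies the chamber concentration by the decay-correction factor to
#' recover the exhaled concentration at the tube entrance. The factor must
#' be at least 1 (decay correction never decreases a concentration).
#'
#' @param chamber_kbq_l concentration in the measurement chamber, kBq/l.
#' @param decay_factor correction factor from [decay_correction_factor()].
#' @return exhaled Rn-219 activity concentration, kBq/l.
#' @examples
#' chamber_to_exhaled(4.6, decay_correction_factor(0.3))
#' @export
chamber_to_exhaled <- function(chamber_kbq_l, decay_factor) {
  if (any(!is.na(decay_factor) & decay_factor < 1)) {
    abort("decay_factor must be >= 1")
  }
  chamber_kbq_l * decay_factor
}

#' Evaluate a raw instrument recording as a censored exhaled concentration
#'
#' The single conversion point from instrument readings (kBq/m3) to exhaled
#' Rn-219 concentrations (kBq/l). An above-range recording becomes a
#' greater-than value at the exhaled equivalent of the range limit; a
#' reading below the evaluability limit becomes a less-than value at the
#' exhaled equivalent of that limit; any other reading becomes a point
#' value via the calibration factor and the in-tube decay correction for
#' the session's flow rate.
#'
#' @param reading_kbq_m3 numeric reading; may be `NA` when `flag` is
#'   `"above_range"`.
#' @param flag `"ok"` for a displayed numeric reading or `"above_range"`
#'   for a saturated display; vectorised.
#' @param flow_l_min pump flow rate, l/min.
#' @param instrument an [instrument_spec()].
#' @param tube_volume_ml sampling-tube volume, ml.
#' @param nuclide a [nuclide_spec()].
#' @return tibble with columns `value` (kBq/l) and `status`.
#' @examples
#' evaluate_recording(c(1000, NA, 400), c("ok", "above_range", "ok"),
#'                    flow_l_min = 4)
#' @export
evaluate_recording <- function(reading_kbq_m3,
                               flag = "ok",
                               flow_l_min,
                               instrument = alphaguard_pq2000(),
                               tube_volume_ml = 20,
                               nuclide = rn219()) {
  n <- max(length(reading_kbq_m3), length(flag), length(flow_l_min))
  reading_kbq_m3 <- vctrs_recycle(reading_kbq_m3, n)
  flag <- vctrs_recycle(flag, n)
  flow_l_min <- vctrs_recycle(flow_l_min, n)
  bad <- !flag %in% c("ok", "above_range")
  if (any(bad)) {
    abort(paste0("unknown recording flag: ",
                 paste(unique(flag[bad]), collapse = ", ")))
  }
  if (any(flag == "ok" & is.na(reading_kbq_m3))) {
    abort("a reading is required unless flag = \"above_range\"")
  }
  dfac <- decay_correction_factor(travel_time(tube_volume_ml, flow_l_min),
                                  nuclide)
  exhaled <- function(r) {
    chamber_to_exhaled(
      reading_to_chamber(r, instrument$calibration_factor), dfac)
  }
  above <- flag == "above_range"
  below <- !above & reading_kbq_m3 < instrument$evaluability_limit_kbq_m3
  value <- ifelse(
    above, exhaled(instrument$range_limit_kbq_m3),
    ifelse(below, exhaled(instrument$evaluability_limit_kbq_m3),
           exhaled(reading_kbq_m3)))
  status <- ifelse(above, "greater_than",
                   ifelse(below, "less_than", "point"))
  tibble::tibble(value = value, status = status)
}
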