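#' Analysis configuration
#'
#' All tunable constants of the pipeline live in one configuration list:
#' the physics constants (calibration factor, instrument limits, tube
#' volume, half-life), the statistical conventions (plotting-position rule,
#' percentile method, treatment of less-than values), the
#' recording-combination options, and the blood-clearance factors used for
#' time-point cross-checks. Defaults reproduce the measurement-campaign
#' setup. A YAML file with any subset of the keys can override the
#' defaults, and `...` overrides both.
#'
#' @param path optional path to a YAML configuration file.
#' @param ... named overrides applied on top of file and defaults, e.g.
#'   `actinon_config(plotting_convention = "blom")`.
#' @return a named list of class `"actinon_config"`.
#' @examples
#' cfg <- actinon_config()
#' cfg$calibration_factor
#' @export
actinon_config <- function(path = NULL, ...) {
  defaults <- list(
    calibration_factor = 2.3,
    evaluability_limit_kbq_m3 = 600,
    range_limit_kbq_m3 = 2000,
    tube_volume_ml = 20,
    half_life_s = 3.98,
    background_kbq_l = 0,
    non_evaluable_models = "P30F",
    plotting_convention = "hazen",
    percentile_method = "distributional",
    include_less_than_in_fit = TRUE,
    use_printed_final = TRUE,
    use_printed_decay_factor = TRUE,
    outlier_heuristic = FALSE,
    clearance_factors = list(
      early_to_late = 3,
      one_min_to_4h = 22.5,
      early_to_late_band = c(4.1, 5.5)
    )
  )
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, dots)
  }
  if (cfg$calibration_factor <= 0) abort("calibration_factor must be positive")
  if (!(cfg$evaluability_limit_kbq_m3 > 0 &&
        cfg$evaluability_limit_kbq_m3 < cfg$range_limit_kbq_m3)) {
    abort("need 0 < evaluability limit < range limit")
  }
  if (!cfg$plotting_convention %in% c("hazen", "weibull", "blom")) {
    abort("plotting_convention must be one of hazen, weibull, blom")
  }
  if (!cfg$percentile_method %in% c("distributional", "empirical")) {
    abort("percentile_method must be distributional or empirical")
  }
  structure(cfg, class = "actinon_config")
}

#' @export
print.actinon_config <- function(x, ...) {
  cat("<actinon_config>\n")
  flat <- x
  flat$clearance_factors <- NULL
  for (k in names(flat)) {
    cat(sprintf("  %-28s %s\n", k, paste(flat[[k]], collapse = ", ")))
  }
  cf <- x$clearance_factors
  cat(sprintf("  clearance: early/late %s, 1 min/4 h %s, band %s\n",
              cf$early_to_late, cf$one_min_to_4h,
              paste(cf$early_to_late_band, collapse = "-")))
  invisible(x)
}

#' Instrument derived from a configuration
#'
#' @param cfg an [actinon_config()].
#' @return an [instrument_spec()] built from the configuration constants.
#' @keywords internal
config_instrument <- function(cfg) {
  instrument_spec("PQ2000",
                  calibration_factor = cfg$calibration_factor,
                  evaluability_limit_kbq_m3 = cfg$evaluability_limit_kbq_m3,
                  range_limit_kbq_m3 = cfg$range_limit_kbq_m3)
}
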