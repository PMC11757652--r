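#' Read a measurement-campaign table
#'
#' A campaign table has one row per administration and time point with
#' columns `admin_id`, `patient_id`, `activity_MBq`, `flow_l_min`,
#' `instrument`, `timepoint` (`"early"` = 20--30 min p.i., `"late"` =
#' 3--4 h p.i.), and two recordings `reading_1`, `reading_2` given as
#' exhaled concentrations in kBq/l in printed censored notation
#' (`"4.51"`, `"> 5.68"`, `"< 1.70"`, `"-"` for absent). `outlier_2`
#' flags a second recording judged to be a sampling failure. Optional
#' columns `decay_factor`, `conv_factor`, `final_printed` and
#' `per_unit_printed` carry values exactly as published for fixtures
#' transcribed from a results table.
#'
#' `read_campaign()` parses the censored notation into paired
#' value/status columns (`r1_value`/`r1_status`, `r2_value`/`r2_status`,
#' and when present `final_printed_value`/`final_printed_status`,
#' `per_unit_printed_value`/`per_unit_printed_status`).
#'
#' @param path path to a delimited text file (comma- or tab-separated).
#' @return a tibble, one row per administration and time point.
#' @seealso [campaign_fixture()] for the packaged study table.
#' @export
read_campaign <- function(path) {
  if (!file.exists(path)) abort(paste0("campaign table not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         progress = FALSE)
  required <- c("admin_id", "activity_MBq", "flow_l_min", "instrument",
                "timepoint", "reading_1", "reading_2")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("campaign table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_tp <- !is.na(raw$timepoint) & !raw$timepoint %in% c("early", "late")
  if (any(bad_tp)) {
    abort(paste0("unknown timepoint label in row(s) ",
                 paste(which(bad_tp), collapse = ", "),
                 " (expected early or late)"))
  }
  out <- raw
  r1 <- parse_censored(out$reading_1)
  r2 <- parse_censored(out$reading_2)
  out$r1_value <- r1$value
  out$r1_status <- r1$status
  out$r2_value <- r2$value
  out$r2_status <- r2$status
  if (!"outlier_2" %in% names(out)) out$outlier_2 <- FALSE
  out$outlier_2 <- isTRUE_vec(out$outlier_2)
  if ("final_printed" %in% names(out)) {
    fp <- parse_censored(out$final_printed)
    out$final_printed_value <- fp$value
    out$final_printed_status <- fp$status
  }
  if ("per_unit_printed" %in% names(out)) {
    pp <- parse_censored(out$per_unit_printed)
    out$per_unit_printed_value <- pp$value
    out$per_unit_printed_status <- pp$status
  }
  dplyr::select(out, -dplyr::any_of(c("reading_1", "reading_2",
                                      "final_printed", "per_unit_printed")))
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == "true")

#' The packaged measurement-campaign table
#'
#' Returns the published results table of the Rn-219 exhalation campaign
#' as a parsed campaign tibble: 17 administrations measured with PQ2000
#' instruments (early and late time points; the early measurement is
#' missing for one administration), transcribed value-for-value from the
#' publication including its printed decay factors, final results and
#' per-unit-activity results. Four further administrations were measured
#' with the Alphaguard P30F, whose range proved insufficient; their data
#' were never published, so they appear as placeholder rows carrying only
#' the instrument model, and exist to exercise [filter_campaign()].
#'
#' @return a campaign tibble (see [read_campaign()] for columns).
#' @examples
#' campaign_fixture()
#' @export
campaign_fixture <- function() {
  path <- system.file("extdata", "published_campaign.csv", package = "actinon")
  read_campaign(path)
}

#' Filter a campaign to analyzable sessions
#'
#' Removes sessions measured with instrument models marked non-evaluable
#' (by default the Alphaguard P30F, whose measurement range was too small
#' for exhaled Rn-219) and sessions with no recordings at all. The
#' exclusions are logged, one row per removed session with a reason, and
#' attached to the result; retrieve them with [exclusion_log()].
#'
#' @param data a campaign tibble from [read_campaign()].
#' @param config an [actinon_config()]; `non_evaluable_models` lists the
#'   instrument models to discard.
#' @return the retained rows, with the exclusion log as an attribute.
#' @examples
#' kept <- filter_campaign(campaign_fixture())
#' dplyr::n_distinct(kept$admin_id)
#' exclusion_log(kept)
#' @export
filter_campaign <- function(data, config = actinon_config()) {
  if (nrow(data) == 0) {
    return(structure(data, exclusions = tibble::tibble(
      admin_id = character(), timepoint = character(), reason = character())))
  }
  non_eval <- data$instrument %in% config$non_evaluable_models
  no_rec <- is.na(data$r1_status) & is.na(data$r2_status)
  reason <- dplyr::case_when(
    non_eval ~ "instrument model not evaluable",
    no_rec ~ "no recordings",
    TRUE ~ NA_character_
  )
  log <- tibble::tibble(
    admin_id = data$admin_id[!is.na(reason)],
    timepoint = data$timepoint[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept <- data[is.na(reason), , drop = FALSE]
  structure(kept, exclusions = log)
}

#' @rdname filter_campaign
#' @param x a tibble returned by [filter_campaign()].
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(admin_id = character(), timepoint = character(),
                   reason = character())
}

#' Combine one pair of recordings into a final censored result
#'
#' Two instrument readings were recorded per session at an interval of a
#' few minutes; they are combined into one final result per session:
#' \itemize{
#'   \item two point values: their arithmetic mean, as a point value;
#'   \item two greater-than values: greater-than at the (common) bound —
#'     unequal bounds combine to the smaller, weaker bound with a warning;
#'   \item a point value paired with a greater-than: "greater than the
#'     lower value", i.e. greater-than at the smaller of the two numbers;
#'   \item two less-than values: less-than at the bound;
#'   \item a point value paired with a less-than value flagged as an
#'     outlier (sampling failure aspirating fresh air): the point value
#'     alone;
#'   \item a single recording: that recording.
#' }
#' A point value paired with an unflagged less-than value has no
#' principled combination and raises an error unless
#' `outlier_heuristic = TRUE`, in which case the less-than recording is
#' discarded with a warning.
#'
#' @param value_1,status_1 first recording (kBq/l, censor status).
#' @param value_2,status_2 second recording, or `NA` if absent.
#' @param outlier_2 logical; is the second recording a flagged outlier?
#' @param outlier_heuristic logical; auto-discard an unflagged less-than
#'   recording whose partner is a point value.
#' @return a one-row tibble with `value` and `status`.
#' @examples
#' combine_pair(4.85, "point", 4.18, "point")        # mean 4.51(5)
#' combine_pair(5.53, "point", 5.68, "greater_than") # > 5.53
#' @export
combine_pair <- function(value_1, status_1, value_2, status_2,
                         outlier_2 = FALSE, outlier_heuristic = FALSE) {
  check_status(status_1)
  check_status(status_2)
  if (is.na(status_1) && is.na(status_2)) {
    abort("at least one recording must be present")
  }
  if (isTRUE(outlier_2) && !is.na(status_1)) {
    return(censored(value_1, status_1))
  }
  if (is.na(status_2)) return(censored(value_1, status_1))
  if (is.na(status_1)) return(censored(value_2, status_2))
  s <- sort(c(status_1, status_2))
  if (status_1 == "point" && status_2 == "point") {
    return(censored(mean(c(value_1, value_2)), "point"))
  }
  if (status_1 == "greater_than" && status_2 == "greater_than") {
    if (value_1 != value_2) {
      warn("greater-than recordings with unequal bounds; combining to the smaller bound")
    }
    return(censored(min(value_1, value_2), "greater_than"))
  }
  if (identical(s, c("greater_than", "point"))) {
    return(censored(min(value_1, value_2), "greater_than"))
  }
  if (status_1 == "less_than" && status_2 == "less_than") {
    return(censored(min(value_1, value_2), "less_than"))
  }
  if (identical(s, c("less_than", "point"))) {
    if (outlier_heuristic) {
      warn("discarding a less-than recording paired with a point value (outlier heuristic)")
      keep <- if (status_1 == "point") 1L else 2L
      return(censored(c(value_1, value_2)[keep], "point"))
    }
    abort(paste0(
      "cannot combine a point value with an unflagged less-than recording; ",
      "flag the outlier or enable outlier_heuristic"))
  }
  abort("cannot combine a greater-than with a less-than recording")
}

#' Combine paired recordings across a campaign table
#'
#' Applies [combine_pair()] row-wise, adding `final_value` and
#' `final_status` columns. When the table carries published final results
#' (`final_printed_value`) and `use_printed = TRUE`, those are used
#' verbatim so that a transcribed results table is reproduced exactly;
#' recombination from the recordings is the fallback for rows without a
#' printed final.
#'
#' @param data a campaign tibble (after [filter_campaign()]).
#' @param use_printed prefer printed final results when present.
#' @param outlier_heuristic passed to [combine_pair()].
#' @return `data` with `final_value` and `final_status` columns.
#' @export
combine_recordings <- function(data, use_printed = TRUE,
                               outlier_heuristic = FALSE) {
  combined <- purrr::pmap_dfr(
    list(data$r1_value, data$r1_status, data$r2_value, data$r2_status,
         data$outlier_2),
    function(v1, s1, v2, s2, o2) {
      combine_pair(v1, s1, v2, s2, outlier_2 = o2,
                   outlier_heuristic = outlier_heuristic)
    })
  out <- data
  out$final_value <- combined$value
  out$final_status <- combined$status
  if (use_printed && "final_printed_value" %in% names(out)) {
    has <- !is.na(out$final_printed_status)
    out$final_value[has] <- out$final_printed_value[has]
    out$final_status[has] <- out$final_printed_status[has]
  }
  out
}

#' Normalise final results per unit applied activity
#'
#' Divides each final concentration by the administered Ra-223 activity,
#' preserving the censor status, and adds `per_unit_value` (kBq/(l MBq))
#' and `per_unit_status` columns.
#'
#' @param data a campaign tibble with `final_value`/`final_status`.
#' @param use_printed prefer printed per-unit results when present
#'   (`per_unit_printed_value` column), mirroring [combine_recordings()].
#' @return `data` with `per_unit_value` and `per_unit_status` columns.
#' @export
per_unit_activity <- function(data, use_printed = TRUE) {
  if (any(!is.na(data$final_value) &
          (is.na(data$activity_MBq) | data$activity_MBq <= 0))) {
    abort("applied activity must be positive for every session with a result")
  }
  out <- data
  out$per_unit_value <- out$final_value / out$activity_MBq
  out$per_unit_status <- out$final_status
  if (use_printed && "per_unit_printed_value" %in% names(out)) {
    has <- !is.na(out$per_unit_printed_status)
    out$per_unit_value[has] <- out$per_unit_printed_value[has]
    out$per_unit_status[has] <- out$per_unit_printed_status[has]
  }
  out
}
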