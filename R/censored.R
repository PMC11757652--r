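#' Censored concentration values
#'
#' Measurement results carry a censor status alongside the numeric value:
#' `"point"` for an ordinary measured value, `"greater_than"` when the true
#' value is only known to exceed the stated bound (the instrument's range
#' limit was hit), and `"less_than"` when it is only known to lie below the
#' bound (the reading fell under the evaluability limit). Throughout the
#' package censored results travel as a value column plus a status column;
#' the status is never encoded in the number itself.
#'
#' `censored()` builds a tibble of value/status pairs, `parse_censored()`
#' converts printed strings such as `"> 4.85"` or `"<1.70"`, and
#' `format_censored()` renders values back to that notation.
#'
#' @param value numeric concentration (the value, or the bound if censored).
#' @param status one of `"point"`, `"greater_than"`, `"less_than"`.
#' @param x character vector of printed results (`"4.51"`, `"> 5.68"`, ...).
#' @return `censored()` and `parse_censored()` return a tibble with columns
#'   `value` and `status`; `format_censored()` a character vector.
#' @examples
#' parse_censored(c("4.51", "> 5.68", "<1.70"))
#' format_censored(c(4.51, 5.68), c("point", "greater_than"))
#' @export
censored <- function(value, status = "point") {
  status <- vctrs_recycle(status, length(value))
  check_status(status)
  if (any(!is.na(value) & value <= 0)) {
    abort("censored concentration values must be positive")
  }
  tibble::tibble(value = as.numeric(value), status = status)
}

censor_statuses <- c("point", "greater_than", "less_than")

check_status <- function(status) {
  bad <- !is.na(status) & !status %in% censor_statuses
  if (any(bad)) {
    abort(paste0(
      "unknown censor status: ",
      paste(unique(status[bad]), collapse = ", "),
      " (expected point, greater_than or less_than)"
    ))
  }
  invisible(status)
}

vctrs_recycle <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) == 1) return(rep(x, n))
  abort("length mismatch while recycling")
}

#' @rdname censored
#' @export
parse_censored <- function(x) {
  x <- trimws(as.character(x))
  status <- dplyr::case_when(
    is.na(x) | x == "" | x == "-" ~ NA_character_,
    startsWith(x, ">") ~ "greater_than",
    startsWith(x, "<") ~ "less_than",
    TRUE ~ "point"
  )
  num <- suppressWarnings(as.numeric(sub("^[<>]\\s*", "", x)))
  bad <- !is.na(status) & is.na(num)
  if (any(bad)) {
    abort(paste0("cannot parse censored value(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  tibble::tibble(value = num, status = status)
}

#' @rdname censored
#' @export
format_censored <- function(value, status) {
  check_status(status)
  prefix <- dplyr::case_when(
    status == "greater_than" ~ "> ",
    status == "less_than" ~ "< ",
    TRUE ~ ""
  )
  out <- paste0(prefix, format(round(value, 2), trim = TRUE, nsmall = 2))
  out[is.na(value) | is.na(status)] <- NA_character_
  out
}
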