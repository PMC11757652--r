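#' Rank censored results for a normal quantile-quantile plot
#'
#' Orders a set of censored concentration results and assigns each a rank,
#' a plotting position and the corresponding standard-normal quantile, the
#' scaffolding for regression on order statistics. Results not censored
#' from above — point values, and less-than values entered at their bound —
#' are sorted ascending and occupy the lowest ranks; greater-than values
#' occupy the highest ranks, ordered by their bounds (ties keep input
#' order). The premise is that the range-censored results are the largest
#' of the sample, which holds when every bound exceeds every real value.
#'
#' Plotting-position conventions for rank \eqn{i} of \eqn{n}:
#' `"hazen"` \eqn{(i - 0.5)/n} (default), `"weibull"` \eqn{i/(n+1)},
#' `"blom"` \eqn{(i - 0.375)/(n + 0.25)}.
#'
#' @param data a tibble with value and status columns.
#' @param value,status column names (strings) holding the concentration
#'   and its censor status; default `"final_value"`/`"final_status"`.
#' @param convention plotting-position rule.
#' @return the rows of `data` reordered by rank, with columns `rank`,
#'   `plotting_position`, `normal_quantile`, `log_value` and `in_fit`
#'   (`TRUE` for entries that enter the q-q regression).
#' @examples
#' d <- censored(c(2.0, 3.1, 4.4, 5.7), c("point", "point", "point",
#'                                        "greater_than"))
#' rank_dataset(d, value = "value", status = "status")
#' @export
rank_dataset <- function(data,
                         value = "final_value",
                         status = "final_status",
                         convention = c("hazen", "weibull", "blom")) {
  convention <- match.arg(convention)
  if (!all(c(value, status) %in% names(data))) {
    abort(paste0("columns not found: ", value, ", ", status))
  }
  vals <- data[[value]]
  stat <- data[[status]]
  check_status(stat)
  keep <- !is.na(stat)
  d <- data[keep, , drop = FALSE]
  vals <- vals[keep]
  stat <- stat[keep]
  n <- nrow(d)
  if (n < 3) abort("ranking needs at least 3 results")
  is_gt <- stat == "greater_than"
  # stable sorts: ties keep input order
  ord <- c(which(!is_gt)[order(vals[!is_gt])],
           which(is_gt)[order(vals[is_gt])])
  d <- d[ord, , drop = FALSE]
  d$rank <- seq_len(n)
  d$plotting_position <- plotting_position(d$rank, n, convention)
  d$normal_quantile <- qnorm(d$plotting_position)
  d$log_value <- log(d[[value]])
  d$in_fit <- d[[status]] != "greater_than"
  attr(d, "convention") <- convention
  attr(d, "value_col") <- value
  attr(d, "status_col") <- status
  d
}

plotting_position <- function(i, n, convention) {
  switch(convention,
         hazen = (i - 0.5) / n,
         weibull = i / (n + 1),
         blom = (i - 0.375) / (n + 0.25))
}

#' Fit the q-q regression of log concentration on normal quantiles
#'
#' Ordinary least squares of \eqn{\ln(\text{value})} on the standard-normal
#' quantile over the entries not censored from above (range-censored
#' results are excluded from the fit; less-than values enter at their
#' bound). Under a lognormal population the points fall on a line whose
#' intercept is the log geometric mean and whose slope is the log
#' geometric standard deviation.
#'
#' @param ranked output of [rank_dataset()].
#' @param include_less_than logical; keep less-than entries in the fit
#'   (the default) or restrict to point values.
#' @return an object of class `"qq_fit"` with elements `intercept`,
#'   `slope`, `r_squared`, `n_fit`, `n_total`, `convention` and the
#'   underlying `lm` model. Supports [tidy()], [glance()], `print()` and
#'   [autoplot()].
#' @export
qq_fit <- function(ranked, include_less_than = TRUE) {
  stopifnot(all(c("log_value", "normal_quantile", "in_fit") %in% names(ranked)))
  status <- ranked[[attr(ranked, "status_col") %||% "final_status"]]
  use <- ranked$in_fit
  if (!include_less_than) use <- use & status != "less_than"
  fit_data <- ranked[use, , drop = FALSE]
  if (nrow(fit_data) < 3) {
    abort("q-q regression needs at least 3 uncensored entries")
  }
  if (sd(fit_data$normal_quantile) == 0) {
    abort("degenerate fit: no variance in normal quantiles")
  }
  model <- lm(log_value ~ normal_quantile, data = fit_data)
  slope <- unname(coef(model)[2])
  if (!is.na(slope) && slope < 0) {
    warn("fitted q-q slope is negative; data are not consistent with increasing order statistics")
  }
  structure(
    list(
      intercept = unname(coef(model)[1]),
      slope = slope,
      r_squared = summary(model)$r.squared,
      n_fit = nrow(fit_data),
      n_total = nrow(ranked),
      convention = attr(ranked, "convention") %||% "hazen",
      model = model
    ),
    class = "qq_fit"
  )
}

#' @export
print.qq_fit <- function(x, ...) {
  cat("q-q regression of log concentration on normal quantiles\n")
  cat(sprintf("  n = %d of %d entries in fit (convention: %s)\n",
              x$n_fit, x$n_total, x$convention))
  cat(sprintf("  intercept %.4f  slope %.4f  R^2 %.3f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  implied GM %.3f, GSD %.3f\n",
              exp(x$intercept), exp(x$slope)))
  invisible(x)
}

#' @rdname qq_fit
#' @param x a `qq_fit` object.
#' @param ... unused.
#' @method tidy qq_fit
#' @export
tidy.qq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = summary(x$model)$coefficients[, "Std. Error"]
  )
}

#' @rdname qq_fit
#' @method glance qq_fit
#' @export
glance.qq_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    intercept = x$intercept,
    slope = x$slope,
    geometric_mean = exp(x$intercept),
    geometric_sd = exp(x$slope),
    n_fit = x$n_fit,
    n_total = x$n_total,
    convention = x$convention
  )
}

#' Impute range-censored entries from the fitted q-q line
#'
#' Evaluates the fitted line at the normal quantile of each greater-than
#' entry's rank: imputed \eqn{\ln(\text{value}) = a + b\,q_i}. An imputed
#' value below its censoring bound contradicts the bound and triggers a
#' warning (the imputation is kept, so the contradiction stays visible).
#'
#' @param ranked output of [rank_dataset()].
#' @param fit a [qq_fit()] object.
#' @return a tibble with one row per greater-than entry: `rank`,
#'   `normal_quantile`, `bound`, `imputed`.
#' @export
impute_censored <- function(ranked, fit) {
  stopifnot(inherits(fit, "qq_fit"))
  value_col <- attr(ranked, "value_col") %||% "final_value"
  gt <- ranked[!ranked$in_fit, , drop = FALSE]
  imputed <- exp(fit$intercept + fit$slope * gt$normal_quantile)
  below <- imputed < gt[[value_col]]
  if (any(below)) {
    warn(sprintf(
      "%d imputation(s) fall below their censoring bound (ranks %s)",
      sum(below), paste(gt$rank[below], collapse = ", ")))
  }
  tibble::tibble(
    rank = gt$rank,
    normal_quantile = gt$normal_quantile,
    bound = gt[[value_col]],
    imputed = imputed
  )
}

#' Lognormal summary statistics from a censored q-q fit
#'
#' Combines the real (non-range-censored) values with the imputations for
#' the range-censored entries and reports lognormal population statistics:
#' \itemize{
#'   \item geometric mean: \eqn{\exp} of the mean of the combined log
#'     values (both methods);
#'   \item geometric standard deviation: `"distributional"` takes
#'     \eqn{\exp(\text{slope})} of the q-q regression, `"empirical"` the
#'     \eqn{\exp} of the sample SD of the combined log values;
#'   \item 95th percentile: `"distributional"`
#'     \eqn{\exp(a + 1.645\,b)}, `"empirical"` the 95th sample percentile
#'     of the combined values.
#' }
#'
#' @param ranked output of [rank_dataset()].
#' @param fit a [qq_fit()] object.
#' @param method `"distributional"` (default) or `"empirical"`.
#' @return a one-row tibble: `n_total`, `n_real`, `n_censored`,
#'   `geometric_mean`, `geometric_sd`, `percentile_95`, `method`.
#' @export
summarize_lognormal <- function(ranked, fit,
                                method = c("distributional", "empirical")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "qq_fit"))
  imput <- suppressWarnings(impute_censored(ranked, fit))
  log_real <- ranked$log_value[ranked$in_fit]
  log_all <- c(log_real, log(imput$imputed))
  gm <- exp(mean(log_all))
  if (method == "distributional") {
    gsd <- exp(fit$slope)
    p95 <- exp(fit$intercept + qnorm(0.95) * fit$slope)
  } else {
    gsd <- exp(sd(log_all))
    p95 <- unname(quantile(exp(log_all), 0.95, type = 7))
  }
  tibble::tibble(
    n_total = nrow(ranked),
    n_real = sum(ranked$in_fit),
    n_censored = sum(!ranked$in_fit),
    geometric_mean = gm,
    geometric_sd = gsd,
    percentile_95 = p95,
    method = method
  )
}

#' Plain statistics of the uncensored subset
#'
#' Median, minimum and maximum of the point values alone, ignoring all
#' censored entries — the naive summary one would report without any
#' distributional assumption. With heavy right censoring these understate
#' the population statistics; they serve as a floor for comparison.
#'
#' @param data a tibble with value and status columns.
#' @param value,status column names, as in [rank_dataset()].
#' @return a one-row tibble: `n`, `median`, `min`, `max`.
#' @export
naive_stats <- function(data, value = "final_value",
                        status = "final_status") {
  vals <- data[[value]][!is.na(data[[status]]) & data[[status]] == "point"]
  if (length(vals) == 0) abort("no uncensored point values")
  tibble::tibble(
    n = length(vals),
    median = median(vals),
    min = min(vals),
    max = max(vals)
  )
}

#' Export a q-q table for external plotting
#'
#' Writes rank, plotting position, normal quantile, log value, censor
#' status, fitted line value and (for range-censored entries) the imputed
#' value as tab-separated text.
#'
#' @param ranked output of [rank_dataset()].
#' @param fit a [qq_fit()] object.
#' @param path output file path.
#' @return the exported tibble, invisibly.
#' @export
write_qq_table <- function(ranked, fit, path) {
  value_col <- attr(ranked, "value_col") %||% "final_value"
  status_col <- attr(ranked, "status_col") %||% "final_status"
  imput <- suppressWarnings(impute_censored(ranked, fit))
  tab <- tibble::tibble(
    rank = ranked$rank,
    plotting_position = ranked$plotting_position,
    normal_quantile = ranked$normal_quantile,
    value = ranked[[value_col]],
    log_value = ranked$log_value,
    status = ranked[[status_col]],
    fitted = fit$intercept + fit$slope * ranked$normal_quantile
  )
  tab <- dplyr::left_join(tab, imput[, c("rank", "imputed")], by = "rank")
  readr::write_tsv(tab, path)
  invisible(tab)
}

#' q-q plot of a censored-lognormal fit
#'
#' Plots log concentration against standard-normal quantiles: real values
#' as filled points, range-censored bounds as open triangles, their
#' imputations as crosses, and the fitted regression line.
#'
#' @param object a [qq_fit()] object.
#' @param ranked the [rank_dataset()] tibble the fit was computed from.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qq_fit
#' @export
autoplot.qq_fit <- function(object, ranked, ...) {
  value_col <- attr(ranked, "value_col") %||% "final_value"
  imput <- suppressWarnings(impute_censored(ranked, object))
  d <- tibble::tibble(
    q = ranked$normal_quantile,
    logv = ranked$log_value,
    censored = !ranked$in_fit
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$logv)) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::geom_point(
      data = tibble::tibble(q = imput$normal_quantile,
                            logv = log(imput$imputed)),
      shape = 4, size = 2, inherit.aes = TRUE) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 2),
      labels = c(`FALSE` = "measured", `TRUE` = "range-censored bound"),
      name = NULL) +
    ggplot2::labs(
      x = "standard-normal quantile",
      y = "ln(activity concentration)",
      subtitle = sprintf("GM %.2f, GSD %.2f, R² %.2f",
                         exp(object$intercept), exp(object$slope),
                         object$r_squared)) +
    ggplot2::theme_minimal()
}
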