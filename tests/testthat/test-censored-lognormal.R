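# published late-timepoint final results of the packaged campaign
late_fixture <- function() {
  combined <- combine_recordings(filter_campaign(campaign_fixture()))
  combined[combined$timepoint == "late", ]
}

test_that("ranking places range-censored entries at the top ranks", {
  ranked <- rank_dataset(late_fixture())
  expect_equal(ranked$rank, 1:17)
  expect_true(all(ranked$final_status[1:11] %in% c("point", "less_than")))
  expect_true(all(ranked$final_status[12:17] == "greater_than"))
  # default convention: median rank of n = 17 sits at probability 0.5
  expect_equal(ranked$plotting_position[9], 0.5)
  expect_equal(ranked$normal_quantile[9], 0)
  # three points, no censoring
  d <- censored(c(3, 1, 2))
  r3 <- rank_dataset(d, value = "value", status = "status")
  expect_equal(r3$value, c(1, 2, 3))
  expect_equal(r3$plotting_position, c(1, 3, 5) / 6)
  expect_error(rank_dataset(d[1:2, ], value = "value", status = "status"),
               "at least 3")
})

test_that("plotting-position conventions differ as documented", {
  d <- censored(c(1, 2, 3, 4))
  r_w <- rank_dataset(d, "value", "status", convention = "weibull")
  expect_equal(r_w$plotting_position, (1:4) / 5)
  r_b <- rank_dataset(d, "value", "status", convention = "blom")
  expect_equal(r_b$plotting_position, ((1:4) - 0.375) / 4.25)
})

test_that("q-q regression on the late fixture matches hand arithmetic", {
  ranked <- rank_dataset(late_fixture())
  fit <- qq_fit(ranked)
  # closed-form OLS over the 11 non-range-censored entries, no lm()
  hand <- ols_by_hand(ranked$normal_quantile[1:11], ranked$log_value[1:11])
  expect_equal(fit$intercept, hand$intercept)
  expect_equal(fit$slope, hand$slope)
  expect_equal(fit$r_squared, hand$r_squared)
  # frozen values from an independent pre-computed regression
  expect_equal(fit$intercept, 1.47547068588, tolerance = 1e-9)
  expect_equal(fit$slope, 0.513186590953, tolerance = 1e-9)
  expect_equal(fit$r_squared, 0.981073321238, tolerance = 1e-9)
  expect_equal(fit$n_fit, 11)
  g <- glance(fit)
  expect_equal(g$geometric_sd, exp(fit$slope))
  expect_equal(tidy(fit)$estimate, c(fit$intercept, fit$slope))
})

test_that("q-q regression handles degenerate and adversarial inputs", {
  # three collinear log-points fit perfectly
  d <- censored(exp(c(0, 0.5, 1)))
  r <- rank_dataset(d, "value", "status")
  r$log_value <- r$normal_quantile  # force exact collinearity
  expect_equal(suppressWarnings(qq_fit(r))$r_squared, 1)
  # decreasing values against increasing quantiles: negative slope warns
  r2 <- rank_dataset(censored(c(1, 2, 3, 4)), "value", "status")
  r2$log_value <- rev(r2$log_value)
  expect_warning(qq_fit(r2), "negative")
  expect_error(qq_fit(rank_dataset(
    censored(c(1, 2, 5, 6), c("point", "point", "greater_than",
                              "greater_than")), "value", "status")),
    "at least 3")
})

test_that("imputations follow the fitted line and increase with rank", {
  ranked <- rank_dataset(late_fixture())
  fit <- qq_fit(ranked)
  imp <- impute_censored(ranked, fit)
  expect_equal(nrow(imp), 6)
  expect_equal(imp$rank, 12:17)
  # top rank evaluated by hand: exp(a + b * qnorm(16.5/17))
  expect_equal(imp$imputed[6],
               exp(fit$intercept + fit$slope * qnorm(16.5 / 17)))
  expect_equal(imp$imputed[6], 11.5321854501, tolerance = 1e-9)
  expect_true(all(diff(imp$imputed) > 0))
  # early time point: 12 imputations at ranks 5..16
  combined <- combine_recordings(filter_campaign(campaign_fixture()))
  ranked_e <- rank_dataset(combined[combined$timepoint == "early" &
                                      !is.na(combined$final_status), ])
  imp_e <- suppressWarnings(impute_censored(ranked_e, qq_fit(ranked_e)))
  expect_equal(imp_e$rank, 5:16)
  # an imputation below its censoring bound is reported, not hidden
  contradictory <- censored(c(1, 2, 3, 100),
                            c("point", "point", "point", "greater_than"))
  rc <- rank_dataset(contradictory, "value", "status")
  expect_warning(impute_censored(rc, qq_fit(rc)), "below")
})

test_that("summary statistics reproduce the published late-timepoint fit", {
  ranked <- rank_dataset(late_fixture())
  fit <- qq_fit(ranked)
  s <- summarize_lognormal(ranked, fit)
  expect_equal(s$n_total, 17)
  expect_equal(s$n_real, 11)
  expect_equal(s$n_censored, 6)
  # frozen from the independent pre-computed regression
  expect_equal(s$geometric_mean, 4.373093642, tolerance = 1e-9)
  expect_equal(s$geometric_sd, 1.67060626077, tolerance = 1e-9)
  expect_equal(s$percentile_95, exp(fit$intercept + qnorm(0.95) * fit$slope))
  se <- summarize_lognormal(ranked, fit, method = "empirical")
  expect_equal(se$geometric_mean, s$geometric_mean)
  expect_true(se$geometric_sd >= 1)
  # both percentile modes exceed the geometric mean under spread > 1
  expect_true(s$percentile_95 > s$geometric_mean)
  expect_true(se$percentile_95 > se$geometric_mean)
})

test_that("with no censoring the summary equals the plain geometric mean", {
  set.seed(11)
  x <- rlnorm(40, log(3), log(1.5))
  d <- censored(x)
  ranked <- rank_dataset(d, "value", "status")
  fit <- qq_fit(ranked)
  s <- summarize_lognormal(ranked, fit)
  expect_equal(s$geometric_mean, exp(mean(log(x))))
  expect_equal(s$n_censored, 0)
  # distributional GSD agrees with the sample geometric SD within the
  # plotting-position bias
  expect_equal(s$geometric_sd, exp(sd(log(x))), tolerance = 0.05)
})

test_that("all statistics are scale equivariant", {
  base <- late_fixture()
  k <- 3.7
  scaled <- dplyr::mutate(base, final_value = k * final_value)
  r1 <- rank_dataset(base)
  r2 <- rank_dataset(scaled)
  f1 <- qq_fit(r1)
  f2 <- qq_fit(r2)
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$intercept, f1$intercept + log(k))
  s1 <- summarize_lognormal(r1, f1)
  s2 <- summarize_lognormal(r2, f2)
  expect_equal(s2$geometric_mean, k * s1$geometric_mean)
  expect_equal(s2$geometric_sd, s1$geometric_sd)
  expect_equal(s2$percentile_95, k * s1$percentile_95)
  expect_equal(impute_censored(r2, f2)$imputed,
               k * impute_censored(r1, f1)$imputed)
})

test_that("appending a greater-than entry only shifts the real-entry quantiles", {
  base <- late_fixture()
  extra <- base[1, ]
  extra$final_value <- 99
  extra$final_status <- "greater_than"
  extra$admin_id <- "EXTRA"
  r1 <- rank_dataset(base)
  r2 <- rank_dataset(dplyr::bind_rows(base, extra))
  real1 <- r1[r1$in_fit, ]
  real2 <- r2[r2$in_fit, ]
  # same real values in the same order, same ranks, quantiles shifted by n
  expect_equal(real2$final_value, real1$final_value)
  expect_equal(real2$rank, real1$rank)
  expect_equal(real2$plotting_position, (real1$rank - 0.5) / 18)
})

test_that("q-q estimates agree with a censored maximum-likelihood oracle", {
  set.seed(202)
  x <- rlnorm(200, log(4.4), log(1.67))
  bound <- quantile(x, 0.62)  # ~38% right censoring
  status <- ifelse(x > bound, "greater_than", "point")
  value <- ifelse(x > bound, bound, x)
  d <- tibble::tibble(value = value, status = status)
  ranked <- rank_dataset(d, "value", "status")
  fit <- qq_fit(ranked)
  s <- summarize_lognormal(ranked, fit)
  mle <- censored_lnorm_mle(d$value, d$status)
  expect_equal(mle$convergence, 0)
  expect_equal(s$geometric_mean, mle$gm, tolerance = 0.1)
  expect_equal(s$geometric_sd, mle$gsd, tolerance = 0.1)
  # the oracle itself cross-checked against survreg on the same data
  sv <- survival::survreg(
    survival::Surv(value, status == "point") ~ 1,
    dist = "lognormal", data = d)
  expect_equal(mle$gm, exp(unname(coef(sv))), tolerance = 0.01)
  expect_equal(log(mle$gsd), sv$scale, tolerance = 0.02)
})

test_that("naive statistics of the uncensored subset match the published ranges", {
  combined <- combine_recordings(filter_campaign(campaign_fixture()))
  early <- combined[combined$timepoint == "early" &
                      !is.na(combined$final_status), ]
  ne <- naive_stats(early)
  expect_equal(ne$n, 4)
  expect_equal(ne$median, 4.715)
  expect_equal(ne$min, 4.51)
  expect_equal(ne$max, 5.37)
  nl <- naive_stats(combined[combined$timepoint == "late", ])
  expect_equal(nl$n, 10)
  expect_equal(nl$median, 3.585)
  expect_equal(nl$min, 2.04)
  expect_equal(nl$max, 4.82)
  expect_equal(naive_stats(censored(7), value = "value", status = "status"),
               tibble::tibble(n = 1L, median = 7, min = 7, max = 7))
  expect_error(naive_stats(censored(7, "greater_than"),
                           value = "value", status = "status"),
               "no uncensored")
})

test_that("the q-q table export carries ranks, fits and imputations", {
  ranked <- rank_dataset(late_fixture())
  fit <- qq_fit(ranked)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  tab <- write_qq_table(ranked, fit, path)
  expect_true(file.exists(path))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 17)
  expect_equal(sum(!is.na(back$imputed)), 6)
  expect_equal(back$fitted,
               fit$intercept + fit$slope * back$normal_quantile)
})

test_that("autoplot builds a q-q plot without error", {
  ranked <- rank_dataset(late_fixture())
  fit <- qq_fit(ranked)
  p <- autoplot(fit, ranked)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
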