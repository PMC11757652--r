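# Independent oracles used to cross-check the implementation.

# Censored-lognormal maximum likelihood: direct numerical optimisation of
# the likelihood with point, right-censored (greater-than) and
# left-censored (less-than) contributions. Deliberately independent of the
# q-q regression path it is used to check.
censored_lnorm_mle <- function(value, status) {
  nll <- function(par) {
    mu <- par[1]
    sig <- exp(par[2])
    ll <- sum(dlnorm(value[status == "point"], mu, sig, log = TRUE)) +
      sum(plnorm(value[status == "greater_than"], mu, sig,
                 lower.tail = FALSE, log.p = TRUE)) +
      sum(plnorm(value[status == "less_than"], mu, sig, log.p = TRUE))
    -ll
  }
  start <- c(mean(log(value)), log(max(sd(log(value)), 0.1)))
  fit <- optim(start, nll, method = "Nelder-Mead")
  list(gm = exp(fit$par[1]), gsd = exp(exp(fit$par[2])),
       convergence = fit$convergence)
}

# Closed-form OLS of y on x (no lm()), for checking the q-q regression.
ols_by_hand <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- sum((x - mean(x)) * (y - mean(y)))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(intercept = a, slope = b, r_squared = r2)
}

# A tiny three-session campaign in the parsed table format.
toy_campaign <- function() {
  tibble::tibble(
    admin_id = c("X1", "X2", "X3"),
    patient_id = NA_character_,
    activity_MBq = c(4, 4, 4),
    flow_l_min = c(4, 4, 1),
    instrument = "PQ2000",
    timepoint = "late",
    r1_value = c(2.0, 3.0, 5.68),
    r1_status = c("point", "point", "greater_than"),
    r2_value = c(2.2, 3.0, 5.68),
    r2_status = c("point", "point", "greater_than"),
    outlier_2 = FALSE
  )
}
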