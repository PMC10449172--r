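# Parametric survival families: evaluation, closed forms, sampling, censored
# MLE, and information-criterion ranking.

test_that("survival curves start at 1, hit their closed-form medians, and validate inputs", {
  ll <- ll_model(1.6742, 0.0095)
  expect_equal(survival_at(ll, 0), 1)
  # log-logistic median is 1/lambda (where (lambda t)^gamma = 1)
  expect_equal(survival_at(ll, 1 / 0.0095), 0.5, tolerance = 1e-12)
  # lognormal median is exp(mu)
  ln <- ln_model(3.0558, 1.0395)
  expect_equal(survival_at(ln, exp(3.0558)), 0.5, tolerance = 1e-12)

  expect_error(survival_at(ll, -1), "times")
  expect_error(surv_model("loglogistic", c(shape = -1, rate = 0.01)), "> 0")
  expect_error(surv_model("lognormal", c(meanlog = 1, sdlog = 0)), "> 0")
  expect_error(surv_model("weibull", c(shape = 1)), "2 parameters")
})

test_that("generalized gamma reduces to Weibull at Q = 1 and lognormal at Q = 0", {
  t <- c(0.5, 5, 20, 80, 250)
  wb <- surv_model("weibull", c(shape = 1.4, scale = 70))
  gg_w <- surv_model("gengamma", c(mu = log(70), sigma = 1 / 1.4, Q = 1))
  expect_equal(survival_at(gg_w, t), survival_at(wb, t), tolerance = 1e-8)

  ln <- ln_model(3.5, 0.9)
  gg_l <- surv_model("gengamma", c(mu = 3.5, sigma = 0.9, Q = 1e-9))
  expect_equal(survival_at(gg_l, t), survival_at(ln, t), tolerance = 1e-6)
})

test_that("every family is a valid survival function on a fine grid", {
  grid <- seq(0, 2000, length.out = 10000)
  for (m in family_examples()) {
    s <- survival_at(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
    tail_tol <- if (m$family == "loglogistic") 1e-2 else 1e-3
    expect_lt(survival_at(m, 1e6), tail_tol)
  }
})

test_that("rmst matches closed-form means at r = 0 and infinite horizon", {
  # exponential: mean 1/rate
  expect_equal(rmst(surv_model("exponential", c(rate = 0.02)), Inf, 0),
               1 / 0.02 / 52, tolerance = 1e-4)
  # weibull: scale * gamma(1 + 1/shape)
  expect_equal(rmst(surv_model("weibull", c(shape = 1.3, scale = 60)), Inf, 0),
               60 * gamma(1 + 1 / 1.3) / 52, tolerance = 1e-4)
  # gamma: shape / rate
  expect_equal(rmst(surv_model("gamma", c(shape = 2, rate = 0.03)), Inf, 0),
               2 / 0.03 / 52, tolerance = 1e-4)
  # lognormal: exp(mu + sigma^2/2)
  expect_equal(rmst(ln_model(3.5, 1.0), Inf, 0),
               exp(3.5 + 0.5) / 52, tolerance = 1e-4)
  # log-logistic (gamma > 1): pi / (gamma * lambda * sin(pi/gamma))
  g <- 1.6742; l <- 0.0095
  expect_equal(rmst(ll_model(g, l), Inf, 0),
               pi / (g * l * sin(pi / g)) / 52, tolerance = 1e-4)
})

test_that("quadrature rmst agrees with a fine-grid trapezoid and discounts correctly", {
  m <- ll_model(1.7826, 0.0136)
  tgrid <- seq(0, 520, by = 0.1)
  trap <- sum(diff(tgrid) * (survival_at(m, tgrid[-1]) +
                               survival_at(m, tgrid[-length(tgrid)])) / 2) / 52
  expect_equal(rmst(m, 520, 0), trap, tolerance = 1e-4)
  expect_lt(rmst(m, 520, 0.03), rmst(m, 520, 0))
  expect_error(rmst(m, -5), "horizon")
})

test_that("sample_times is reproducible and matches distribution summaries", {
  m <- ll_model(1.7, 0.01)
  x1 <- sample_times(m, 1e5, seed = 7)
  x2 <- sample_times(m, 1e5, seed = 7)
  expect_identical(x1, x2)
  expect_lt(abs(median(x1) - 1 / 0.01) / (1 / 0.01), 0.02)

  ex <- surv_model("exponential", c(rate = 0.02))
  y <- sample_times(ex, 1e5, seed = 8)
  se <- (1 / 0.02) / sqrt(1e5)
  expect_lt(abs(mean(y) - 1 / 0.02), 3 * se)
})

test_that("exponential censored MLE equals its closed form", {
  ipd <- censored_sample(surv_model("exponential", c(rate = 0.015)), 400,
                         cens_q = 0.7, seed = 11)
  fit <- fit_censored_mle(ipd, "exponential")
  expect_true(fit$converged)
  expect_equal(unname(fit$model$params["rate"]),
               sum(ipd$event) / sum(ipd$time_weeks), tolerance = 1e-5)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$bic, log(nrow(ipd)) - 2 * fit$loglik)
})

test_that("censored MLE recovers log-logistic parameters within 5% at n = 2000", {
  truth <- ll_model(1.7, 0.01)
  ipd <- censored_sample(truth, 2000, cens_q = 0.8, seed = 13)
  fit <- fit_censored_mle(ipd, "loglogistic")
  expect_true(fit$converged)
  expect_lt(abs(fit$model$params["shape"] - 1.7) / 1.7, 0.05)
  expect_lt(abs(fit$model$params["rate"] - 0.01) / 0.01, 0.05)
  # covariance is symmetric PSD with positive variances
  V <- fit$param_covariance
  expect_true(isSymmetric(V, tol = 1e-8))
  expect_true(all(diag(V) > 0))
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # fitted RMST tracks truth RMST within 3%
  expect_lt(abs(rmst(fit$model, 520, 0) - rmst(truth, 520, 0)) /
              rmst(truth, 520, 0), 0.03)
})

test_that("cross-check: in-package MLE matches flexsurvreg loglik on the same data", {
  ipd <- censored_sample(ln_model(3.2, 0.9), 500, cens_q = 0.75, seed = 17)
  fit <- fit_censored_mle(ipd, "lognormal")
  ref <- flexsurv::flexsurvreg(survival::Surv(time_weeks, event) ~ 1,
                               data = ipd, dist = "lnorm")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$model$params),
               unname(ref$res[, "est"]), tolerance = 1e-4)
})

test_that("AIC model selection identifies the generating family", {
  truth <- ln_model(3.0, 1.0)
  wins <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    ipd <- censored_sample(truth, 600, cens_q = 0.8, seed = 100 + r)
    ranked <- fit_all_families(ipd, n_starts = 2L)
    if (attr(ranked, "ranking")$family[1] == "lognormal") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("rank_fits orders by AIC with BIC, parameter-count and family tie-breaks", {
  ipd <- censored_sample(ln_model(3.0, 1.0), 200, seed = 19)
  f1 <- fit_censored_mle(ipd, "lognormal")
  expect_identical(rank_fits(list(f1))[[1]], f1)

  fake <- function(family, aic, bic, npar) {
    structure(list(model = NULL, family = family, loglik = 0, aic = aic,
                   bic = bic, n_obs = 10, n_params = npar,
                   param_covariance = NULL, converged = TRUE,
                   diagnostics = "ok"), class = "fit_result")
  }
  r <- rank_fits(list(fake("weibull", 101, 90, 2), fake("gamma", 100, 95, 2)))
  expect_equal(attr(r, "ranking")$family, c("gamma", "weibull"))
  # AIC tie -> lower BIC first
  r <- rank_fits(list(fake("weibull", 100, 96, 2), fake("gamma", 100, 95, 2)))
  expect_equal(attr(r, "ranking")$family, c("gamma", "weibull"))
  # AIC+BIC tie -> fewer parameters first
  r <- rank_fits(list(fake("gengamma", 100, 95, 3), fake("gamma", 100, 95, 2)))
  expect_equal(attr(r, "ranking")$family, c("gamma", "gengamma"))
  # full tie -> canonical family order
  r <- rank_fits(list(fake("lognormal", 100, 95, 2), fake("weibull", 100, 95, 2)))
  expect_equal(attr(r, "ranking")$family, c("weibull", "lognormal"))
  # non-converged fits sort last
  bad <- fake("exponential", 10, 10, 1); bad$converged <- FALSE
  r <- rank_fits(list(bad, fake("gamma", 100, 95, 2)))
  expect_equal(attr(r, "ranking")$family, c("gamma", "exponential"))
  expect_error(rank_fits(list(bad)), "no converged fit")
})

test_that("too few events is rejected up front", {
  ipd <- pseudo_ipd(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0))
  expect_error(fit_censored_mle(ipd, "gengamma"), "at least")
})
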