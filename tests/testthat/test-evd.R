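test_that("uncensored and censored fits recover known Gumbel parameters", {
  set.seed(7)
  x <- rgumbel(1e4, mu = 100, lambda = 0.3)
  fit <- fit_censored_evd(x, censor_value = "none", m = 200, n = 200)
  expect_true(fit$converged)
  expect_equal(fit$n_censored, 0L)
  expect_lt(abs(fit$lambda - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$mu - 100), 1)

  # censoring at the 30th percentile moves the estimates only within the
  # same bands
  c30 <- as.numeric(quantile(x, 0.30))
  fitc <- fit_censored_evd(x, censor_value = c30, m = 200, n = 200)
  expect_true(fitc$converged)
  expect_equal(fitc$n_observed + fitc$n_censored, length(x))
  expect_gt(fitc$n_censored, 0L)
  expect_lt(abs(fitc$lambda - 0.3) / 0.3, 0.05)
  expect_lt(abs(fitc$mu - 100), 1)
})

test_that("uncensored fit agrees with an independent ML fitter", {
  suppressMessages(library(fitdistrplus))
  # fitdist resolves d<name>/p<name> by name from the global environment
  assign("dgumbel2", function(x, loc, rate) {
    rate * exp(-rate * (x - loc) - exp(-rate * (x - loc)))
  }, envir = globalenv())
  assign("pgumbel2", function(q, loc, rate) exp(-exp(-rate * (q - loc))),
         envir = globalenv())
  on.exit(rm("dgumbel2", "pgumbel2", envir = globalenv()))
  set.seed(11)
  x <- rgumbel(4000, mu = 40, lambda = 0.45)
  ref <- fitdistrplus::fitdist(
    x, "gumbel2", start = list(loc = median(x), rate = 1 / sd(x))
  )
  fit <- fit_censored_evd(x, censor_value = "none", m = 100, n = 100)
  expect_lt(abs(fit$lambda - ref$estimate[["rate"]]) / ref$estimate[["rate"]], 1e-3)
  expect_lt(abs(fit$mu - ref$estimate[["loc"]]), 0.01)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_censored_evd(rep(42, 200), censor_value = "none", m = 10, n = 10),
               "zero variance")
  expect_error(fit_censored_evd(c(1, 2, 3), censor_value = "none", m = 10, n = 10),
               ">= 50 required")
  set.seed(3)
  x <- rgumbel(200, 50, 0.4)
  # censoring everything but a handful violates the fit precondition
  expect_error(fit_censored_evd(x, censor_value = as.numeric(quantile(x, 0.9)),
                                m = 10, n = 10), ">= 50")
})

test_that("the two P-value parameterisations are identical", {
  set.seed(19)
  x <- round(rgumbel(1000, 60, 0.25))
  fit <- fit_censored_evd(x, censor_value = "auto", m = 150, n = 250)
  for (s in c(40, 60, 80, 120)) {
    e_from_k <- fit$K * 150 * 250 * exp(-fit$lambda * s)
    e_from_mu <- exp(-fit$lambda * (s - fit$mu))
    expect_lt(abs(e_from_k - e_from_mu) / e_from_mu, 1e-12)
    expect_equal(pvalue(s, fit)$e_value, e_from_k)
  }
})

test_that("censored values contribute only their count", {
  set.seed(23)
  x <- round(rgumbel(1000, 30, 0.35))
  cfix <- as.numeric(quantile(x, 0.25))
  fit1 <- fit_censored_evd(x, censor_value = cfix, m = 90, n = 90)
  # shuffle the values below the censor point arbitrarily (keep them <= c)
  y <- x
  low <- y <= cfix
  y[low] <- floor(cfix) - sample.int(20, sum(low), replace = TRUE)
  fit2 <- fit_censored_evd(y, censor_value = cfix, m = 90, n = 90)
  expect_identical(fit1$lambda, fit2$lambda)
  expect_identical(fit1$mu, fit2$mu)
  expect_identical(fit1$K, fit2$K)
})

test_that("P-values follow the closed forms and are monotone in the score", {
  fit <- structure(list(lambda = 1, mu = 0, K = 1, converged = TRUE,
                        m = 1L, n = 1L), class = "gumbel_fit")
  expect_equal(pvalue(0, fit)$p_value, 1 - exp(-1))
  # E = ln 2 at x = -log(log(2)) gives P = 0.5
  expect_equal(pvalue(-log(log(2)), fit)$p_value, 0.5)
  # x -> infinity: E -> 0, P -> 0
  expect_equal(pvalue(1e6, fit)$p_value, 0)
  # monotone decreasing in x (away from the floating-point saturation at 1)
  xs <- seq(0, 10, by = 0.25)
  ps <- pvalue(xs, fit)$p_value
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("broom-style accessors expose the fitted parameters", {
  set.seed(31)
  x <- round(rgumbel(1000, 45, 0.3))
  fit <- fit_censored_evd(x, m = 120, n = 120)
  td <- tidy(fit)
  expect_equal(td$term, c("lambda", "mu", "K"))
  expect_equal(td$estimate[1], fit$lambda)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_observed + gl$n_censored, 1000L)
  expect_s3_class(autoplot(fit), "ggplot")
})
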