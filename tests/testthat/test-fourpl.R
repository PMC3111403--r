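test_that("noiseless 4PL data are refit to the generating parameters", {
  truth <- fourpl_params(0, 100, 63.8, -2)
  d <- simulate_monotherapy(63.8, -2, noise_sd = 0, seed = 1)
  fit <- fit_4pl(d)
  expect_equal(fit$ed50, 63.8, tolerance = 1e-6)
  expect_equal(coef(fit)[["hillslope"]], -2, tolerance = 1e-6)
  expect_equal(coef(fit)[["top"]], 100, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # invariants of the fit object
  expect_gt(coef(fit)[["top"]], coef(fit)[["bottom"]])
  expect_true(all(fit$ci$conf.low <= fit$ci$conf.high))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-8))
  expect_equal(fit$residual_df, fit$n_obs - 4L)
})

test_that("degenerate and undersized inputs are rejected with classed errors", {
  flat <- tibble::tibble(dose_um = c(1, 3, 10, 30, 100), response_pct = rep(50, 5))
  expect_error(fit_4pl(flat), class = "drcombo_fit_error")
  small <- tibble::tibble(dose_um = c(1, 3, 10, 30), response_pct = c(90, 70, 40, 20))
  expect_error(fit_4pl(small), class = "drcombo_input_error")
  few_doses <- tibble::tibble(dose_um = c(1, 1, 3, 3, 10, 10),
                              response_pct = c(95, 94, 60, 62, 20, 18))
  expect_error(fit_4pl(few_doses), class = "drcombo_input_error")
})

test_that("predict_effect obeys the midpoint, zero-dose and closed-form identities", {
  p <- fourpl_params(0, 100, 10, -1)
  expect_equal(predict_effect(p, 10), 50)
  expect_equal(predict_effect(p, 0), 100)  # top asymptote for a decreasing curve
  # hand evaluation at dose 100: 100 - 100 / (1 + 10^-1)
  expect_equal(predict_effect(p, 100), 100 - 100 / (1 + 10^-1))
  expect_error(predict_effect(p, -1), class = "drcombo_input_error")
})

test_that("inverse_dose is the exact inverse of predict_effect", {
  p <- fourpl_params(5, 95, 22, -1.7)
  expect_equal(inverse_dose(p, 50), 22)
  # round-trip through a specific dose
  eff <- (coef_p <- p$coefficients)[["top"]] - predict_effect(p, 37.2)
  eff <- eff / (coef_p[["top"]] - coef_p[["bottom"]]) * 100
  expect_equal(inverse_dose(p, eff), 37.2, tolerance = 1e-9)
  expect_error(inverse_dose(p, 0), class = "drcombo_domain_error")
  expect_error(inverse_dose(p, 100), class = "drcombo_domain_error")
})

test_that("round-trip identity holds to 1e-9 relative across random curves", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- fourpl_params(stats::runif(1, 0, 20), stats::runif(1, 80, 120),
                         10^stats::runif(1, 0, 2), -stats::runif(1, 0.5, 4))
      eff <- seq(1, 99, by = 1)
      d <- inverse_dose(p, eff)
      top <- p$coefficients[["top"]]
      bot <- p$coefficients[["bottom"]]
      back <- (top - predict_effect(p, d)) / (top - bot) * 100
      expect_equal(back, eff, tolerance = 1e-9)
      # monotonicity: decreasing response in dose, increasing dose in effect
      expect_true(all(diff(predict_effect(p, sort(d))) < 0))
      expect_true(all(diff(d) > 0))
    }
  })
})

test_that("fits are scale-equivariant in dose", {
  d <- simulate_monotherapy(40, -1.5, noise_sd = 3, seed = 7)
  f1 <- fit_4pl(d)
  d2 <- dplyr::mutate(d, dose_um = dose_um * 12.5)
  f2 <- fit_4pl(d2)
  expect_equal(f2$ed50, f1$ed50 * 12.5, tolerance = 1e-5)
  expect_equal(coef(f2)[["hillslope"]], coef(f1)[["hillslope"]], tolerance = 1e-5)
})

test_that("ED50 is recovered across 200 simulated noisy datasets", {
  truth <- 63.8
  res <- vapply(0:199, function(s) {
    fit <- fit_4pl(simulate_monotherapy(truth, -2, noise_sd = 5, seed = s))
    ci <- fit$ci[fit$ci$term == "log10_ed50", ]
    c(fit$ed50, ci$conf.low <= log10(truth) && log10(truth) <= ci$conf.high)
  }, numeric(2))
  expect_gte(mean(res[2, ]), 0.90)                        # CI coverage
  expect_lt(abs(median(res[1, ]) - truth) / truth, 0.05)  # median bias
})

test_that("a noisy SK-BR-3-like dataset covers its generating ED50", {
  truth <- 63.8
  fit <- fit_4pl(simulate_monotherapy(truth, -2, noise_sd = 5, seed = 2024))
  ci <- fit$ci[fit$ci$term == "log10_ed50", ]
  expect_true(ci$conf.low <= log10(truth) && log10(truth) <= ci$conf.high)
  expect_equal(fit$n_obs, 48L)
})

test_that("broom-style accessors return well-formed tibbles", {
  fit <- fit_4pl(simulate_monotherapy(30, -2, noise_sd = 4, seed = 3))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$ed50, fit$ed50)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$response_pct)
  expect_s3_class(autoplot(fit), "ggplot")
})
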