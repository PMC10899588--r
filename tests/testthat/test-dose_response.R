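test_that("effect_at evaluates the sigmoid families correctly", {
  m <- response_model("logistic", theta_max = 1, alpha = -1, beta = 1)
  expect_equal(effect_at(m, 10), 0.5)            # alpha + beta*log10(10) = 0
  expect_equal(effect_at(m, 100), 1 / (1 + exp(-1)))
  expect_equal(effect_at(m, 0), 0)               # explicit lower limit
  w <- response_model("weibull", theta_max = 1, alpha = 0, beta = 1)
  expect_equal(effect_at(w, 1), 1 - exp(-1))
  expect_equal(effect_at(w, 0), 0)
  expect_error(effect_at(m, -1), "finite and >= 0")
})

test_that("ecx inverts both families and round-trips with effect_at", {
  m <- response_model("logistic", theta_max = 1, alpha = -1, beta = 1)
  expect_equal(ecx(m, 0.5), 10)
  w <- response_model("weibull", theta_max = 1, alpha = 0, beta = 1)
  expect_equal(ecx(w, 1 - exp(-1)), 1)
  for (model in list(m, w,
                     response_model("logistic", 0.8, 2, 2.5),
                     response_model("weibull", 0.9, -3, 0.7))) {
    for (conc in c(0.1, 1, 10, 100))
      expect_equal(ecx(model, effect_at(model, conc)), conc,
                   tolerance = 1e-9)
    for (x in c(0.05, 0.10, 0.25, 0.5) * model$theta_max)
      expect_lt(abs(effect_at(model, ecx(model, x)) - x), 1e-9)
  }
  expect_error(ecx(m, 0), "theta_max")
  expect_error(ecx(m, 1), "theta_max")
  expect_error(ecx(response_model("logistic", 0.7, 0, 1), 0.7), "0.7")
})

test_that("fitted curves are monotone over the working concentration range", {
  models <- list(
    response_model("logistic", 1, -1, 1),
    response_model("weibull", 0.85, 1.5, 0.6),
    response_model("logistic", 0.6, 4, 3))
  grid <- 10^seq(-3, 5, length.out = 200)
  for (m in models) {
    e <- effect_at(m, grid)
    expect_true(all(diff(e) >= 0))
    # the asymptote is attainable in floating point (weibull saturates)
    expect_true(all(e >= 0 & e <= m$theta_max))
  }
})

test_that("fit_model recovers generating parameters from noiseless data", {
  truth <- response_model("logistic", 1, -1, 1)
  pl <- plate_from(truth, 10^seq(-1, 3, length.out = 8))
  f <- fit_model(pl, "logistic")
  expect_true(f$converged)
  expect_equal(f$model$alpha, -1, tolerance = 1e-6)
  expect_equal(f$model$beta, 1, tolerance = 1e-6)
  expect_equal(f$model$theta_max, 1, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)

  wt <- response_model("weibull", 0.9, -2, 1.3)
  fw <- fit_model(plate_from(wt, 10^seq(-1, 4, length.out = 10)), "weibull")
  expect_equal(fw$model$alpha, -2, tolerance = 1e-5)
  expect_equal(fw$model$beta, 1.3, tolerance = 1e-5)
  expect_equal(fw$model$theta_max, 0.9, tolerance = 1e-5)
})

test_that("fit_model matches a dense grid-search oracle on small fixtures", {
  fixtures <- list(
    list(m = response_model("logistic", 1, -1, 1), fam = "logistic"),
    list(m = response_model("logistic", 0.8, -2, 2), fam = "logistic"),
    list(m = response_model("weibull", 1, 0, 1), fam = "weibull"),
    list(m = response_model("weibull", 0.9, -1.5, 0.8), fam = "weibull"),
    list(m = response_model("logistic", 0.7, 1, 1.5), fam = "logistic"))
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    pl <- plate_from(fx$m, 10^seq(-1, 3, length.out = 6), reps = 2,
                     noise_sd = 0.03, seed = 100 + i)
    f <- fit_model(pl, fx$fam)
    oracle <- grid_search_rss(pl, fx$fam)
    expect_lte(f$rss, oracle + 1e-10)  # optimiser at least as good as the grid
  }
})

test_that("fit_model rejects bad input and flags degenerate data", {
  truth <- response_model("logistic", 1, -1, 1)
  expect_error(fit_model(plate_from(truth, c(1, 10, 100))), "4 distinct")
  bad <- plate_from(truth, 10^seq(0, 3, length.out = 6))
  bad$response[1] <- 1.5
  expect_error(fit_model(bad), "data errors")
  flat <- data.frame(concentration = 10^seq(0, 3, length.out = 6),
                     response = rep(0.4, 6))
  f <- fit_model(flat, "logistic")
  expect_false(f$converged)
})

test_that("select_best picks the generating family by AIC", {
  lt <- response_model("logistic", 1, -1, 1)
  wt <- response_model("weibull", 1, -2, 1.2)
  conc <- 10^seq(-1, 4, length.out = 10)
  expect_identical(select_best(plate_from(lt, conc))$model$family, "logistic")
  expect_identical(select_best(plate_from(wt, conc))$model$family, "weibull")
  # weibull truth: weibull fit must beat logistic on AIC
  pw <- plate_from(wt, conc)
  expect_lt(fit_model(pw, "weibull")$aic, fit_model(pw, "logistic")$aic)
  # single requested family wins by default
  expect_identical(select_best(plate_from(wt, conc), "logistic")$model$family,
                   "logistic")
})

test_that("noisy EC50 recovery stays within 10% in the median over seeds", {
  truth <- logistic_ec50(100, beta = 1.2)
  errs <- vapply(1:50, function(s) {
    pl <- plate_from(truth, 10^seq(0, 3.5, length.out = 8), reps = 3,
                     noise_sd = 0.02, seed = s)
    f <- select_best(pl)
    abs(ecx(f$model, f$model$theta_max / 2) - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
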