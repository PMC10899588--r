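make_survey <- function(teqs, db) {
  # atrazine-only stations whose TEQ equals the requested values exactly
  n <- length(teqs)
  df <- data.frame(station_id = sprintf("s%02d", seq_len(n)),
                   region = "test", lat = 0, lon = 0, year = 2015,
                   atrazine = teqs)
  for (h in setdiff(names(db$curves), "atrazine")) df[[h]] <- 0
  df
}

test_that("station inhibition maps TEQ through the community curve", {
  db <- default_curve_db()
  cc <- build_community_curve()
  sv <- make_survey(c(11.9, 5.1, 0), db)
  res <- station_inhibition(sv, db, cc)
  expect_equal(res$teq, c(11.9, 5.1, 0), tolerance = 1e-9)
  expect_equal(res$inhibition, c(10, 5, 0), tolerance = 1e-6)
  expect_false(any(res$saturated))
})

test_that("station ranking by TEQ equals ranking by inhibition", {
  db <- default_curve_db()
  sv <- gen_survey(survey_spec(n_per_region = c("US East Coast" = 5L,
                                                "East Asia" = 5L)), seed = 2)
  sv <- sv[sv$region %in% c("US East Coast", "East Asia"), ]
  res <- station_inhibition(sv, db)
  expect_identical(order(res$teq), order(res$inhibition))
})

test_that("unknown herbicides are reported with the offending station", {
  db <- curve_db(list(atrazine = logistic_ec50(10)))
  sv <- data.frame(station_id = "sX", region = "r", lat = 0, lon = 0,
                   year = 2000, atrazine = 1, mysteryX = 2)
  expect_error(station_inhibition(sv, db), "mysteryX")
  expect_error(station_inhibition(sv, db), "sX")
})

test_that("exceedance counts use strict inequality", {
  ex <- exceedance(c(4, 6, 11), thresholds = c(5, 10))
  expect_equal(ex$count, c(2L, 1L))
  expect_equal(ex$fraction, c(2 / 3, 1 / 3))
  expect_equal(exceedance(c(5, 10), thresholds = c(5, 10))$count, c(1L, 0L))
  expect_equal(exceedance(rep(0, 4))$count, c(0L, 0L, 0L))
  expect_error(exceedance(numeric(0)), "no inhibition")
  expect_error(exceedance(1:3, thresholds = c(10, 5)), "ascending")
})

test_that("inhibition > 5% if and only if TEQ > 5.1", {
  db <- default_curve_db()
  cc <- build_community_curve()
  teqs <- c(5.1 - 1e-6, 5.1, 5.1 + 1e-6, 1, 20)
  inh <- predict(cc, teqs)
  expect_identical(inh > 5, teqs > 5.1)
})

test_that("regional summaries produce ordered quartiles and sane CIs", {
  r <- summarize_region(rep("a", 3), c(1, 2, 3), B = 200, seed = 1)
  expect_equal(r$median, 2)
  expect_equal(r$max, 3)
  expect_true(r$q1 <= r$median && r$median <= r$q3 && r$q3 <= r$max)
  expect_true(r$ci_lo <= r$median && r$median <= r$ci_hi)
  # identical values -> zero-width CI
  r2 <- summarize_region(rep("a", 10), rep(7, 10), B = 200, seed = 1)
  expect_equal(r2$ci_lo, 7)
  expect_equal(r2$ci_hi, 7)
  # single-station region flagged degenerate
  r3 <- summarize_region(c("a", "b", "b"), c(1, 2, 3), B = 50, seed = 1)
  expect_true(r3$degenerate[r3$region == "a"])
  # reproducible under the seed
  v <- stats::rlnorm(50)
  r4 <- summarize_region(rep("a", 50), v, B = 500, seed = 9)
  r5 <- summarize_region(rep("a", 50), v, B = 500, seed = 9)
  expect_identical(r4[c("ci_lo", "ci_hi")], r5[c("ci_lo", "ci_hi")])
})

test_that("chronology ANOVA matches hand computation and the lm oracle", {
  # groups 1:3, 4:6, 7:9 -> SSB = 54 (df 2), SSW = 6 (df 6), F = 27
  years <- c(1995, 1996, 1997, 2005, 2006, 2007, 2015, 2016, 2017)
  vals <- 1:9
  res <- chronology_anova(years, vals)
  expect_equal(res$F, 27)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 6L)
  # two identical groups -> F = 0
  res0 <- chronology_anova(c(1995, 1996, 2005, 2006), c(2, 4, 2, 4))
  expect_equal(res0$F, 0)
  # oracle check on random fixtures
  set.seed(21)
  for (i in 1:5) {
    yr <- sample(c(1995, 2005, 2015), 30, replace = TRUE)
    v <- stats::rnorm(30) + (yr - 2005) / 100
    mine <- chronology_anova(yr, v)
    stage <- factor(findInterval(yr, c(1990, 2001, 2012)))
    orc <- stats::anova(stats::lm(v ~ stage))
    expect_equal(mine$F, orc$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, orc$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # insufficient data flagged, not an error
  resna <- chronology_anova(c(1995, 1995), c(1, 2))
  expect_false(resna$ok)
})

test_that("p-values are roughly uniform under the null", {
  set.seed(99)
  ps <- vapply(1:100, function(i) {
    yr <- rep(c(1995, 2005, 2015), each = 8)
    chronology_anova(yr, stats::rnorm(24))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the carbon-loss arithmetic reproduces the headline range", {
  expect_equal(carbon_loss(), c(3.75e8, 8.75e8))
  expect_equal(carbon_loss(5e10, coastal_share = 0.25, inhibition = 0.05),
               6.25e8)
})
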