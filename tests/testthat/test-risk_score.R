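test_that("residual integral has the first-order closed form", {
  # lambda = 0.01/day, T = 3650 -> (1 - e^-36.5)/0.01 ~ 100
  expect_equal(residual_integral(69.3147180559945, 3650), 100,
               tolerance = 1e-9)
  # unit exponential: DT50 = ln 2, long horizon -> 1
  expect_equal(residual_integral(log(2), 1e6), 1)
  # negligible decay -> integral approaches the horizon
  expect_equal(residual_integral(1e12, 365), 365, tolerance = 1e-6)
  expect_error(residual_integral(-1, 10), "> 0")
  # numeric quadrature oracle on 10 fixtures
  set.seed(5)
  for (i in 1:10) {
    dt50 <- stats::runif(1, 5, 500); tt <- stats::runif(1, 30, 2000)
    quad <- stats::integrate(function(u) exp(-log(2) / dt50 * u), 0, tt,
                             rel.tol = 1e-12)$value
    expect_equal(residual_integral(dt50, tt), quad, tolerance = 1e-9)
  }
})

test_that("soil load, PEC and PNEC follow the indicator formulas", {
  expect_equal(soil_load(100, 1), 1)
  expect_equal(soil_load(0, 5), 0)
  expect_equal(soil_load(50, 2), 1)
  expect_error(soil_load(120, 1), "\\[0, 100\\]")
  expect_equal(pec(1, 100), 1 / 4500)
  expect_equal(pec(0, 100), 0)
  expect_equal(pec(2, 100), 2 * pec(1, 100))   # linearity in S
  expect_equal(pnec(1000), 1)
  expect_equal(pnec(0.2222), 2.222e-4)
  expect_equal(pnec(5 * 1000), 5 * pnec(1000)) # scaling
  expect_error(pnec(0), "> 0")
})

test_that("the hand-computed cell gives RQ = 1, RP = 0, class negligible", {
  # VDT 100, AR 1 -> S = 1; DT50 = 100 ln2 and T = 3650 -> integral = 100;
  # PEC = 1/4500; LC50 = 1000/4500 -> PNEC = 1/4500 -> RQ = 1 exactly
  props <- data.frame(herbicide = "atrazine", DT50_days = 100 * log(2),
                      DT90_days = NA, LC50_earthworm = 1000 / 4500,
                      LC50_fish = 1000 / 4500)
  cells <- data.frame(cell_id = "c1", region = "r", area_km2 = 10,
                      crop = "corn", herbicide = "atrazine", AR = 1, VDT = 100)
  r <- risk_point(cells, props, horizon_days = 3650)$cells
  expect_equal(r$sum_RQ, 1, tolerance = 1e-9)
  expect_equal(r$RP, 0, tolerance = 1e-9)
  expect_identical(as.character(r$class), "negligible")  # RP <= 0
})

test_that("risk points aggregate over pairs and classify on log10 scale", {
  props <- default_herbicide_props()
  # three pairs engineered to RQ {1, 10, 100}: rp = log10(111)
  base <- data.frame(cell_id = "c1", region = "r", area_km2 = 1,
                     crop = "corn", herbicide = "atrazine", VDT = 100)
  i <- match("atrazine", props$herbicide)
  integ <- residual_integral(props$DT50_days[i], 365)
  pn <- min(pnec(props$LC50_earthworm[i]), pnec(props$LC50_fish[i]))
  ar1 <- 1 * pn * 4500 * 100 / integ * 100 / 100  # AR giving RQ = 1 at VDT 100
  cells <- rbind(base, base, base)
  cells$crop <- c("corn", "wheat", "rice")
  cells$AR <- ar1 * c(1, 10, 100)
  r <- risk_point(cells, props)$cells
  expect_equal(r$RP, log10(111), tolerance = 1e-9)
  expect_identical(as.character(r$class), "medium")
})

test_that("class boundaries respect the printed inequalities", {
  expect_identical(as.character(classify_rp(c(-Inf, -1, 0, 1e-12, 1, 1.0001, 3, 3.0001))),
                   c("negligible", "negligible", "negligible", "low", "low",
                     "medium", "medium", "high"))
  # every finite rp maps to exactly one class
  rp <- seq(-5, 6, by = 0.25)
  expect_false(anyNA(classify_rp(rp)))
})

test_that("zero application leads to negligible risk", {
  props <- default_herbicide_props()
  cells <- data.frame(cell_id = "c1", region = "r", area_km2 = 5,
                      crop = "corn", herbicide = "atrazine", AR = 0, VDT = 50)
  r <- risk_point(cells, props)$cells
  expect_equal(r$sum_RQ, 0)
  expect_identical(r$RP, -Inf)
  expect_identical(as.character(r$class), "negligible")
})

test_that("risk point is monotone nondecreasing in every application rate", {
  props <- default_herbicide_props()
  cells <- data.frame(cell_id = "c1", region = "r", area_km2 = 1,
                      crop = c("corn", "wheat"),
                      herbicide = c("atrazine", "simazine"),
                      AR = c(1, 2), VDT = c(50, 80))
  rp0 <- risk_point(cells, props)$cells$RP
  for (j in 1:2) {
    up <- cells; up$AR[j] <- up$AR[j] * 1.5
    expect_gte(risk_point(up, props)$cells$RP, rp0)
  }
})

test_that("missing properties are reported with the offending pair", {
  props <- default_herbicide_props()
  cells <- data.frame(cell_id = "c9", region = "r", area_km2 = 1,
                      crop = "corn", herbicide = "glyphosate", AR = 1, VDT = 50)
  expect_error(risk_point(cells, props), "glyphosate")
  expect_error(risk_point(cells, props), "c9")
})

test_that("regional class fractions are area-weighted and sum to one", {
  res <- data.frame(cell_id = c("a", "b", "c"), region = "r",
                    area_km2 = c(10, 10, 0),
                    class = factor(c("high", "low", "medium"),
                                   levels = c("negligible", "low", "medium", "high")))
  sm <- summarize_risk_map(res)
  expect_equal(sm$frac_high, 0.5)
  expect_equal(sm$frac_low, 0.5)
  expect_equal(sm$frac_medium, 0)   # zero-area cell excluded
  expect_equal(sm$frac_negligible + sm$frac_low + sm$frac_medium + sm$frac_high,
               1, tolerance = 1e-9)
  expect_error(summarize_risk_map(res[, -1]), "lack")
})

test_that("planted risk-class fractions are recovered exactly", {
  planted <- c(negligible = 0.3498, low = 0.2, medium = 0.2818, high = 0.1684)
  g <- gen_grid(n_cells = 10000, planted = planted)
  r <- risk_point(g$cells, g$props)$cells
  tot <- sum(r$area_km2)
  for (cl in names(planted))
    expect_equal(sum(r$area_km2[r$class == cl]) / tot, planted[[cl]],
                 tolerance = 1e-12)
})
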