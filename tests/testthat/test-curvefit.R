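test_that("noiseless data generated from each family is recovered exactly", {
  x <- seq(10, 150, by = 10)
  cases <- list(
    linear = list(b = c(b0 = 1.2, b1 = -0.004),
                  y = function(x) 1.2 - 0.004 * x),
    logarithm = list(b = c(b0 = 2.5, b1 = -0.33),
                     y = function(x) 2.5 - 0.33 * log(x)),
    quadratic = list(b = c(b0 = 0.7, b1 = 0.003, b2 = -2e-5),
                     y = function(x) 0.7 + 0.003 * x - 2e-5 * x^2),
    composite = list(b = c(b0 = 1.4, b1 = 0.997),
                     y = function(x) 1.4 * 0.997^x),
    power = list(b = c(b0 = 6.5, b1 = -0.39),
                 y = function(x) 6.5 * x^-0.39),
    growth = list(b = c(b0 = 0.31, b1 = -0.0026),
                  y = function(x) exp(0.31 - 0.0026 * x)),
    exponential = list(b = c(b0 = 1.37, b1 = -0.0026),
                       y = function(x) 1.37 * exp(-0.0026 * x)))
  for (form in names(cases)) {
    fit <- quiet(fit_curve(x, cases[[form]]$y(x), form))
    expect_equal(fit$coefficients, cases[[form]]$b, tolerance = 1e-8,
                 label = form)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10, label = form)
    expect_equal(predict(fit, x), cases[[form]]$y(x), tolerance = 1e-8,
                 label = form)
  }
  # logistic with a finite ceiling
  u <- 1.1
  ylog <- 1 / (1 / u + 0.002 * 1.03^x)
  fl <- quiet(fit_curve(x, ylog, "logistic", logistic_u = u))
  expect_equal(unname(fl$coefficients), c(0.002, 1.03), tolerance = 1e-8)
  expect_equal(predict(fl, x), ylog, tolerance = 1e-10)
})

test_that("OLS invariants hold on the fitting scale", {
  sw <- case_study_sweeps()$W9
  fq <- fit_curve(sw, form = "quadratic")
  # residual orthogonality to the regressors
  resid <- sw$bor - predict(fq, sw)
  expect_lt(abs(sum(resid)), 1e-10)
  expect_lt(abs(sum(resid * sw$beds)), 1e-7)
  expect_lt(abs(sum(resid * sw$beds^2)), 1e-3)
  # R^2 = squared correlation for a single regressor
  fl <- fit_curve(sw, form = "linear")
  expect_equal(fl$r_squared, cor(sw$beds, sw$bor)^2, tolerance = 1e-12)
  # F = (R2/df1) / ((1-R2)/df2)
  expect_equal(fq$f_stat,
               (fq$r_squared / fq$df1) / ((1 - fq$r_squared) / fq$df2),
               tolerance = 1e-10)
  expect_equal(fq$df1, 2L)
  expect_equal(fq$df2, nrow(sw) - 3L)
})

test_that("adding a constant to y shifts only b0 for additive families", {
  x <- seq(20, 120, by = 10)
  set.seed(2)
  y <- 0.9 - 0.002 * x + rnorm(length(x), 0, 0.01)
  for (form in c("linear", "quadratic", "logarithm")) {
    f0 <- fit_curve(x, y, form)
    f1 <- fit_curve(x, y + 0.25, form)
    expect_equal(f1$coefficients[["b0"]], f0$coefficients[["b0"]] + 0.25,
                 tolerance = 1e-9, label = form)
    expect_equal(f1$coefficients[-1], f0$coefficients[-1],
                 tolerance = 1e-9, label = form)
  }
})

test_that("selection ranks by R^2 with a fewer-coefficients tie-break", {
  # data exactly on a line: linear and quadratic both attain R^2 = 1,
  # linear wins by parsimony
  x <- seq(10, 100, by = 10)
  cf <- quiet(fit_bor_curves(x, 0.2 + 0.005 * x))
  expect_equal(cf$best$form, "linear")
  expect_equal(cf$fits$quadratic$r_squared, 1, tolerance = 1e-10)
  # the packaged W9 sweep: quadratic beats the other seven
  cfw <- fit_bor_curves(case_study_sweeps()$W9)
  expect_equal(cfw$best$form, "quadratic")
  expect_equal(cfw$table$form[1], "quadratic")
  expect_true(all(cfw$table$r_squared[-1] <= cfw$table$r_squared[1]))
})

test_that("families with domain violations are skipped, not fatal", {
  x <- 1:8
  y <- c(0.5, 0.4, 0.3, 0.2, 0.1, -0.05, -0.1, -0.2)  # non-positive tail
  expect_error(fit_curve(x, y, "composite"), "domain")
  cf <- quiet(fit_bor_curves(x, y))
  expect_false(any(c("composite", "power", "growth", "exponential",
                     "logistic") %in% names(cf$fits)))
  expect_true(all(c("linear", "quadratic", "logarithm") %in% names(cf$fits)))
  # non-positive predictors knock out the log-x families
  expect_error(fit_curve(c(-1, 0:6), seq(0.1, 0.8, by = 0.1), "logarithm"),
               "domain")
  expect_error(fit_curve(1:3, c(0.1, 0.2, 0.3), "quadratic"), "at least")
})

test_that("quadratic fits export to BOR response functions and round-trip", {
  sw <- case_study_sweeps()$W10
  cf <- fit_bor_curves(sw)
  fn <- as_bor_function(cf)
  expect_s3_class(fn, "bor_function")
  expect_equal(evaluate_bor(fn, sw$beds), predict(cf, sw), tolerance = 1e-12)
  # non-quadratic fits are rejected
  flin <- fit_curve(sw, form = "linear")
  expect_error(as_bor_function(flin), "quadratic")
  # constant function evaluates flat
  expect_equal(evaluate_bor(bor_function(0.5, 0, 0), c(1, 50, 500)),
               rep(0.5, 3))
  expect_message(evaluate_bor(bor_function(1.2, 0, 0), 10, warn = TRUE),
                 "outside")
})
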