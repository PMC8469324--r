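test_that("OLS fit matches the normal-equations oracle on random data", {
  set.seed(31)
  for (i in 1:20) {
    doses <- sort(10^runif(6, -1, 3))
    y <- 5 + 18 * log10(doses) + rnorm(6, 0, 4)
    fit <- fit_dose_response(data.frame(dose = doses, effect_pct = y))
    o <- ols_oracle(log10(doses), y)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(fit$slope, o$slope, tolerance = 1e-8)
    expect_equal(fit$cov, unname(o$cov), tolerance = 1e-8)
    expect_equal(fit$residual_df, o$df)
  }
})

test_that("points on an exact line are fitted without residual", {
  doses <- c(1, 10, 100, 1000)
  fit <- fit_dose_response(data.frame(dose = doses,
                                      effect_pct = 10 * log10(doses) + 5))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$r2, 1)
  expect_equal(max(abs(fit$cov)), 0, tolerance = 1e-12)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_dose_response(data.frame(dose = c(1, 10),
                                            effect_pct = c(1, 2))),
               "3 distinct")
  expect_error(fit_dose_response(data.frame(dose = c(0, 1, 10),
                                            effect_pct = 1:3)),
               "> 0")
})

test_that("study-table fits reproduce the frozen oracle coefficients", {
  # frozen from the normal-equations oracle on the printed group means
  fa <- fit_dose_response(table_drug_a())
  expect_equal(fa$slope, 22.791, tolerance = 1e-3)
  expect_equal(fa$intercept, 9.698, tolerance = 1e-3)
  fb <- fit_dose_response(table_drug_b())
  expect_equal(fb$slope, 35.261, tolerance = 1e-3)
  expect_equal(fb$intercept, -31.853, tolerance = 1e-3)
  fe <- fit_dose_response(table_combo())
  oe <- ols_oracle(log10(table_combo()$dose), table_combo()$effect_pct)
  expect_equal(fe$slope, oe$slope, tolerance = 1e-8)
  expect_equal(fe$intercept, oe$intercept, tolerance = 1e-8)
})

test_that("inverse prediction is self-consistent and unit-anchored", {
  fit <- fit_dose_response(table_drug_a())
  for (lvl in c(20, 30, 50)) {
    ed <- suppressWarnings(ed_x(fit, level = lvl))
    expect_equal(predict_effect(fit, log10(ed$dose))$effect, lvl,
                 tolerance = 1e-9)
  }
  # intercept equal to the level puts the ED at 1 mg/kg whatever the slope
  for (s in c(5, 20, 80)) {
    doses <- c(0.1, 1, 10)
    f <- fit_dose_response(data.frame(dose = doses,
                                      effect_pct = 30 + s * log10(doses)))
    expect_equal(ed_x(f, 30)$dose, 1, tolerance = 1e-9)
  }
})

test_that("study-table effective doses land at the frozen oracle values", {
  eda <- ed_x(fit_dose_response(table_drug_a()), 30)
  expect_equal(eda$dose, ed_oracle(log10(table_drug_a()$dose),
                                   table_drug_a()$effect_pct, 30),
               tolerance = 1e-9)
  expect_equal(eda$dose, 7.7764, tolerance = 1e-4)
  edb <- ed_x(fit_dose_response(table_drug_b()), 30)
  expect_equal(edb$dose, 56.773, tolerance = 1e-3)
  ede <- suppressWarnings(ed_x(fit_dose_response(table_combo()), 30))
  expect_equal(ede$dose, 1.1465, tolerance = 1e-4)
  expect_true(ede$ci_low <= ede$dose && ede$dose <= ede$ci_high)
})

test_that("raising the intercept lowers the effective dose", {
  doses <- c(1, 10, 100)
  eds <- vapply(c(0, 5, 10, 20), function(b0) {
    f <- fit_dose_response(data.frame(dose = doses,
                                      effect_pct = b0 + 15 * log10(doses)))
    suppressWarnings(ed_x(f, 30)$dose)
  }, numeric(1))
  expect_true(all(diff(eds) < 0))
})

test_that("inverse prediction guards its domain", {
  falling <- fit_dose_response(data.frame(dose = c(1, 10, 100),
                                          effect_pct = c(50, 30, 10)))
  expect_error(ed_x(falling, 30), "slope")
  fit <- fit_dose_response(table_drug_a())
  expect_error(ed_x(fit, 0), "level")
  expect_error(ed_x(fit, 100), "level")
  # an ED below the lowest fitted dose triggers the extrapolation warning
  steep <- fit_dose_response(data.frame(dose = c(10, 100, 1000),
                                        effect_pct = c(40, 60, 80)))
  expect_warning(ed_x(steep, 30), "extrapolation")
  # the combination ED25 also extrapolates below the lowest printed dose
  expect_warning(ed_x(fit_dose_response(table_combo()), 25), "extrapolation")
})

test_that("delta-method SE matches a parametric bootstrap at small noise", {
  set.seed(33)
  doses <- 10^seq(0, 2.5, by = 0.5)
  truth <- 10 + 20 * log10(doses)
  sigma <- 0.5
  # fit object carrying the exact coefficient covariance of the generating
  # model, so the check isolates the delta-method propagation itself
  X <- cbind(1, log10(doses))
  fit <- structure(
    list(intercept = 10, slope = 20, cov = sigma^2 * solve(t(X) %*% X),
         residual_df = 1e6, r2 = 1, n_points = 6L,
         dose_range = range(doses), label = ""),
    class = "dr_fit")
  ed <- ed_x(fit, 30)
  boots <- replicate(2000, {
    y <- truth + rnorm(6, 0, sigma)
    ed_oracle(log10(doses), y, 30)
  })
  expect_lt(abs(ed$se - sd(boots)) / sd(boots), 0.15)
})

test_that("curve comparison separates and equates as expected", {
  doses <- c(1, 10, 100, 1000)
  base <- data.frame(dose = doses, effect_pct = 10 + 15 * log10(doses))
  fit1 <- fit_dose_response(base)
  self <- compare_curves(fit1, fit1)
  expect_true(all(self$comparisons$difference == 0))
  expect_true(all(!self$comparisons$significant))
  set.seed(34)
  lifted <- base; lifted$effect_pct <- lifted$effect_pct + 20 + rnorm(4, 0, 0.01)
  fit2 <- fit_dose_response(lifted)
  sep <- compare_curves(fit2, fit1)
  expect_true(all(sep$comparisons$significant))
  expect_match(sep$verdict, "curve A")
})

test_that("drug A outperforms drug B at the shared low-to-mid doses", {
  cmp <- compare_curves(fit_dose_response(table_drug_a()),
                        fit_dose_response(table_drug_b()),
                        log10_doses = c(1.0, 1.5, 2.0, 2.5))
  diffs <- cmp$comparisons$difference
  expect_true(all(diffs[cmp$comparisons$log10_dose <= 2.0] > 0))
})

test_that("non-overlapping dose ranges are rejected", {
  lo <- fit_dose_response(data.frame(dose = c(0.1, 0.3, 1),
                                     effect_pct = c(10, 20, 30)))
  hi <- fit_dose_response(data.frame(dose = c(100, 300, 1000),
                                     effect_pct = c(10, 20, 30)))
  expect_error(compare_curves(lo, hi), "overlap")
})
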