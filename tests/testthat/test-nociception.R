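test_that("trapezoidal AUC matches closed forms on simple shapes", {
  expect_equal(trapezoid_auc(std_grid, rep(2, 13), c(0, 60)), 120)
  expect_equal(trapezoid_auc(c(0, 5, 10), c(0, 4, 0), c(0, 10)), 20)
  counts4 <- rep(4, 13)
  expect_equal(trapezoid_auc(std_grid, counts4, c(0, 15)), 60)
  expect_equal(trapezoid_auc(std_grid, counts4, c(15, 60)), 180)
  expect_equal(trapezoid_auc(std_grid, counts4, c(0, 60)), 240)
})

test_that("trapezoidal AUC rejects bad windows", {
  expect_error(trapezoid_auc(std_grid, rep(1, 13), c(10, 10)), "inverted")
  expect_error(trapezoid_auc(std_grid, rep(1, 13), c(30, 10)), "inverted")
  expect_error(trapezoid_auc(c(0), c(1), c(0, 1)), "at least 2")
  expect_error(trapezoid_auc(std_grid, rep(1, 13), c(-5, 20)), "within")
})

test_that("AUC agrees with a fine-grid Riemann oracle, windows included", {
  set.seed(21)
  for (i in 1:20) {
    times <- sort(runif(8, 0, 60))
    counts <- runif(8, 0, 10)
    w <- sort(runif(2, times[1], times[8]))
    if (diff(w) < 1) w[2] <- w[1] + 1
    expect_equal(trapezoid_auc(times, counts, w),
                 riemann_auc(times, counts, w[1], w[2]),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with pracma's trapezoid on grid-aligned windows", {
  skip_if_not_installed("pracma")
  set.seed(22)
  counts <- rpois(13, 5)
  expect_equal(trapezoid_auc(std_grid, counts, c(0, 60)),
               pracma::trapz(std_grid, counts))
})

test_that("phase AUCs partition the overall integral exactly", {
  tc <- make_tc(rep(2, 13))
  a <- split_phase_aucs(tc)
  expect_equal(a$phase1, 30)
  expect_equal(a$phase2, 90)
  expect_equal(a$overall, 120)
  z <- split_phase_aucs(make_tc(rep(0, 13)))
  expect_equal(unlist(z), c(phase1 = 0, phase2 = 0, overall = 0))
  # early plateau then decay to zero by minute 20; hand-checkable segments
  decay <- make_tc(c(6, 6, 6, 6, rep(0, 9)))
  d <- split_phase_aucs(decay)
  expect_equal(d$phase1, 90)
  expect_equal(d$phase2, riemann_auc(std_grid, decay$counts, 15, 60),
               tolerance = 1e-9)
  set.seed(23)
  for (i in 1:25) {
    tc <- make_tc(rpois(13, 6))
    a <- split_phase_aucs(tc)
    expect_equal(a$phase1 + a$phase2, a$overall, tolerance = 1e-12)
  }
})

test_that("percent antinociception follows the vehicle-relative formula", {
  expect_equal(percent_antinociception(600, 600), 0)
  expect_equal(percent_antinociception(600, 0), 100)
  expect_equal(percent_antinociception(600, 420), 30)
  expect_equal(percent_antinociception(600, 900), -50)  # hyperalgesia kept
  expect_error(percent_antinociception(0, 10), "positive")
  # strictly decreasing in the treated AUC
  treated <- seq(0, 1200, by = 100)
  eff <- vapply(treated, percent_antinociception,
                auc_vehicle_mean = 600, FUN.VALUE = numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("group summaries are exact for proportional suppression", {
  veh <- make_group(list(rep(4, 13), rep(6, 13)), group = "vehicle",
                    is_vehicle = TRUE)
  same <- make_group(list(rep(4, 13), rep(6, 13)), group = "same", dose_a = 1)
  s0 <- summarize_group(same, veh)
  expect_equal(s0$effect_overall, 0)
  expect_equal(s0$effect_phase1, 0)
  half <- make_group(list(rep(2, 13), rep(3, 13)), group = "half", dose_a = 2)
  s50 <- summarize_group(half, veh)
  expect_equal(s50$effect_overall, 50)
  expect_equal(s50$effect_phase2, 50)
  expect_error(summarize_group(half, same), "vehicle")
})

test_that("effect scale is invariant to rescaling all counts", {
  set.seed(24)
  base_veh <- replicate(4, rpois(13, 6) + 1, simplify = FALSE)
  base_trt <- replicate(4, rpois(13, 3) + 1, simplify = FALSE)
  s1 <- summarize_group(make_group(base_trt, "t", dose_a = 1),
                        make_group(base_veh, "v", is_vehicle = TRUE))
  scale3 <- function(l) lapply(l, `*`, 3)
  s3 <- summarize_group(make_group(scale3(base_trt), "t", dose_a = 1),
                        make_group(scale3(base_veh), "v", is_vehicle = TRUE))
  expect_equal(s3$effect_overall, s1$effect_overall, tolerance = 1e-12)
  expect_equal(s3$effect_phase1, s1$effect_phase1, tolerance = 1e-12)
  expect_equal(s3$se_overall, s1$se_overall, tolerance = 1e-12)
})

test_that("summaries recover the simulator's true suppression at large n", {
  p <- sim_params(n_per_group = 200, seed = 425)
  dose <- ground_truth_ed(p, "A", 30)  # true effect exactly 30%
  gs <- simulate_study(p, data.frame(
    label = c("vehicle", "treated"), dose_a = c(0, dose), dose_b = c(0, 0),
    vehicle = c(TRUE, FALSE)))
  s <- summarize_group(gs$treated, gs$vehicle)
  expect_lt(abs(s$effect_overall - 30), 2)
})

test_that("ANOVA with Bonferroni control flags only separated groups", {
  set.seed(26)
  jitter13 <- function(mu) lapply(1:4, function(i) rpois(13, mu))
  veh <- make_group(jitter13(6), "vehicle", is_vehicle = TRUE)
  g0a <- summarize_group(make_group(jitter13(6), "a", dose_a = 1), veh)
  g0b <- summarize_group(make_group(jitter13(6), "b", dose_a = 2), veh)
  ghi <- summarize_group(make_group(jitter13(1), "c", dose_a = 3), veh)
  res <- anova_bonferroni(list(g0a, g0b, ghi), control_label = "a")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$comparisons$p_adj < 0.05,
               res$comparisons$group == "c")
  expect_true(all(res$comparisons$p_adj <= 1))
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_raw))
})

test_that("identical groups give a null ANOVA", {
  set.seed(27)
  counts <- replicate(4, rpois(13, 5), simplify = FALSE)
  veh <- make_group(counts, "vehicle", is_vehicle = TRUE)
  s1 <- summarize_group(make_group(counts, "g1", dose_a = 1), veh)
  s2 <- summarize_group(make_group(counts, "g2", dose_a = 2), veh)
  res <- anova_bonferroni(list(s1, s2), control_label = "g1")
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)
})

test_that("Bonferroni control holds the familywise type-I rate", {
  set.seed(28)
  n_rep <- 1000
  rej <- matrix(NA, n_rep, 2L)
  for (r in seq_len(n_rep)) {
    veh <- make_group(replicate(4, rpois(13, 6), simplify = FALSE),
                      "vehicle", is_vehicle = TRUE)
    ss <- lapply(1:3, function(i)
      summarize_group(make_group(replicate(4, rpois(13, 4), simplify = FALSE),
                                 paste0("g", i), dose_a = i), veh))
    cmp <- anova_bonferroni(ss, control_label = "g1")$comparisons
    rej[r, ] <- cmp$p_adj < 0.05
  }
  # adjusted per-comparison rejection rate stays below the nominal level,
  # and the familywise rate is controlled up to Monte Carlo error
  expect_lte(mean(rej), 0.05)
  expect_lte(mean(rej[, 1] | rej[, 2]),
             0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("ANOVA input validation", {
  veh <- make_group(list(rep(4, 13), rep(5, 13)), "vehicle", is_vehicle = TRUE)
  s <- summarize_group(make_group(list(rep(2, 13), rep(3, 13)), "g"), veh)
  expect_error(anova_bonferroni(list(s), "g"), "at least 2")
  singleton <- summarize_group(make_group(list(rep(2, 13)), "solo"), veh)
  expect_error(anova_bonferroni(list(s, singleton), "g"), "n >= 2")
  expect_error(anova_bonferroni(list(s, s), "missing"), "not among")
})
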