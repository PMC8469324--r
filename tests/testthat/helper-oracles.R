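# Independent oracles and small fixtures used across the suite.

std_grid <- seq(0, 60, by = 5)

make_tc <- function(counts, times = std_grid, animal = "a1",
                    group = "g", dose_a = 0, dose_b = 0) {
  flinch_timecourse(animal, group, dose_a, dose_b, times, counts)
}

make_group <- function(count_list, group = "g", dose_a = 0, dose_b = 0,
                       is_vehicle = FALSE) {
  members <- lapply(seq_along(count_list), function(i)
    make_tc(count_list[[i]], animal = sprintf("%s_%d", group, i),
            group = group, dose_a = dose_a, dose_b = dose_b))
  treatment_group(group, members, is_vehicle = is_vehicle)
}

# fine-grid Riemann midpoint sum of the piecewise-linear interpolant;
# independent of the trapezoid implementation under test
riemann_auc <- function(times, counts, t0, t1, n = 200000L) {
  x <- seq(t0, t1, length.out = n + 1L)
  mid <- (x[-1L] + x[-length(x)]) / 2
  y <- approx(times, counts, xout = mid)$y
  sum(y) * (t1 - t0) / n
}

# closed-form OLS via the normal equations, with coefficient covariance
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- sum(res^2) / df
  list(intercept = beta[1L], slope = beta[2L],
       cov = s2 * solve(XtX), df = df)
}

# inverse prediction through the oracle fit
ed_oracle <- function(x, y, level) {
  o <- ols_oracle(x, y)
  10^((level - o$intercept) / o$slope)
}

# the printed group-mean dose-effect tables (overall % antinociception)
table_drug_a <- function() data.frame(  # acetylsalicylic acid
  dose = c(3.16, 10, 31.62, 100, 316.22, 562.34),
  effect_pct = c(14.78, 38.77, 46.85, 56.02, 62.43, 72.94))

table_drug_b <- function() data.frame(  # pomegranate peel extract
  dose = c(10, 31.62, 100, 316.22, 562.34, 1000),
  effect_pct = c(4.83, 25.99, 28.69, 57.81, 60.92, 80.22))

table_combo <- function() data.frame(   # 1:1 fixed-ratio combination
  dose = c(34, 17, 8.51, 4.27, 2.12, 1.06),
  effect_pct = c(62.80, 50.60, 48.70, 43.51, 33.48, 30.41))
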