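test_that("single-regime fit recovers exact and noisy slopes", {
  s <- synthetic_charge_series(1.25, duration = 200, noise_sd = 0)
  fit <- fit_single(s, voltage = 40)
  expect_equal(fit$segments$slope, 1.25, tolerance = 1e-10)
  expect_equal(fit$segments$r_squared, 1, tolerance = 1e-10)

  # zero-trend noise: slope indistinguishable from zero
  s0 <- synthetic_charge_series(0, duration = 500, noise_sd = 0.5, seed = 3)
  f0 <- fit_single(s0, voltage = 40)
  se <- sqrt(sum(residuals(f0)^2) / (length(s0$times) - 2) /
               sum((s0$times - mean(s0$times))^2))
  expect_lt(abs(f0$segments$slope) / se, 3)

  expect_error(fit_single(cumulative_charge(events_df(), times = 0:5)),
               "grid points")
})

test_that("the change point is found exactly on clean data and within
           tolerance under noise", {
  clean <- synthetic_charge_series(c(0.8, 1.9), change_at = 270, noise_sd = 0)
  expect_equal(fit_changepoint(clean, 50, voltage = 40)$bifurcation_time, 270)

  hits <- 0; taus <- numeric(20)
  for (sd in 1:20) {
    qs <- synthetic_charge_series(c(0.8, 1.9), change_at = 270, seed = sd)
    taus[sd] <- fit_changepoint(qs, 50, voltage = 40)$bifurcation_time
    if (abs(taus[sd] - 270) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_lt(sqrt(mean((taus - 270)^2)), 10)

  # the returned time respects the min-segment exclusion window
  edge <- synthetic_charge_series(c(0.5, 3), change_at = 30, noise_sd = 0,
                                  duration = 500)
  tau <- fit_changepoint(edge, 50, voltage = 40)$bifurcation_time
  expect_gte(tau, 50)
  expect_lte(tau, 450)

  expect_error(fit_changepoint(synthetic_charge_series(1, duration = 10), 50),
               "min_segment")
})

test_that("two-segment SSE never exceeds the single-segment SSE", {
  for (sd in 1:5) {
    qs <- synthetic_charge_series(c(1, 1.5), change_at = 200, seed = sd)
    expect_lte(fit_changepoint(qs, 50, voltage = 40)$sse,
               fit_single(qs, voltage = 40)$sse + 1e-9)
  }
})

test_that("model selection separates genuine bifurcations from noise", {
  # a clean single line stays single
  fit <- regime_fit(synthetic_charge_series(1.5, noise_sd = 0.4, seed = 1),
                    voltage = 40, min_segment = 50)
  expect_equal(fit$model, "single")

  # strong two-slope series: selected in at least 18/20 seeds
  two <- sum(vapply(1:20, function(sd) {
    regime_fit(synthetic_charge_series(c(0.8, 1.9), change_at = 270,
                                       seed = sd),
               voltage = 40, min_segment = 50)$model == "two-segment"
  }, logical(1)))
  expect_gte(two, 18)

  # zero-trend random walks: at most 2/20 false selections
  fp <- sum(vapply(1:20, function(sd) {
    regime_fit(synthetic_charge_series(0, noise = "step", seed = 100 + sd),
               voltage = 40, min_segment = 50)$model == "two-segment"
  }, logical(1)))
  expect_lte(fp, 2)
})

test_that("regime_fit objects expose the standard modelling methods", {
  qs <- synthetic_charge_series(c(0.8, 1.9), change_at = 270, seed = 2)
  fit <- regime_fit(qs, voltage = 40, renorm = 0.586, min_segment = 50)
  expect_s3_class(fit, "regime_fit")
  expect_equal(fit$model, "two-segment")
  expect_length(coef(fit), 4)
  expect_equal(length(predict(fit)), length(qs$times))
  expect_equal(length(residuals(fit)), length(qs$times))
  expect_equal(predict(fit, times = 0)[1], fit$segments$intercept[1])
  expect_lt(mean(abs(residuals(fit))), 1)
  expect_output(print(fit), "two-segment")
  expect_output(summary(fit), "selection score")
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("state classification reproduces the reference thresholds", {
  mk_fit <- function(conductances, r2 = 0.995) {
    seg <- data.frame(start = c(0, 270)[seq_along(conductances)],
                      end = c(270, 500)[seq_along(conductances)],
                      slope = conductances, intercept = 0,
                      conductance = conductances, r_squared = r2,
                      n_events = 100, current_ratio = 2)
    poregate:::new_regime_fit(
      model = if (length(conductances) == 1) "single" else "two-segment",
      segments = seg,
      bifurcation_time = if (length(conductances) == 2) 270 else NA_real_,
      sse = 1, series = NULL, voltage = 40, renorm = 1)
  }
  # sigma = 2.18 nS, R2 = 0.99 against a 3.71 nS open state: stable low,
  # sitting at 59% of the open conductance
  cls <- classify_state(mk_fit(2.18, r2 = 0.99), 3.71)
  expect_equal(cls$label, "stable-low")
  expect_equal(round(cls$criteria$fraction_of_open, 2), 0.59)

  expect_equal(classify_state(mk_fit(3.71), 3.71)$label, "open-like")
  # low/high segment pair spanning the bifurcation: bistable
  expect_equal(classify_state(mk_fit(c(1.57, 3.66)), 3.71)$label, "bistable")
  expect_equal(classify_state(mk_fit(c(3.66, 1.57)), 3.71)$label, "bistable")
  # low conductance but poor linearity is not a stable state
  expect_equal(classify_state(mk_fit(2.18, r2 = 0.8), 3.71)$label, "unstable")

  # monotone in the sigma threshold: raising it never shrinks the set
  sigmas <- c(1.2, 1.9, 2.2, 2.6, 3.0)
  lab <- function(th) vapply(sigmas, function(g)
    classify_state(mk_fit(g, r2 = 0.995), 3.71,
                   thresholds = list(sigma = th))$label, character(1))
  low1 <- lab(2.3) == "stable-low"
  low2 <- lab(3.0) == "stable-low"
  expect_true(all(low2[low1]))
  expect_gte(sum(low2), sum(low1))
})

test_that("conductance screening selects strictly sub-threshold conformers", {
  scr <- screen_conformers(data.frame(conductance = c(1, 2, 2.49, 2.5, 3)),
                           threshold_nS = 2.5, open_reference_nS = 3.7)
  expect_equal(scr$summary$n_selected, 3)
  expect_equal(scr$summary$percent_of_open, 67)

  # constructed batch: exactly the 55 sub-threshold members are selected
  batch <- data.frame(conformer = 1:200,
                      conductance = c(runif(55, 1, 2.4), runif(145, 2.6, 4)))
  scr2 <- screen_conformers(batch, 2.5, 3.7)
  expect_equal(scr2$summary$n_selected, 55)
  expect_true(all(scr2$selected$conformer <= 55))

  empty <- screen_conformers(data.frame(conductance = c(3, 4)), 2.5, 3.7)
  expect_equal(empty$summary$n_selected, 0)
  expect_equal(nrow(empty$selected), 0)
  expect_error(screen_conformers(data.frame(conductance = numeric(0))),
               "empty")
})

test_that("abrupt regime switches have bimodal local slopes", {
  # a bistable series (obstruction released at 250 ns): local slopes in
  # 50 ns windows cluster at the two regime currents with no plateau between
  qs <- synthetic_charge_series(c(0.9, 1.9), change_at = 250, seed = 8)
  win <- 50; step <- 10
  starts <- seq(0, 500 - win, by = step)
  slopes <- vapply(starts, function(t0) {
    sel <- qs$times >= t0 & qs$times <= t0 + win
    poregate:::ols_line(qs$times[sel], qs$q[sel])$slope
  }, numeric(1))
  km <- stats::kmeans(slopes, centers = c(min(slopes), max(slopes)))
  centres <- sort(km$centers)
  gap <- centres[2] - centres[1]
  within_sd <- sqrt(max(km$withinss / km$size))
  expect_gt(gap, 4 * within_sd)     # two well-separated slope clusters
  # no intermediate plateau: nothing dwells midway between the two regimes
  mid <- abs(slopes - mean(centres)) < gap / 6
  expect_lt(mean(mid), 0.1)
})
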