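test_that("the Boltzmann curve evaluates to its midrange and asymptotes", {
  m <- cell_death_threshold() # K 16.2, alpha 0.5, t0 90, C 5.5
  expect_equal(predict(m, 90), 16.2 / 2 + 5.5) # 13.6 kPa at midrange
  expect_equal(predict(m, 1e6), 5.5, tolerance = 1e-9)   # lower asymptote C
  expect_equal(predict(m, -1e6), 21.7, tolerance = 1e-9) # upper asymptote K+C
  # midrange identity holds for arbitrary models
  set.seed(1)
  for (i in 1:10) {
    r <- threshold_model(K = runif(1, 1, 40), alpha = runif(1, 0.05, 3),
                         t0 = runif(1, 40, 110), C = runif(1, 0, 10))
    expect_equal(predict(r, r$t0), r$K / 2 + r$C)
  }
})

test_that("the curve is strictly decreasing in t, increasing in K and C", {
  m <- cell_death_threshold()
  tt <- seq(20, 130, by = 1)
  expect_true(all(diff(predict(m, tt)) < 0))
  up_K <- threshold_model(m$K + 1, m$alpha, m$t0, m$C)
  up_C <- threshold_model(m$K, m$alpha, m$t0, m$C + 1)
  expect_true(all(predict(up_K, tt) > predict(m, tt)))
  expect_true(all(predict(up_C, tt) > predict(m, tt)))
})

test_that("invalid parameters are rejected", {
  expect_error(threshold_model(K = -1, alpha = 0.5, t0 = 90, C = 5), "`K`")
  expect_error(threshold_model(K = 1, alpha = 0, t0 = 90, C = 5), "`alpha`")
  expect_error(threshold_model(K = 1, alpha = 0.5, t0 = 90, C = -2), "`C`")
})

test_that("sum of squared residuals matches hand-computed values", {
  m <- cell_death_threshold()
  t <- c(30, 60, 90, 120)
  on_curve <- tibble::tibble(t_min = t, sigma_kpa = predict(m, t))
  expect_equal(sse_threshold(m, on_curve), 0)
  one_off <- tibble::tibble(t_min = 90, sigma_kpa = predict(m, 90) + 1)
  expect_equal(sse_threshold(m, one_off), 1)
  two_off <- tibble::tibble(t_min = c(30, 90),
                            sigma_kpa = predict(m, c(30, 90)) + c(1, -2))
  expect_equal(sse_threshold(m, two_off), 5)
  expect_error(sse_threshold(m, tibble::tibble(t_min = numeric(),
                                               sigma_kpa = numeric())),
               "no points")
})

test_that("model comparison returns componentwise deltas", {
  a <- cell_death_threshold()
  b <- in_vivo_reference_threshold()
  cmp <- compare_thresholds(a, b)
  expect_equal(cmp$delta[cmp$term == "K"], 6.8)
  expect_equal(cmp$delta[cmp$term == "C"], 3.1)
  same <- compare_thresholds(a, a)
  expect_true(all(same$delta == 0))
  arb <- compare_thresholds(threshold_model(10, 1, 50, 2),
                            threshold_model(12, 0.5, 70, 1))
  expect_equal(arb$delta, c(2, -0.5, 20, -1))
})

test_that("noiseless fits recover the generating parameters", {
  pts <- simulate_fit_points(cell_death_threshold(),
                             t_grid = seq(30, 120, by = 5),
                             noise_sd = 0, replicates = 1)
  fit <- fit_threshold(pts, "cell_death", seed = 1)
  expect_equal(fit$K, 16.2, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-6)
  expect_equal(fit$t0, 90, tolerance = 1e-6)
  expect_equal(fit$C, 5.5, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  # refitting from the solution cannot improve the optimum
  refit <- fit_threshold(pts, "cell_death",
                         constraints = fit$constraints, starts = 1, seed = 2)
  expect_gte(refit$sse, fit$sse - 1e-10)
})

test_that("noiseless recovery holds across random truth models", {
  set.seed(99)
  tg <- seq(30, 120, by = 5)
  for (i in 1:20) {
    truth <- threshold_model(K = runif(1, 5, 30), alpha = runif(1, 0.1, 1.5),
                             t0 = runif(1, 45, 105), C = runif(1, 0.5, 15))
    pts <- simulate_fit_points(truth, tg, noise_sd = 0, replicates = 1)
    fit <- fit_threshold(pts, "reference", starts = 12, seed = i)
    expect_equal(fit$K, truth$K, tolerance = 1e-4)
    expect_equal(fit$alpha, truth$alpha, tolerance = 1e-4)
    expect_equal(fit$t0, truth$t0, tolerance = 1e-4)
    expect_equal(fit$C, truth$C, tolerance = 1e-4)
  }
})

test_that("degenerate fit inputs error", {
  m <- cell_death_threshold()
  few <- simulate_fit_points(m, t_grid = c(30, 60, 90), noise_sd = 0,
                             replicates = 1)
  expect_error(fit_threshold(few, "cell_death"), "underdetermined")
  same_t <- tibble::tibble(t_min = rep(60, 6), sigma_kpa = rnorm(6, 15))
  expect_error(fit_threshold(same_t, "cell_death"), "degenerate")
})

test_that("parameters can be fixed at reference values", {
  pts <- simulate_fit_points(cell_death_threshold(), seq(30, 120, 15),
                             noise_sd = 0, replicates = 1)
  fit <- fit_threshold(pts, "cell_death", fixed = c(alpha = 0.5, t0 = 90),
                       seed = 4)
  expect_equal(fit$alpha, 0.5)
  expect_equal(fit$t0, 90)
  expect_equal(fit$K, 16.2, tolerance = 1e-6)
  expect_equal(fit$C, 5.5, tolerance = 1e-6)
  expect_true(all(tidy(fit)$fixed[tidy(fit)$term %in% c("alpha", "t0")]))
})

test_that("C constraints are enforced when the data pull past them", {
  # truth C above the cell-death cap: fit must stop below 6
  truth_hi <- threshold_model(K = 16, alpha = 0.5, t0 = 90, C = 7)
  pts_hi <- simulate_fit_points(truth_hi, seq(30, 120, 5), noise_sd = 0,
                                replicates = 1)
  fit_hi <- fit_threshold(pts_hi, "cell_death", seed = 5)
  expect_lt(fit_hi$C, 6)
  expect_gt(fit_hi$C, 5.5) # pushed against the bound, not somewhere low
  # truth C below the no-damage floor: fit must stay above 3.7
  truth_lo <- threshold_model(K = 13, alpha = 0.5, t0 = 90, C = 3)
  pts_lo <- simulate_fit_points(truth_lo, seq(30, 120, 5), noise_sd = 0,
                                replicates = 1)
  fit_lo <- fit_threshold(pts_lo, "no_damage", seed = 6)
  expect_gt(fit_lo$C, 3.7)
  expect_lt(fit_lo$C, 4.2)
})

test_that("noisy recovery: median relative error of K and C stays small", {
  truth <- cell_death_threshold()
  tg <- seq(30, 120, by = 15)
  errs <- t(vapply(1:100, function(i) {
    pts <- simulate_fit_points(truth, tg, noise_sd = 0.3, replicates = 5,
                               seed = 1000 + i)
    fit <- fit_threshold(pts, "cell_death", starts = 6, seed = i)
    c(K = abs(fit$K - truth$K) / truth$K,
      C = abs(fit$C - truth$C) / truth$C)
  }, c(K = 0, C = 0)))
  expect_lte(stats::median(errs[, "K"]), 0.05)
  expect_lte(stats::median(errs[, "C"]), 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  pts <- simulate_fit_points(no_damage_threshold(), seq(30, 120, 15),
                             noise_sd = 0.2, replicates = 3, seed = 2)
  fit <- fit_threshold(pts, "no_damage", seed = 3)
  td <- tidy(fit)
  expect_equal(td$term, c("K", "alpha", "t0", "C"))
  expect_true(all(c("estimate", "unit", "fixed") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_points, nrow(pts))
  expect_equal(gl$sigma_mid, fit$K / 2 + fit$C)
  expect_s3_class(autoplot(fit), "ggplot")
})
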