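test_that("noiseless data from a single-point prior are predicted exactly", {
  truth <- pk_parameters(5, 1, 25)
  dat <- tiny_dataset(3, params = truth, crcl_ml_min = c(40, 80, 120))
  fit <- fake_fit(point_dist(truth$intercept, truth$slope, truth$vc), dat)
  preds <- predictions(fit)
  expect_equal(preds$pred_ind, preds$observed, tolerance = 1e-9)
  expect_equal(preds$pred_pop, preds$observed, tolerance = 1e-9)
  expect_equal(preds$wres, rep(0, nrow(preds)), tolerance = 1e-9)
  m <- fit_metrics(preds)
  expect_equal(m$r2_pop, 1, tolerance = 1e-9)
  expect_equal(m$r2_ind, 1, tolerance = 1e-9)
  expect_equal(m$bias, 0, tolerance = 1e-9)
  expect_equal(m$imprecision, 0, tolerance = 1e-9)
})

test_that("fit metrics match hand-computed regression and moment formulas", {
  withr::local_seed(31)
  obs <- runif(20, 5, 80)
  pred <- obs + rnorm(20, 0, 4)
  preds <- tibble::tibble(
    subject_id = "X", time_h = seq_along(obs), observed = obs,
    pred_pop = pred, pred_ind = pred, wres = (obs - pred) / 2
  )
  m <- fit_metrics(preds)
  expect_equal(m$r2_pop, summary(lm(obs ~ pred))$r.squared)
  expect_equal(m$bias, mean(preds$wres))
  expect_equal(m$imprecision, mean(preds$wres^2) - mean(preds$wres)^2)
  # constant-shift case: wres = -c/SD, imprecision 0
  shift <- tibble::tibble(
    subject_id = "X", time_h = 1:5, observed = c(1, 2, 3, 4, 5),
    pred_pop = c(1, 2, 3, 4, 5) + 3, pred_ind = c(1, 2, 3, 4, 5) + 3,
    wres = -3 / 1
  )
  ms <- fit_metrics(shift)
  expect_equal(ms$bias, -3)
  expect_equal(ms$imprecision, 0)
})

test_that("individual R2 beats population R2 on a mixed-population cohort", {
  withr::local_seed(32)
  pts <- tibble::tibble(intercept = c(3, 8), slope = c(0.8, 1.8),
                        vc = c(18, 45), weight = c(0.5, 0.5))
  dist <- np_distribution(pts)
  # subjects alternate between the two true points
  dat <- purrr::map_dfr(1:6, function(i) {
    p <- pk_parameters(pts$intercept[(i %% 2) + 1], pts$slope[(i %% 2) + 1],
                       pts$vc[(i %% 2) + 1])
    d <- tiny_dataset(1, params = p, crcl_ml_min = 40 + 10 * i,
                      noise_sd = 0.5)
    d$subject_id <- paste0("M", i)
    d
  })
  fit <- fake_fit(dist, dat)
  m <- fit_metrics(predictions(fit))
  expect_gt(m$r2_ind, m$r2_pop)
})

test_that("npde is zero at the simulated median and calibrated under the truth", {
  truth <- pk_parameters(5, 1, 25)
  dat <- tiny_dataset(1, params = truth, obs_times = 44)
  fit <- fake_fit(point_dist(truth$intercept, truth$slope, truth$vc), dat)
  # the observation equals the noiseless prediction = simulation median
  res <- npde(fit, nsim = 2000, seed = 33)
  expect_lt(abs(res$npde$npde[1]), 0.1)
  # calibration: data simulated from the model itself
  withr::local_seed(340)
  coh <- generate_cohort(25, seed = 34)
  dat2 <- simulate_dataset(coh, assay_error(gamma = 1), seed = 35)
  pts <- tibble::tibble(intercept = 4.556, slope = 1.353, vc = 30.68,
                        weight = 1)
  # a generously dispersed prior would miscalibrate; use the fitted model
  fit2 <- suppressWarnings(npag_fit(dat2, control = quick_control(max_cycles = 30)))
  coh3 <- coh
  idx <- sample.int(nrow(fit2$distribution$points), nrow(coh),
                    replace = TRUE, prob = fit2$distribution$points$weight)
  coh3$intercept <- fit2$distribution$points$intercept[idx]
  coh3$slope <- fit2$distribution$points$slope[idx]
  coh3$vc <- fit2$distribution$points$vc[idx]
  dat3 <- simulate_dataset(coh3, fit2$error, seed = 36)
  res3 <- npde(fit2, dat3, nsim = 600, seed = 37)
  expect_lt(abs(res3$mean), 0.15)
  expect_gt(res3$variance, 0.7)
  expect_lt(res3$variance, 1.3)
})

test_that("npde detects inflated residual noise", {
  withr::local_seed(380)
  coh <- generate_cohort(25, seed = 38)
  pts <- tibble::tibble(intercept = 4.556, slope = 1.353, vc = 30.68,
                        weight = 1)
  dat_ok <- simulate_dataset(coh, assay_error(gamma = 1), seed = 39)
  fit <- suppressWarnings(npag_fit(dat_ok, control = quick_control(max_cycles = 30)))
  # regenerate with doubled residual SD relative to the fitted gamma
  coh2 <- coh
  idx <- sample.int(nrow(fit$distribution$points), nrow(coh),
                    replace = TRUE, prob = fit$distribution$points$weight)
  coh2$intercept <- fit$distribution$points$intercept[idx]
  coh2$slope <- fit$distribution$points$slope[idx]
  coh2$vc <- fit$distribution$points$vc[idx]
  dat_bad <- simulate_dataset(
    coh2, assay_error(gamma = 2.5 * fit$gamma), seed = 40
  )
  res_bad <- npde(fit, dat_bad, nsim = 600, seed = 41)
  expect_gt(res_bad$variance, 1)
})

test_that("vpc bands are ordered and collapse without noise", {
  coh <- generate_cohort(10, seed = 51)
  dat <- simulate_dataset(coh, assay_error(gamma = 1), seed = 52)
  pts <- tibble::tibble(intercept = 4.556, slope = 1.353, vc = 30.68,
                        weight = 1)
  fit <- fake_fit(np_distribution(pts), dat)
  bands <- vpc(fit, nsim = 300, seed = 53)
  expect_true(all(bands$sim_lo <= bands$sim_med + 1e-12))
  expect_true(all(bands$sim_med <= bands$sim_hi + 1e-12))
  expect_true(all(bands$obs_lo <= bands$obs_hi + 1e-12))
  # a homogeneous noiseless cohort under a single-point prior with near-zero
  # assay noise: the simulation bands collapse onto the prediction curve
  one <- generate_cohort(1, seed = 54)
  coh0 <- one[rep(1, 10), ]
  coh0$subject_id <- sprintf("H%02d", 1:10)
  coh0$intercept <- 4.556
  coh0$slope <- 1.353
  coh0$vc <- 30.68
  dat0 <- simulate_dataset(coh0, assay_error(gamma = 0), seed = 55)
  fit0 <- fake_fit(np_distribution(pts), dat0,
                   error = assay_error(c0 = 1e-9, c1 = 0, gamma = 1))
  b0 <- vpc(fit0, nsim = 250, seed = 56)
  expect_lt(max(b0$sim_hi - b0$sim_lo), 1e-6)
  expect_equal(b0$sim_med, b0$obs_med, tolerance = 1e-6)
})

test_that("diagnostics are deterministic given a seed", {
  coh <- generate_cohort(6, seed = 55)
  dat <- simulate_dataset(coh, assay_error(gamma = 1), seed = 56)
  pts <- tibble::tibble(intercept = 4.556, slope = 1.353, vc = 30.68,
                        weight = 1)
  fit <- fake_fit(np_distribution(pts), dat)
  expect_identical(npde(fit, nsim = 250, seed = 57)$npde,
                   npde(fit, nsim = 250, seed = 57)$npde)
  expect_identical(vpc(fit, nsim = 250, seed = 58),
                   vpc(fit, nsim = 250, seed = 58))
})
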