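test_that("assay SD follows the proportional polynomial", {
  expect_equal(assay_sd(0, assay_error(gamma = 1)), 0.4388)
  expect_equal(assay_sd(100, assay_error(gamma = 1)), 0.4388 + 0.027 * 100)
  expect_equal(assay_sd(100, assay_error(gamma = 2)),
               2 * (0.4388 + 0.027 * 100))
  expect_error(assay_sd(-1), "conc")
})

test_that("subject log-likelihood matches a direct density product", {
  dat <- tiny_dataset(1, crcl_ml_min = 80)
  subj <- pippk:::as_subjects(dat)[[1]]
  p <- pk_parameters(6, 0.8, 30)
  err <- assay_error(gamma = 1.3)
  pred <- concentration_at(subj$schedule, p, subj$crcl_L_h, subj$obs_times)
  by_hand <- sum(log(dnorm(subj$obs_conc, pred,
                           err$gamma * (0.4388 + 0.027 * pred))))
  expect_equal(subject_loglik(subj, p, err), by_hand, tolerance = 1e-12)
  # observation exactly at the prediction with SD 1
  subj1 <- subj
  subj1$obs_times <- subj$obs_times[1]
  subj1$obs_conc <- pred[1]
  err_unit <- assay_error(c0 = 1 / 1, c1 = 0, gamma = 1) # SD = 1 always
  expect_equal(subject_loglik(subj1, p, err_unit), -0.5 * log(2 * pi))
  # monotone in |residual|
  subj2 <- subj1
  subj2$obs_conc <- pred[1] + 2
  subj3 <- subj1
  subj3$obs_conc <- pred[1] + 4
  expect_gt(subject_loglik(subj2, p, err_unit),
            subject_loglik(subj3, p, err_unit))
})

test_that("solve_weights handles degenerate and symmetric cases", {
  # one column dominates every row
  L <- cbind(rep(1, 4), rep(1e-12, 4), rep(1e-10, 4))
  sw <- solve_weights(L)
  expect_gt(sw$weights[1], 1 - 1e-6)
  # two identical columns split evenly from the symmetric start
  L2 <- cbind(c(1, 0.2), c(1, 0.2), c(0.1, 1))
  sw2 <- solve_weights(L2)
  expect_equal(sw2$weights[1], sw2$weights[2], tolerance = 1e-9)
  expect_error(solve_weights(rbind(c(1, 1), c(0, 0))), "zero likelihood")
})

test_that("EM weights match a dense simplex grid search", {
  withr::local_seed(21)
  for (rep in 1:3) {
    L <- matrix(rexp(15), 5, 3)
    sw <- solve_weights(L, tol = 1e-14, max_iter = 100000)
    step <- 1e-3
    w1 <- seq(0, 1, by = step)
    grid <- expand.grid(w1 = w1, w2 = w1)
    grid <- grid[grid$w1 + grid$w2 <= 1, ]
    W <- cbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
    obj <- rowSums(log(W %*% t(L)))
    expect_gte(sw$objective, max(obj) - 1e-6)
    expect_lt(sw$objective - max(obj), 1e-3) # same optimum, grid-resolution gap
  }
})

test_that("a single true support point is recovered from noiseless data", {
  truth <- pk_parameters(5, 1.2, 28)
  dat <- tiny_dataset(4, params = truth,
                      crcl_ml_min = c(30, 60, 90, 120))
  fit <- suppressWarnings(npag_fit(
    dat, control = quick_control(estimate_gamma = FALSE, max_cycles = 40)
  ))
  pts <- fit$distribution$points
  # intercept and slope trade off along CL = intercept + slope * crcl, so
  # recovery is asserted on the identified quantities: clearance at the
  # cohort's central creatinine clearance, and the volume
  crcl_ref <- crcl_to_L_h(75)
  cl_true <- truth$intercept + truth$slope * crcl_ref
  near <- abs(pts$intercept + pts$slope * crcl_ref - cl_true) / cl_true < 0.01 &
    abs(pts$vc - truth$vc) / truth$vc < 0.01
  expect_gte(sum(pts$weight[near]), 0.99)
})

test_that("log-likelihood trace is non-decreasing and weights stay on the simplex", {
  withr::local_seed(22)
  coh <- generate_cohort(8, seed = 81)
  dat <- simulate_dataset(coh, assay_error(gamma = 1), seed = 82)
  fit <- suppressWarnings(npag_fit(dat, control = quick_control(max_cycles = 25)))
  expect_true(all(diff(fit$trace$log_likelihood) >= -1e-9))
  expect_equal(sum(fit$distribution$points$weight), 1, tolerance = 1e-9)
  expect_true(all(fit$distribution$points$weight >= 0))
})

test_that("posterior estimates implement the two-point Bayes rule", {
  # single-point prior: posterior equals the prior point
  truth <- pk_parameters(5, 1, 25)
  dat <- tiny_dataset(2, params = truth)
  fit1 <- fake_fit(point_dist(4, 1, 30), dat)
  post1 <- posterior_estimates(fit1)
  expect_equal(unique(post1$intercept), 4)
  expect_equal(unique(post1$vc), 30)
  # two-point prior with data generated at one of the points
  pts <- tibble::tibble(intercept = c(5, 15), slope = c(1, 2),
                        vc = c(25, 60), weight = c(0.5, 0.5))
  fit2 <- fake_fit(np_distribution(pts), dat)
  post2 <- posterior_estimates(fit2)
  expect_equal(post2$intercept, rep(5, 2), tolerance = 0.01)
  expect_equal(post2$vc, rep(25, 2), tolerance = 0.01)
  # hand-computed posterior for subject 1
  subj <- fit2$subjects[[1]]
  l1 <- exp(subject_loglik(subj, pk_parameters(5, 1, 25), fit2$error))
  l2 <- exp(subject_loglik(subj, pk_parameters(15, 2, 60), fit2$error))
  w1 <- 0.5 * l1 / (0.5 * l1 + 0.5 * l2)
  expect_equal(post2$intercept[1], w1 * 5 + (1 - w1) * 15, tolerance = 1e-9)
})

test_that("fitted gamma increases with the simulated noise level", {
  coh <- generate_cohort(12, seed = 91)
  dat_lo <- simulate_dataset(coh, assay_error(gamma = 0.5), seed = 92)
  dat_hi <- simulate_dataset(coh, assay_error(gamma = 3), seed = 92)
  ctrl <- quick_control(max_cycles = 30)
  fit_lo <- suppressWarnings(npag_fit(dat_lo, control = ctrl))
  fit_hi <- suppressWarnings(npag_fit(dat_hi, control = ctrl))
  expect_gt(fit_hi$gamma, fit_lo$gamma)
})

test_that("LLOQ policies exclude or substitute flagged observations", {
  dat <- tiny_dataset(2)
  dat$conc_mg_L[dat$event == "obs"][1] <- 0.4
  dat$lloq_flag[dat$event == "obs"][1] <- TRUE
  subs_ex <- pippk:::as_subjects(dat, "exclude", 1)
  expect_equal(length(subs_ex[[1]]$obs_times), 3)
  subs_half <- pippk:::as_subjects(dat, "half", 1)
  expect_equal(length(subs_half[[1]]$obs_times), 4)
  expect_equal(subs_half[[1]]$obs_conc[1], 0.5)
})
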