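test_that("standard dosage regimens deliver the right dose accounting", {
  regs <- standard_dosages()
  in_day1 <- function(s) sum(s$dose[s$start_time < 24])
  expect_equal(in_day1(regs$d1), 12000) # 3 x 4 g q8h
  expect_equal(in_day1(regs$d2), 12000)
  expect_equal(in_day1(regs$d3), 16000) # loading dose adds one
  expect_equal(in_day1(regs$d4), 8000) # q12h
  expect_equal(in_day1(regs$d5), 8000)
  expect_equal(in_day1(regs$d6), 12000)
  expect_equal(regs$d3$start_time[1:3], c(0, 0.5, 8))
  expect_equal(regs$d6$start_time[1:3], c(0, 0.5, 12))
  expect_equal(unique(regs$d4$duration), 0.5)
  expect_equal(unique(regs$d5$duration), 4)
})

test_that("ft_above_mic applies the unbound-fraction threshold scaling", {
  sched <- standard_dosages()$d2
  p <- pk_parameters(4.556, 1.353, 30.68)
  crcl <- crcl_to_L_h(110)
  expect_equal(
    ft_above_mic(sched, p, crcl, mic = 8),
    time_above(sched, p, crcl, threshold = 8 / 0.7, window = c(0, 24)) / 24
  )
  # vanishing MIC on an always-positive profile; absurd MIC gives zero
  expect_equal(ft_above_mic(sched, p, crcl, mic = 1e-9), 1)
  expect_equal(ft_above_mic(sched, p, crcl, mic = 1e6), 0)
  expect_error(ft_above_mic(sched, p, crcl, mic = 0), "mic")
})

test_that("PTA is monotone non-increasing across the doubling MIC grid", {
  withr::local_seed(61)
  pop <- piperacillin_population()
  pars <- parametric_sample(pop$means, pop$sds, 300)
  crcl <- crcl_to_L_h(runif(300, 90, 129))
  for (reg in standard_dosages()[c("d1", "d3")]) {
    curve <- pta_curve(pars, crcl, reg)
    expect_true(all(diff(curve$pta_pct) <= 1e-9))
    expect_true(all(curve$pta_pct >= 0 & curve$pta_pct <= 100))
  }
})

test_that("loading-dose regimens dominate their maintenance counterparts", {
  withr::local_seed(62)
  regs <- standard_dosages()
  times <- seq(0, 48, by = 0.25)
  for (i in 1:5) {
    cs <- random_case()
    d2 <- concentration_at(regs$d2, cs$params, cs$crcl, times)
    d3 <- concentration_at(regs$d3, cs$params, cs$crcl, times)
    expect_true(all(d3 >= d2 - 1e-9))
    d5 <- concentration_at(regs$d5, cs$params, cs$crcl, times)
    d6 <- concentration_at(regs$d6, cs$params, cs$crcl, times)
    expect_true(all(d6 >= d5 - 1e-9))
  }
})

test_that("PTA bands use the published cut-offs inclusively", {
  expect_equal(pta_band(c(95, 90, 89.9, 50, 49.9)),
               c("optimal", "optimal", "intermediate", "intermediate",
                 "poor"))
})

test_that("toxicity exceedance follows closed-form accumulation", {
  regs <- standard_dosages()
  # one very slow-clearing patient on the extended q8h regimen: day-2 free
  # trough far exceeds the sensitive neurotoxicity threshold
  slow <- tibble::tibble(intercept = 0.5, slope = 0, vc = 5)
  tox <- toxicity_probability(slow, 0.5, regs$d2)
  expect_equal(tox$exceedance_pct[tox$name == "neurotoxicity_low"], 100)
  # cross-check with the exact trough
  cmin_free <- 0.7 * cmin_in_window(regs$d2, slow, 0.5, c(24, 48))
  expect_gt(cmin_free, 157.2)
  # an infinite threshold is never exceeded
  thr_inf <- tibble::tibble(name = "inf", threshold = Inf)
  expect_equal(
    toxicity_probability(slow, 0.5, regs$d2, thr_inf)$exceedance_pct, 0
  )
  # non-increasing in the threshold
  withr::local_seed(63)
  pop <- piperacillin_population()
  pars <- parametric_sample(pop$means, pop$sds, 300)
  crcl <- crcl_to_L_h(runif(300, 5, 29))
  tox5 <- toxicity_probability(pars, crcl, regs$d5)
  expect_true(all(diff(tox5$exceedance_pct[order(tox5$threshold)]) <= 0))
})

test_that("simulate_pta assembles a reproducible long-format report", {
  sim1 <- simulate_pta(n = 150, seed = 64)
  sim2 <- simulate_pta(n = 150, seed = 64)
  expect_identical(sim1$pta, sim2$pta)
  expect_equal(nrow(sim1$pta), 6 * 13) # 6 regimens x 13 MICs
  expect_setequal(unique(sim1$pta$band),
                  intersect(c("optimal", "intermediate", "poor"),
                            unique(sim1$pta$band)))
  expect_true(all(sim1$pta$pta_pct >= 0 & sim1$pta$pta_pct <= 100))
  expect_equal(nrow(sim1$toxicity), 6 * 3)
  # q8h regimens simulated in the normal cohort, q12h in the severe cohort
  expect_equal(unique(sim1$pta$category[sim1$pta$regimen == "d1"]), "normal")
  expect_equal(unique(sim1$pta$category[sim1$pta$regimen == "d6"]), "severe")
  # patient-order invariance: PTA recomputed from a permuted cohort
  withr::local_seed(65)
  pop <- piperacillin_population()
  pars <- parametric_sample(pop$means, pop$sds, 200)
  crcl <- crcl_to_L_h(runif(200, 90, 129))
  perm <- sample.int(200)
  a <- pta_curve(pars, crcl, standard_dosages()$d2, mics = c(4, 8, 16))
  b <- pta_curve(pars[perm, ], crcl[perm], standard_dosages()$d2,
                 mics = c(4, 8, 16))
  expect_equal(a, b)
})

test_that("semi-parametric population sampling feeds the simulation", {
  pts <- tibble::tibble(
    intercept = c(3.5, 6), slope = c(1.2, 1.6), vc = c(20, 45),
    weight = c(0.6, 0.4)
  )
  dist <- np_distribution(pts, covariance = diag(c(0.5, 0.05, 5)))
  sim <- simulate_pta(population = dist, n = 150, seed = 66,
                      mics = c(0.0625, 8, 256))
  expect_equal(nrow(sim$pta), 6 * 3)
  expect_true(all(is.finite(sim$pta$pta_pct)))
})
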