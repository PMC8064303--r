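# Shared fixtures: everything is generated in code at test time.

# Fast fitting settings for unit tests (small grid, capped cycles).
quick_control <- function(...) {
  args <- list(n_grid = 128, max_cycles = 60, n_explore = 100)
  user <- list(...)
  args[names(user)] <- user
  do.call(npag_control, args)
}

# A random single-event or multi-event schedule with plausible parameters,
# used by the oracle-agreement property tests.
random_case <- function() {
  n_ev <- sample(1:4, 1)
  starts <- sort(runif(n_ev, 0, 24))
  durs <- runif(n_ev, 0.5, 4)
  list(
    schedule = infusion_schedule(starts, durs, runif(n_ev, 1000, 8000),
                                 horizon = 48),
    params = pk_parameters(
      intercept = runif(1, 0.5, 10),
      slope = runif(1, 0.1, 3),
      vc = runif(1, 5, 60)
    ),
    crcl = runif(1, 0.5, 8)
  )
}

# Minimal hand-built long-format dataset: `n` subjects on 4 g q8h (4 h
# infusion), observations simulated noiselessly from `params` unless given.
tiny_dataset <- function(n = 2, params = pk_parameters(5, 1, 25),
                         crcl_ml_min = seq(40, 120, length.out = n),
                         obs_times = c(41, 44, 46, 48), noise_sd = 0) {
  purrr::map_dfr(seq_len(n), function(i) {
    sched <- infusion_schedule(seq(0, 40, by = 8), 4, 4000, horizon = 56)
    conc <- concentration_at(sched, params, crcl_to_L_h(crcl_ml_min[i]),
                             obs_times)
    if (noise_sd > 0) conc <- pmax(conc + rnorm(length(conc), 0, noise_sd), 0)
    dplyr::bind_rows(
      tibble::tibble(
        subject_id = paste0("T", i), event = "dose",
        time_h = seq(0, 40, by = 8), amount_mg = 4000, infusion_h = 4,
        conc_mg_L = NA_real_, lloq_flag = NA
      ),
      tibble::tibble(
        subject_id = paste0("T", i), event = "obs",
        time_h = obs_times, amount_mg = NA_real_, infusion_h = NA_real_,
        conc_mg_L = conc, lloq_flag = conc < 1
      )
    ) |>
      dplyr::mutate(age_y = 60, sex = "male", weight_kg = 75,
                    scr_mg_dL = 1, crcl_mL_min = crcl_ml_min[i])
  })
}

# Wrap a known distribution + subjects into a fit object so diagnostics can
# be tested against hand-computable cases without running the estimator.
fake_fit <- function(dist, data, gamma = 1, error = assay_error(gamma = gamma)) {
  subjects <- pippk:::as_subjects(data)
  structure(list(
    distribution = dist, gamma = error$gamma,
    log_likelihood = NA_real_, cycles = 0L, converged = TRUE,
    trace = tibble::tibble(), error = error, bounds = pk_bounds(),
    control = npag_control(), covariate_model = "crcl",
    subjects = subjects, n_subjects = length(subjects),
    n_obs = sum(vapply(subjects, function(s) length(s$obs_times), 1L))
  ), class = "npag_fit")
}

# uniform simplex draw (Dirichlet(1,...,1))
gtools_rdirichlet <- function(k) {
  g <- rexp(k)
  g / sum(g)
}

point_dist <- function(intercept, slope, vc, covariance = diag(0, 3)) {
  np_distribution(
    tibble::tibble(intercept = intercept, slope = slope, vc = vc, weight = 1),
    covariance = covariance
  )
}
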