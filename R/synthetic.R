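#' Generate a synthetic patient cohort
#'
#' Draws a virtual cohort with the structure of a sparse therapeutic drug
#' monitoring study in non-critically ill adults with Gram-negative
#' bloodstream infection: ages uniform over a late-adult range, weight
#' normal (truncated above 40 kg), sex mostly male, serum creatinine
#' log-normal so that Cockcroft-Gault creatinine clearance spans roughly
#' 15--255 mL/min. True pharmacokinetic parameters come from the supplied
#' population model, and each subject is assigned q8h dosing or, when
#' creatinine clearance is below `q12_below` mL/min, the renally adjusted
#' q12h regimen.
#'
#' @param n Number of subjects.
#' @param population True population: an [np_distribution()] or a
#'   `means`/`sds` list (default [piperacillin_population()]).
#' @param age_range Years, uniform.
#' @param weight_mean,weight_sd,weight_min Weight distribution, kg.
#' @param p_male Probability of male sex.
#' @param scr_meanlog,scr_sdlog Log-normal serum creatinine (mg/dL).
#' @param q12_below Creatinine clearance cut-off (mL/min) below which the
#'   q12h regimen is assigned.
#' @param infusion_h Infusion duration of the assigned maintenance doses, h.
#' @param dose_mg Piperacillin dose per administration, mg.
#' @param seed Optional integer seed.
#' @return A tibble of class `synthetic_cohort`: one row per subject with
#'   covariates, true parameters (`intercept`, `slope`, `vc`), derived
#'   `crcl_mL_min`, and `interval_h` (8 or 12).
#' @export
#' @examples
#' generate_cohort(5, seed = 1)
generate_cohort <- function(n,
                            population = piperacillin_population(),
                            age_range = c(48, 86),
                            weight_mean = 75, weight_sd = 12,
                            weight_min = 40,
                            p_male = 0.63,
                            scr_meanlog = log(1.4), scr_sdlog = 0.6,
                            q12_below = 20,
                            infusion_h = 4, dose_mg = 4000,
                            seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  with_seed_(seed, {
    age <- runif(n, age_range[1], age_range[2])
    weight <- rnorm(n, weight_mean, weight_sd)
    while (any(bad <- weight <= weight_min)) {
      weight[bad] <- rnorm(sum(bad), weight_mean, weight_sd)
    }
    sex <- ifelse(rbinom(n, 1, p_male) == 1, "male", "female")
    scr <- rlnorm(n, scr_meanlog, scr_sdlog)
    crcl <- cockcroft_gault(age, weight, scr, sex)
    params <- draw_population(population, n)
    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age_y = age, sex = sex, weight_kg = weight, scr_mg_dL = scr,
      crcl_mL_min = crcl,
      intercept = params$intercept, slope = params$slope, vc = params$vc,
      interval_h = ifelse(crcl < q12_below, 12, 8),
      infusion_h = infusion_h, dose_mg = dose_mg
    )
    class(out) <- c("synthetic_cohort", class(out))
    out
  })
}

# Maintenance schedule for one subject covering the sampled steady-state
# interval: dosing from t = 0, sampling in the first interval starting at or
# after `ss_after` hours.
subject_schedule <- function(interval_h, infusion_h, dose_mg,
                             ss_after = 40) {
  first_ss <- interval_h * ceiling(ss_after / interval_h)
  starts <- seq(0, first_ss, by = interval_h)
  infusion_schedule(starts, infusion_h, dose_mg,
                    horizon = first_ss + interval_h)
}

#' Simulate a sparse-sampled concentration dataset from a cohort
#'
#' For each subject the noiseless concentration is computed at the design
#' times of a steady-state dosing interval (doses are simulated from t = 0
#' and sampling starts in the first interval beginning at or after
#' `ss_after` hours, several half-lives for typical parameters). Independent
#' normal noise with SD from the assay error model is added, negative values
#' are clamped to zero, and values below the limit of quantification are
#' flagged.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param error An [assay_error()]; its `gamma` scales the simulated noise
#'   (`gamma = 0` is allowed here and yields noiseless data).
#' @param sample_times Hours after the start of the sampled interval's
#'   infusion (default `c(1, 4, 6, 8)`).
#' @param ss_after Earliest start (h) of the sampled interval.
#' @param lloq Lower limit of quantification, mg/L.
#' @param seed Optional integer seed.
#' @return A long-format dataset tibble (the [read_dataset()] schema) with
#'   dose and observation rows for every subject.
#' @export
simulate_dataset <- function(cohort, error = assay_error(),
                             sample_times = c(1, 4, 6, 8),
                             ss_after = 40, lloq = 1, seed = NULL) {
  stopifnot(is.data.frame(cohort))
  with_seed_(seed, {
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      s <- cohort[i, ]
      sched <- subject_schedule(s$interval_h, s$infusion_h, s$dose_mg,
                                ss_after)
      t_last <- max(sched$start_time)
      obs_t <- t_last + sample_times
      params <- s[c("intercept", "slope", "vc")]
      pred <- concentration_at(sched, params, crcl_to_L_h(s$crcl_mL_min),
                               obs_t)
      sd0 <- if (error$gamma == 0) 0 else assay_sd(pred, error)
      obs <- pmax(pred + rnorm(length(pred), 0, sd0), 0)
      cov_cols <- tibble::tibble(
        age_y = s$age_y, sex = s$sex, weight_kg = s$weight_kg,
        scr_mg_dL = s$scr_mg_dL, crcl_mL_min = s$crcl_mL_min
      )
      dose_rows <- tibble::tibble(
        subject_id = s$subject_id, event = "dose",
        time_h = sched$start_time, amount_mg = sched$dose,
        infusion_h = sched$duration, conc_mg_L = NA_real_, lloq_flag = NA
      )
      obs_rows <- tibble::tibble(
        subject_id = s$subject_id, event = "obs",
        time_h = obs_t, amount_mg = NA_real_, infusion_h = NA_real_,
        conc_mg_L = obs, lloq_flag = obs < lloq
      )
      dplyr::bind_cols(dplyr::bind_rows(dose_rows, obs_rows), cov_cols)
    })
  })
}
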