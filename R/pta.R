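#' Pharmacodynamic efficacy target
#'
#' Beta-lactam efficacy is driven by the fraction of the dosing interval
#' during which the unbound drug concentration exceeds the pathogen's MIC
#' (fT>MIC). The default target is the classic piperacillin criterion:
#' unbound concentration above the MIC for at least 50% of the first 24 h,
#' with the unbound fraction fixed at 0.7.
#'
#' @param fraction_threshold Required fraction of the window above MIC,
#'   in (0, 1].
#' @param unbound_fraction Unbound (free) drug fraction, in (0, 1].
#' @param window Evaluation window `[a, b)`, hours.
#' @return A list of class `pd_target`.
#' @export
pd_target <- function(fraction_threshold = 0.5, unbound_fraction = 0.7,
                      window = c(0, 24)) {
  if (fraction_threshold <= 0 || fraction_threshold > 1) {
    abort("`fraction_threshold` must be in (0, 1].")
  }
  if (unbound_fraction <= 0 || unbound_fraction > 1) {
    abort("`unbound_fraction` must be in (0, 1].")
  }
  structure(list(
    fraction_threshold = fraction_threshold,
    unbound_fraction = unbound_fraction,
    window = window
  ), class = "pd_target")
}

#' Doubling-dilution MIC grid
#'
#' Thirteen doubling dilutions from 0.0625 to 256 mg/L, the panel assessed
#' in the target-attainment analysis. EUCAST piperacillin-tazobactam
#' breakpoints annotate the susceptible (<= 8 mg/L) and resistant
#' (> 16 mg/L) ranges.
#'
#' @return A tibble with columns `mic` and `susceptibility`.
#' @export
mic_grid <- function() {
  mic <- 0.0625 * 2^(0:12)
  tibble::tibble(
    mic = mic,
    susceptibility = dplyr::case_when(
      mic <= 8 ~ "S",
      mic <= 16 ~ "I",
      TRUE ~ "R"
    )
  )
}

#' Renal-function simulation scenarios
#'
#' Creatinine-clearance sampling ranges (mL/min, treated as interchangeable
#' with mL/min/1.73 m^2 in the simulation arm) for the simulated cohorts:
#' `normal` covers the KDIGO normal band (90--129); `severe` pools the
#' severely-decreased (15--29) and kidney-failure (< 15) bands into a single
#' 5--29 range, the lower edge avoiding degenerate near-zero clearances.
#'
#' @return A tibble with columns `category`, `crcl_lo`, `crcl_hi` (mL/min).
#' @export
renal_scenarios <- function() {
  tibble::tibble(
    category = c("normal", "severe"),
    crcl_lo = c(90, 5),
    crcl_hi = c(129, 29)
  )
}

#' Toxicodynamic thresholds
#'
#' Published unbound-trough thresholds associated with piperacillin
#' toxicity: neurotoxicity at Cmin > 157.2 mg/L (sensitive threshold) or
#' > 361.4 mg/L, nephrotoxicity at Cmin > 452.65 mg/L; evaluated on the
#' unbound concentration over the second day of therapy (24--48 h).
#'
#' @return A tibble with columns `name` and `threshold` (mg/L).
#' @export
toxicity_thresholds <- function() {
  tibble::tibble(
    name = c("neurotoxicity_low", "neurotoxicity_high", "nephrotoxicity"),
    threshold = c(157.2, 361.4, 452.65)
  )
}

#' Fraction of a window with unbound concentration above MIC
#'
#' Computes fT>MIC for one subject: the exact time with total concentration
#' above `mic / unbound_fraction` (equivalently unbound concentration above
#' the MIC) divided by the window length.
#'
#' @inheritParams concentration_at
#' @param mic MIC, mg/L (> 0).
#' @param target A [pd_target()].
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' sched <- standard_dosages()$d2
#' p <- pk_parameters(4.556, 1.353, 30.68)
#' ft_above_mic(sched, p, crcl_to_L_h(110), mic = 8)
ft_above_mic <- function(schedule, params, crcl_L_h, mic,
                         target = pd_target()) {
  if (any(mic <= 0)) abort("`mic` must be > 0.")
  width <- diff(target$window)
  time_above(schedule, params, crcl_L_h,
             threshold = mic / target$unbound_fraction,
             window = target$window) / width
}

# Shared engine: exposure profile for a whole parameter sample under one
# schedule (same breakpoints for everyone).
cohort_profile <- function(schedule, params, crcl_L_h, include) {
  exposure_profile(schedule, params, crcl_L_h, include = include)
}

#' PTA across a MIC grid for one regimen and cohort
#'
#' For each virtual patient the fraction of the target window with unbound
#' concentration above the MIC is computed analytically; the PTA at a given
#' MIC is the percentage of patients at or above the target fraction.
#'
#' @param params Parameter tibble (`intercept`, `slope`, `vc`), one row per
#'   virtual patient (from [parametric_sample()] or
#'   [semiparametric_sample()]).
#' @param crcl_L_h Creatinine clearance per patient, L/h (recycled).
#' @param schedule An [infusion_schedule()].
#' @param mics MIC values, mg/L (default the doubling-dilution panel).
#' @param target A [pd_target()].
#' @return A tibble with columns `mic`, `pta_pct`, `band`.
#' @export
pta_curve <- function(params, crcl_L_h, schedule, mics = mic_grid()$mic,
                      target = pd_target()) {
  prof <- cohort_profile(schedule, params, crcl_L_h, include = target$window)
  width <- diff(target$window)
  pta <- vapply(mics, function(m) {
    ft <- time_above_profile(prof, m / target$unbound_fraction,
                             target$window) / width
    100 * mean(ft >= target$fraction_threshold)
  }, numeric(1))
  tibble::tibble(mic = mics, pta_pct = pta, band = pta_band(pta))
}

#' Classify a PTA percentage
#'
#' `optimal` for PTA >= 90%, `intermediate` for 50--90% (both boundaries
#' inclusive at the lower edge), `poor` below 50%.
#'
#' @param pta_pct PTA percentage(s) in `[0, 100]`.
#' @return Character vector of band labels.
#' @export
pta_band <- function(pta_pct) {
  dplyr::case_when(
    pta_pct >= 90 ~ "optimal",
    pta_pct >= 50 ~ "intermediate",
    TRUE ~ "poor"
  )
}

#' Probability of exceeding toxicity thresholds
#'
#' Percentage of virtual patients whose minimum unbound concentration over
#' the day-2 window exceeds each threshold.
#'
#' @inheritParams pta_curve
#' @param thresholds Tibble with columns `name`, `threshold` (mg/L, unbound
#'   scale); default [toxicity_thresholds()].
#' @param window Trough-evaluation window, default `c(24, 48)` h.
#' @param unbound_fraction Unbound fraction applied to the total
#'   concentration before comparison.
#' @return A tibble with columns `name`, `threshold`, `exceedance_pct`.
#' @export
toxicity_probability <- function(params, crcl_L_h, schedule,
                                 thresholds = toxicity_thresholds(),
                                 window = c(24, 48),
                                 unbound_fraction = 0.7) {
  prof <- cohort_profile(schedule, params, crcl_L_h, include = window)
  cmin_free <- unbound_fraction * cmin_profile(prof, window)
  tibble::tibble(
    name = thresholds$name,
    threshold = thresholds$threshold,
    exceedance_pct = vapply(
      thresholds$threshold,
      function(thr) 100 * mean(cmin_free > thr),
      numeric(1)
    )
  )
}

#' Monte Carlo target-attainment and toxicity simulation
#'
#' The full simulation pipeline: for each renal scenario, draw `n` virtual
#' patients (pharmacokinetic parameters from the supplied population model,
#' creatinine clearance uniform over the scenario range), and evaluate every
#' regimen against the MIC panel (PTA over the efficacy window) and the
#' toxicity thresholds (unbound trough over the day-2 window). Regimens
#' `d1`--`d3` (q8h) are evaluated against the normal-function cohort and
#' `d4`--`d6` (q12h renal adjustments) against the severe cohort, mirroring
#' how adjusted regimens are prescribed; pass an explicit `pairing` to
#' change this.
#'
#' @param population Either an [np_distribution()] (sampled
#'   semi-parametrically) or a list with `means` and `sds` (log-normal
#'   fallback, default [piperacillin_population()]).
#' @param n Virtual patients per scenario (default 2000).
#' @param regimens Named list of schedules (default [standard_dosages()]).
#' @param scenarios Tibble as [renal_scenarios()].
#' @param pairing Tibble with columns `regimen`, `category` naming which
#'   regimen is simulated in which scenario; default q8h in `normal`, q12h
#'   in `severe`.
#' @param mics MIC panel (mg/L).
#' @param target A [pd_target()].
#' @param thresholds Toxicity thresholds tibble.
#' @param tox_window Day-2 trough window, h.
#' @param seed Integer seed.
#' @return A list of class `pta_simulation` with tibbles `pta` (`regimen`,
#'   `category`, `mic`, `pta_pct`, `band`) and `toxicity` (`regimen`,
#'   `category`, `name`, `threshold`, `exceedance_pct`); both carry `seed`
#'   and `n` attributes.
#' @export
simulate_pta <- function(population = piperacillin_population(), n = 2000,
                         regimens = standard_dosages(),
                         scenarios = renal_scenarios(),
                         pairing = NULL,
                         mics = mic_grid()$mic,
                         target = pd_target(),
                         thresholds = toxicity_thresholds(),
                         tox_window = c(24, 48),
                         seed = NULL) {
  if (n < 100) abort("`n` must be at least 100.")
  pairing <- pairing %||% tibble::tibble(
    regimen = names(regimens),
    category = rep(c("normal", "severe"), each = 3)[seq_along(regimens)]
  )
  with_seed_(seed, {
    cohorts <- purrr::map(seq_len(nrow(scenarios)), function(i) {
      list(
        params = draw_population(population, n),
        crcl_L_h = crcl_to_L_h(
          runif(n, scenarios$crcl_lo[i], scenarios$crcl_hi[i])
        )
      )
    })
    names(cohorts) <- scenarios$category
    pta <- purrr::map_dfr(seq_len(nrow(pairing)), function(i) {
      reg <- pairing$regimen[i]
      cat_ <- pairing$category[i]
      co <- cohorts[[cat_]]
      dplyr::mutate(
        pta_curve(co$params, co$crcl_L_h, regimens[[reg]], mics, target),
        regimen = reg, category = cat_, .before = 1
      )
    })
    tox <- purrr::map_dfr(seq_len(nrow(pairing)), function(i) {
      reg <- pairing$regimen[i]
      cat_ <- pairing$category[i]
      co <- cohorts[[cat_]]
      dplyr::mutate(
        toxicity_probability(co$params, co$crcl_L_h, regimens[[reg]],
                             thresholds, tox_window,
                             target$unbound_fraction),
        regimen = reg, category = cat_, .before = 1
      )
    })
    attr(pta, "seed") <- seed
    attr(pta, "n") <- n
    attr(tox, "seed") <- seed
    attr(tox, "n") <- n
    structure(list(pta = pta, toxicity = tox, n = n, seed = seed),
              class = "pta_simulation")
  })
}

# Draw n parameter vectors from whichever population representation is given.
draw_population <- function(population, n) {
  if (inherits(population, "np_distribution")) {
    semiparametric_sample(population, n)[c("intercept", "slope", "vc")]
  } else if (is.list(population) && all(c("means", "sds") %in%
                                          names(population))) {
    parametric_sample(population$means, population$sds, n)
  } else if (is.data.frame(population)) {
    if (nrow(population) != n) {
      abort("a pre-drawn parameter data frame must have exactly `n` rows.")
    }
    tibble::as_tibble(population)[c("intercept", "slope", "vc")]
  } else {
    abort("`population` must be an np_distribution, a means/sds list, or a parameter data frame.")
  }
}

#' @export
print.pta_simulation <- function(x, ...) {
  cat("<pta_simulation> ", x$n, " virtual patients per cohort",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  print(tidyr::pivot_wider(
    x$pta[c("mic", "regimen", "pta_pct")],
    names_from = "regimen", values_from = "pta_pct"
  ), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pta_simulation <- function(x, ...) x$pta

#' Heatmap of a PTA table
#'
#' @param object A `pta_simulation` result.
#' @param ... Unused.
#' @return A ggplot object: MIC by regimen, tiles coloured by attainment
#'   band and labelled with the PTA percentage.
#' @exportS3Method ggplot2::autoplot
autoplot.pta_simulation <- function(object, ...) {
  d <- object$pta
  d$mic_f <- factor(d$mic, levels = sort(unique(d$mic)))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$regimen, y = .data$mic_f, fill = .data$band
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pta_pct)),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(
      optimal = "#4daf4a", intermediate = "#ffff99", poor = "#e41a1c"
    )) +
    ggplot2::labs(x = "regimen", y = "MIC (mg/L)", fill = "PTA band") +
    ggplot2::theme_minimal()
}

#' Concentration-time profile plot for one or more regimens
#'
#' @param regimens Named list of schedules.
#' @param params Single-row parameter tibble.
#' @param crcl_L_h Creatinine clearance, L/h.
#' @param by Time step of the plotting grid, h.
#' @return A ggplot object of total concentration versus time.
#' @export
plot_regimens <- function(regimens, params, crcl_L_h, by = 0.05) {
  d <- purrr::map_dfr(names(regimens), function(nm) {
    dplyr::mutate(
      concentration_profile(
        regimens[[nm]], params, crcl_L_h,
        times = seq(0, schedule_horizon(regimens[[nm]]), by = by)
      ),
      regimen = nm
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$conc,
                                  colour = .data$regimen)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "total concentration (mg/L)") +
    ggplot2::theme_minimal()
}
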