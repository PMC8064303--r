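#' Subject-level pharmacokinetic parameters
#'
#' The structural model is a one-compartment model with zero-order infusion
#' input, linear elimination, and a renal covariate on clearance:
#' `CL (L/h) = intercept + slope * CrCl (L/h)`, `ke = CL / vc`. One row per
#' (virtual) subject.
#'
#' @param intercept Clearance intercept, L/h, non-negative.
#' @param slope Dimensionless slope of clearance on creatinine clearance
#'   (both in L/h), non-negative.
#' @param vc Central volume of distribution, L, strictly positive.
#' @return A tibble with columns `intercept`, `slope`, `vc`.
#' @export
#' @examples
#' pk_parameters(intercept = 4.556, slope = 1.353, vc = 30.68)
pk_parameters <- function(intercept, slope, vc) {
  out <- tibble::tibble(
    intercept = as.numeric(intercept),
    slope = as.numeric(slope),
    vc = as.numeric(vc)
  )
  if (any(out$intercept < 0) || any(out$slope < 0)) {
    abort("`intercept` and `slope` must be non-negative.")
  }
  if (any(out$vc <= 0)) abort("`vc` must be strictly positive.")
  out
}

#' Piperacillin clearance from the renal covariate model
#'
#' @param params A parameter tibble from [pk_parameters()] (or any data frame
#'   with `intercept` and `slope` columns).
#' @param crcl_L_h Creatinine clearance in L/h (convert mL/min values with
#'   [crcl_to_L_h()]). Recycled against the rows of `params`.
#' @return Clearance in L/h.
#' @export
#' @examples
#' clearance(pk_parameters(3.503, 1.39, 20), crcl_to_L_h(50.7))
clearance <- function(params, crcl_L_h) {
  if (any(crcl_L_h < 0, na.rm = TRUE)) abort("`crcl_L_h` must be >= 0.")
  params$intercept + params$slope * crcl_L_h
}

# Vectorised closed-form profile machinery ------------------------------------
#
# Superposition of zero-order infusion events in a linear one-compartment
# model. For an event with rate R starting at t0 with duration d and
# elimination rate ke = CL/vc:
#   t in (t0, t0+d]: C = (R/CL) (1 - exp(-ke (t - t0)))
#   t > t0+d:        C = (R/CL) (1 - exp(-ke d)) exp(-ke (t - t0 - d))
# Concentrations over multiple events add (linear system).

# Concentration matrix: n parameter sets x length(times).
# params: data frame (intercept, slope, vc); crcl_L_h recycled to n rows.
conc_matrix <- function(schedule, params, crcl_L_h, times) {
  n <- nrow(params)
  crcl_L_h <- rep_len(crcl_L_h, n)
  cl <- params$intercept + params$slope * crcl_L_h
  if (any(cl <= 0)) abort("clearance must be > 0 for every parameter set.")
  ke <- cl / params$vc
  out <- matrix(0, nrow = n, ncol = length(times))
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start_time[i]
    d <- schedule$duration[i]
    r <- schedule$rate[i]
    if (r == 0) next
    for (j in seq_along(times)) {
      t <- times[j]
      if (t <= t0) next
      te <- min(t - t0, d) # infused time
      contrib <- (r / cl) * (1 - exp(-ke * te)) * exp(-ke * pmax(t - t0 - d, 0))
      out[, j] <- out[, j] + contrib
    }
  }
  out
}

# Piecewise-exponential representation of the concentration profile for n
# parameter sets sharing one schedule. Between consecutive event boundaries
# the net infusion rate is constant, so
#   C(t) = plateau + (C(a) - plateau) exp(-ke (t - a)),  plateau = R_active/CL,
# which is monotone on each segment. `include` adds extra breakpoints
# (e.g. analysis-window edges).
exposure_profile <- function(schedule, params, crcl_L_h, include = numeric()) {
  horizon <- schedule_horizon(schedule)
  breaks <- sort(unique(c(
    0, schedule$start_time, schedule$start_time + schedule$duration,
    pmin(include, horizon), horizon
  )))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]
  n <- nrow(params)
  crcl_L_h <- rep_len(crcl_L_h, n)
  cl <- params$intercept + params$slope * crcl_L_h
  ke <- cl / params$vc
  # net active rate on each segment [breaks[k], breaks[k+1])
  mid <- head(breaks, -1) + diff(breaks) / 2
  seg_rate <- vapply(mid, function(t) {
    sum(schedule$rate[schedule$start_time <= t &
                        t < schedule$start_time + schedule$duration])
  }, numeric(1))
  conc <- conc_matrix(schedule, params, crcl_L_h, breaks)
  list(
    breaks = breaks, seg_rate = seg_rate,
    conc = conc, cl = cl, ke = ke
  )
}

# Exact time spent with C > threshold inside [window[1], window[2]), one value
# per parameter set. Each segment is monotone, so it contributes at most one
# threshold crossing, located by a logarithm.
time_above_profile <- function(prof, threshold, window) {
  breaks <- prof$breaks
  n <- nrow(prof$conc)
  total <- numeric(n)
  for (k in seq_along(prof$seg_rate)) {
    a <- breaks[k]
    b <- breaks[k + 1]
    lo <- max(a, window[1])
    hi <- min(b, window[2])
    if (hi <= lo) next
    plateau <- prof$seg_rate[k] / prof$cl
    # concentration at the clipped segment start
    c_lo <- plateau + (prof$conc[, k] - plateau) * exp(-prof$ke * (lo - a))
    c_hi <- plateau + (prof$conc[, k] - plateau) * exp(-prof$ke * (hi - a))
    dt <- hi - lo
    above_lo <- c_lo > threshold
    above_hi <- c_hi > threshold
    seg <- numeric(n)
    seg[above_lo & above_hi] <- dt
    # one crossing: solve plateau + (c_lo - plateau) e^{-ke tau} = threshold
    cross <- xor(above_lo, above_hi)
    if (any(cross)) {
      tau <- log((c_lo[cross] - plateau[cross]) /
                   (threshold - plateau[cross])) / prof$ke[cross]
      tau <- pmin(pmax(tau, 0), dt)
      seg[cross] <- ifelse(above_lo[cross], tau, dt - tau)
    }
    total <- total + seg
  }
  total
}

# Minimum concentration over [window[1], window[2]); segment monotonicity means
# the minimum is attained at a segment boundary or window edge. Requires the
# window edges to be among the profile breaks (pass them via `include`).
cmin_profile <- function(prof, window) {
  keep <- prof$breaks >= window[1] - 1e-12 & prof$breaks <= window[2] + 1e-12
  if (!any(keep)) abort("window outside profile range.")
  apply(prof$conc[, keep, drop = FALSE], 1, min)
}

#' Concentration at given times (closed form)
#'
#' Evaluates the total (bound + unbound) piperacillin concentration under the
#' one-compartment infusion model by analytic superposition of the schedule's
#' events.
#'
#' @param schedule An [infusion_schedule()].
#' @param params A single-row parameter tibble from [pk_parameters()].
#' @param crcl_L_h Creatinine clearance in L/h.
#' @param times Numeric vector of times (h, >= 0).
#' @return Numeric vector of concentrations (mg/L), one per time.
#' @export
#' @examples
#' sched <- infusion_schedule(0, 4, 4000)
#' p <- pk_parameters(10, 0, 20)
#' concentration_at(sched, p, 0, c(0, 4, 6))
concentration_at <- function(schedule, params, crcl_L_h, times) {
  if (nrow(params) != 1L) abort("`params` must have exactly one row.")
  if (any(times < 0)) abort("`times` must be >= 0.")
  drop(conc_matrix(schedule, params, crcl_L_h, times))
}

#' Concentration profile as a tidy tibble
#'
#' @inheritParams concentration_at
#' @param times Evaluation grid in hours; defaults to a 0.1-h grid over the
#'   schedule horizon.
#' @return A tibble with columns `time` (h) and `conc` (mg/L).
#' @export
concentration_profile <- function(schedule, params, crcl_L_h,
                                  times = NULL) {
  times <- times %||% seq(0, schedule_horizon(schedule), by = 0.1)
  tibble::tibble(
    time = times,
    conc = concentration_at(schedule, params, crcl_L_h, times)
  )
}

#' Numerically integrated concentration profile (test oracle)
#'
#' Integrates the amount-space differential equation
#' `dX/dt = R(t) - (CL/vc) X`, `C = X/vc`, with `R(t)` the summed active
#' infusion rates, using `deSolve::lsoda` segment by segment. This exists as
#' an independent check of the closed-form engine and is not used by the
#' analysis functions.
#'
#' @inheritParams concentration_at
#' @param times Strictly increasing evaluation grid (h).
#' @return A tibble with columns `time` and `conc`.
#' @export
ode_profile <- function(schedule, params, crcl_L_h, times) {
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    abort("`ode_profile()` requires the deSolve package.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  cl <- clearance(params, crcl_L_h)
  ke <- cl / params$vc
  rate_at <- function(t) {
    sum(schedule$rate[schedule$start_time <= t &
                        t < schedule$start_time + schedule$duration])
  }
  bounds <- sort(unique(c(
    0, schedule$start_time, schedule$start_time + schedule$duration,
    times
  )))
  bounds <- bounds[bounds >= 0 & bounds <= max(times)]
  x <- 0
  amounts <- numeric(length(times))
  if (any(times == 0)) amounts[times == 0] <- 0
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]
    b <- bounds[k + 1]
    r <- rate_at((a + b) / 2)
    sol <- deSolve::lsoda(
      y = c(X = unname(x)), times = c(a, b),
      func = function(t, y, parms) list(r - ke * y[1]),
      rtol = 1e-12, atol = 1e-12
    )
    x <- unname(sol[nrow(sol), "X"])
    hit <- which(abs(times - b) < 1e-12)
    if (length(hit)) amounts[hit] <- x
  }
  tibble::tibble(time = times, conc = amounts / params$vc)
}

#' Time above a concentration threshold
#'
#' Exact cumulative time within a window during which the total concentration
#' exceeds `threshold`, computed analytically from the piecewise-exponential
#' profile (each inter-event segment is monotone, so crossings are found by a
#' logarithm rather than a grid search).
#'
#' @inheritParams concentration_at
#' @param threshold Total-concentration threshold, mg/L (pre-scale MIC
#'   thresholds by the unbound fraction upstream; see [ft_above_mic()]).
#' @param window Half-open analysis window `[a, b)` in hours, within the
#'   schedule horizon.
#' @return Time above threshold in hours.
#' @export
#' @examples
#' sched <- infusion_schedule(0, 4, 4000)
#' p <- pk_parameters(10, 0, 20)
#' time_above(sched, p, 0, threshold = 40, window = c(0, 24))
time_above <- function(schedule, params, crcl_L_h, threshold,
                       window = c(0, schedule_horizon(schedule))) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  check_window(window, schedule)
  prof <- exposure_profile(schedule, params, crcl_L_h, include = window)
  time_above_profile(prof, threshold, window)
}

#' Minimum concentration in a window
#'
#' Minimum total concentration over a half-open window, evaluated exactly at
#' segment boundaries and window edges (the profile is piecewise monotone).
#' Used with a 24--48 h window for day-2 trough-based toxicity analysis.
#'
#' @inheritParams time_above
#' @return Minimum concentration (mg/L) in the window.
#' @export
cmin_in_window <- function(schedule, params, crcl_L_h,
                           window = c(24, 48)) {
  check_window(window, schedule)
  prof <- exposure_profile(schedule, params, crcl_L_h, include = window)
  cmin_profile(prof, window)
}

check_window <- function(window, schedule) {
  if (length(window) != 2L || window[1] < 0 ||
      window[2] > schedule_horizon(schedule) + 1e-9 ||
      window[1] >= window[2]) {
    abort("`window` must be [a, b) with 0 <= a < b <= horizon.")
  }
  invisible(window)
}
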