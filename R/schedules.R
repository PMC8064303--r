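#' Build an infusion schedule
#'
#' An infusion schedule is a tibble of timed zero-order (constant-rate)
#' infusion events, the input side of the one-compartment model. Overlapping
#' events are allowed; their rates add, which is how loading-dose regimens
#' (a short infusion immediately followed by an extended one) are expressed.
#'
#' @param start_time Numeric vector, hours from the start of therapy at which
#'   each infusion begins. Must be non-negative.
#' @param duration Numeric vector (recycled), infusion duration in hours,
#'   strictly positive.
#' @param dose Numeric vector (recycled), dose per event in mg.
#' @param horizon Simulation end in hours; every event must finish at or
#'   before it. Default 48 h, covering both the efficacy window (first 24 h)
#'   and the day-2 toxicity window (24--48 h).
#' @return A tibble of class `infusion_schedule` with columns
#'   `start_time`, `duration`, `dose`, `rate` (mg/h) and a `horizon`
#'   attribute, sorted by `start_time`.
#' @export
#' @examples
#' # 4 g over 4 h every 8 h, three doses
#' infusion_schedule(c(0, 8, 16), duration = 4, dose = 4000)
infusion_schedule <- function(start_time, duration, dose, horizon = 48) {
  n <- length(start_time)
  duration <- rep_len(duration, n)
  dose <- rep_len(dose, n)
  if (any(start_time < 0)) abort("`start_time` must be >= 0.")
  if (any(duration <= 0)) abort("`duration` must be > 0.")
  if (any(dose < 0)) abort("`dose` must be >= 0.")
  if (any(start_time + duration > horizon + 1e-9)) {
    abort("every infusion must end at or before `horizon`.")
  }
  out <- tibble::tibble(
    start_time = as.numeric(start_time),
    duration = as.numeric(duration),
    dose = as.numeric(dose),
    rate = as.numeric(dose) / as.numeric(duration)
  )
  out <- out[order(out$start_time), , drop = FALSE]
  attr(out, "horizon") <- as.numeric(horizon)
  class(out) <- c("infusion_schedule", class(tibble::tibble()))
  out
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat("<infusion_schedule> ", nrow(x), " event(s), horizon ",
      schedule_horizon(x), " h, total dose ", sum(x$dose) / 1000, " g\n",
      sep = "")
  NextMethod()
}

#' Horizon of an infusion schedule
#'
#' @param schedule An [infusion_schedule()].
#' @return The simulation horizon in hours.
#' @export
schedule_horizon <- function(schedule) {
  h <- attr(schedule, "horizon")
  if (is.null(h)) max(schedule$start_time + schedule$duration) else h
}

#' Standard piperacillin dosage regimens
#'
#' The six intermittent, extended-infusion and loading-dose regimens of 4 g
#' piperacillin evaluated in the target-attainment analysis:
#'
#' * `d1`: 4 g / 0.5 h infusion q8h
#' * `d2`: 4 g / 4 h infusion q8h
#' * `d3`: loading 4 g / 0.5 h at t = 0 plus 4 g / 4 h starting at t = 0.5 h,
#'   then 4 g / 4 h q8h from t = 8 h
#' * `d4`--`d6`: the same three patterns given q12h (renal dose adjustment)
#'
#' @param horizon Simulation horizon in hours (default 48).
#' @return A named list of six [infusion_schedule()] objects.
#' @export
#' @examples
#' standard_dosages()$d3
standard_dosages <- function(horizon = 48) {
  q8 <- seq(0, horizon - 8, by = 8)
  q12 <- seq(0, horizon - 12, by = 12)
  list(
    d1 = infusion_schedule(q8, duration = 0.5, dose = 4000, horizon = horizon),
    d2 = infusion_schedule(q8, duration = 4, dose = 4000, horizon = horizon),
    d3 = infusion_schedule(
      c(0, 0.5, q8[-1]),
      duration = c(0.5, rep(4, length(q8))),
      dose = 4000, horizon = horizon
    ),
    d4 = infusion_schedule(q12, duration = 0.5, dose = 4000, horizon = horizon),
    d5 = infusion_schedule(q12, duration = 4, dose = 4000, horizon = horizon),
    d6 = infusion_schedule(
      c(0, 0.5, q12[-1]),
      duration = c(0.5, rep(4, length(q12))),
      dose = 4000, horizon = horizon
    )
  )
}
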