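#' Assay error model
#'
#' One-standard-deviation assay error as a linear polynomial in the
#' concentration, inflated by a process-noise multiplier:
#' `SD (mg/L) = gamma * (c0 + c1 * C)`. The default coefficients are those of
#' the validated piperacillin HPLC assay (c0 = 0.4388 mg/L, c1 = 0.027);
#' `gamma` absorbs model and process noise beyond pure assay variance and is
#' re-estimated during fitting.
#'
#' @param c0 Additive SD coefficient, mg/L.
#' @param c1 Proportional SD coefficient, dimensionless.
#' @param gamma Process-noise multiplier (>= 0; zero only meaningful for
#'   noiseless simulation, not for likelihood evaluation).
#' @return An object of class `assay_error`.
#' @export
#' @examples
#' assay_sd(c(0, 100), assay_error())
assay_error <- function(c0 = 0.4388, c1 = 0.027, gamma = 1) {
  if (c0 < 0 || c1 < 0 || gamma < 0) {
    abort("`c0`, `c1` and `gamma` must be >= 0.")
  }
  structure(list(c0 = c0, c1 = c1, gamma = gamma), class = "assay_error")
}

#' @rdname assay_error
#' @param conc Concentration(s), mg/L (>= 0).
#' @param error An `assay_error` object.
#' @export
assay_sd <- function(conc, error = assay_error()) {
  if (any(conc < 0)) abort("`conc` must be >= 0.")
  error$gamma * (error$c0 + error$c1 * conc)
}

#' Parameter search box for nonparametric estimation
#'
#' @param intercept,slope,vc Length-2 numeric `(low, high)` ranges. The
#'   defaults are generous boxes around the published piperacillin
#'   population estimates.
#' @return A named list of ranges, class `pk_bounds`.
#' @export
pk_bounds <- function(intercept = c(0.01, 50), slope = c(0.001, 10),
                      vc = c(1, 200)) {
  b <- list(intercept = intercept, slope = slope, vc = vc)
  for (nm in names(b)) {
    r <- b[[nm]]
    if (length(r) != 2 || r[1] < 0 || r[1] >= r[2]) {
      abort(paste0("`", nm, "` bounds must satisfy 0 <= low < high."))
    }
  }
  structure(b, class = "pk_bounds")
}

#' Control settings for [npag_fit()]
#'
#' @param n_grid Initial number of quasi-random support-point candidates
#'   (Latin hypercube over the bounds box).
#' @param max_cycles Cycle cap; exceeding it returns `converged = FALSE`.
#' @param ll_tol Convergence tolerance on the cycle-to-cycle log-likelihood
#'   improvement, applied at the minimum perturbation size.
#' @param delta_init,delta_min Adaptive-grid perturbation size as a fraction
#'   of each parameter range; starts at `delta_init` and halves down to
#'   `delta_min` whenever a cycle fails to improve by `ll_tol`.
#' @param seed Integer seed for the initial grid.
#' @param estimate_gamma Re-estimate the assay-noise multiplier each cycle by
#'   one-dimensional likelihood maximisation?
#' @param gamma_bounds Search interval for `gamma`.
#' @param lloq_policy `"exclude"` drops observations flagged below the limit
#'   of quantification from the likelihood; `"half"` substitutes LLOQ/2.
#' @param lloq Lower limit of quantification, mg/L.
#' @param em_tol,em_max_iter Convergence tolerance and iteration cap of the
#'   multiplicative (EM) updates in the convex weight sub-problem.
#' @param prune_tol Support points with weight below `prune_tol * max(w)`
#'   are dropped.
#' @param n_explore Fresh quasi-random candidate points screened each cycle
#'   by their mixture directional derivative (points that would raise the
#'   likelihood are added to the grid); 0 disables exploration.
#' @param seed_individual Also seed the grid with each subject's individual
#'   maximum-likelihood parameter vector (a box-constrained quasi-Newton
#'   polish from a few starts)? The nonparametric optimum concentrates near
#'   these points, so seeding them sharply improves convergence.
#' @return A list of class `npag_control`.
#' @export
npag_control <- function(n_grid = 2048, max_cycles = 200, ll_tol = 1e-4,
                         delta_init = 0.2, delta_min = 0.001,
                         seed = 20210348, estimate_gamma = TRUE,
                         gamma_bounds = c(0.1, 10),
                         lloq_policy = c("exclude", "half"), lloq = 1,
                         em_tol = 1e-10, em_max_iter = 10000,
                         prune_tol = 1e-6, n_explore = 200,
                         seed_individual = TRUE) {
  structure(list(
    n_grid = n_grid, max_cycles = max_cycles, ll_tol = ll_tol,
    delta_init = delta_init, delta_min = delta_min, seed = seed,
    estimate_gamma = estimate_gamma, gamma_bounds = gamma_bounds,
    lloq_policy = match.arg(lloq_policy), lloq = lloq,
    em_tol = em_tol, em_max_iter = em_max_iter, prune_tol = prune_tol,
    n_explore = n_explore, seed_individual = seed_individual
  ), class = "npag_control")
}

# Long-format dataset -> list of per-subject structures ----------------------

as_subjects <- function(data, lloq_policy = "exclude", lloq = 1) {
  data <- validate_dataset(data)
  split_rows <- split(seq_len(nrow(data)), data$subject_id)
  purrr::map(split_rows, function(idx) {
    d <- data[idx, ]
    doses <- d[d$event == "dose", ]
    obs <- d[d$event == "obs", ]
    if (nrow(obs) && nrow(doses) &&
        min(obs$time_h) < min(doses$time_h)) {
      warn(paste0("subject ", d$subject_id[1],
                  ": observation precedes first dose (pre-dose baseline)."))
    }
    horizon <- max(c(doses$time_h + doses$infusion_h, obs$time_h, 48))
    schedule <- infusion_schedule(
      doses$time_h, doses$infusion_h, doses$amount_mg, horizon = horizon
    )
    below <- as.logical(obs$lloq_flag) | obs$conc_mg_L < lloq
    if (lloq_policy == "exclude") {
      obs_use <- obs[!below, ]
      conc <- obs_use$conc_mg_L
      times <- obs_use$time_h
    } else {
      conc <- ifelse(below, lloq / 2, obs$conc_mg_L)
      times <- obs$time_h
    }
    list(
      subject_id = d$subject_id[1],
      schedule = schedule,
      obs_times = times,
      obs_conc = conc,
      n_below_lloq = sum(below),
      crcl_L_h = crcl_to_L_h(d$crcl_mL_min[1]),
      covariates = d[1, intersect(
        c("age_y", "sex", "weight_kg", "scr_mg_dL", "crcl_mL_min"),
        names(d)
      )]
    )
  })
}

#' Log-likelihood of one subject's observations
#'
#' Gaussian observation model: each measured concentration is the model
#' prediction plus independent noise with SD given by the assay error model
#' evaluated at the prediction.
#'
#' @param subject A subject structure as produced internally from the
#'   long-format dataset (see [read_dataset()]); lists `schedule`,
#'   `obs_times`, `obs_conc`, `crcl_L_h`.
#' @param params Single-row parameter tibble ([pk_parameters()]).
#' @param error An [assay_error()].
#' @return Total log-likelihood over the subject's observations.
#' @export
subject_loglik <- function(subject, params, error = assay_error()) {
  pred <- drop(conc_matrix(subject$schedule, params, subject$crcl_L_h,
                           subject$obs_times))
  sdv <- assay_sd(pred, error)
  if (any(sdv <= 0)) abort("assay SD must be > 0 at every prediction.")
  sum(dnorm(subject$obs_conc, mean = pred, sd = sdv, log = TRUE))
}

# Gamma-separable likelihood pieces: with sd = gamma * sd0(pred),
#   logL_ij(gamma) = -sum_k log sd0 - K_i log gamma - K_i/2 log(2*pi)
#                    - sse_ij / (2 gamma^2),
# so the matrix can be re-evaluated at any gamma without re-predicting.
likelihood_parts <- function(subjects, grid, error) {
  base <- assay_error(error$c0, error$c1, gamma = 1)
  n <- length(subjects)
  m <- nrow(grid)
  sum_log_sd0 <- matrix(0, n, m)
  sse <- matrix(0, n, m)
  nobs <- integer(n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    nobs[i] <- length(s$obs_times)
    if (nobs[i] == 0) next
    pred <- conc_matrix(s$schedule, grid, s$crcl_L_h, s$obs_times) # m x k
    sd0 <- base$c0 + base$c1 * pred
    res <- sweep(pred, 2, s$obs_conc)
    sum_log_sd0[i, ] <- rowSums(log(sd0))
    sse[i, ] <- rowSums((res / sd0)^2)
  }
  list(sum_log_sd0 = sum_log_sd0, sse = sse, nobs = nobs)
}

loglik_from_parts <- function(parts, gamma) {
  -parts$sum_log_sd0 - parts$nobs * log(gamma) -
    parts$nobs / 2 * log(2 * pi) - parts$sse / (2 * gamma^2)
}

#' Convex weight sub-problem of nonparametric estimation
#'
#' Given the matrix of per-subject likelihoods at each candidate support
#' point, finds the probability weights on the simplex maximising the total
#' log-likelihood `sum_i log sum_j w_j L_ij` by multiplicative (EM) updates
#' `w_j <- w_j * mean_i (L_ij / sum_k w_k L_ik)`, iterated until the
#' objective improves by less than `tol`.
#'
#' @param L Numeric matrix (subjects x points) of non-negative finite
#'   likelihoods; no row may be entirely zero.
#' @param w_init Optional starting weights (defaults to uniform).
#' @param tol,max_iter EM stopping rule.
#' @return A list with `weights` (simplex vector) and `objective` (maximised
#'   total log-likelihood).
#' @export
solve_weights <- function(L, w_init = NULL, tol = 1e-10, max_iter = 2000) {
  L <- as.matrix(L)
  if (any(!is.finite(L)) || any(L < 0)) {
    abort("`L` must be finite and non-negative.")
  }
  row_max <- apply(L, 1, max)
  if (any(row_max == 0)) {
    abort("some subject has zero likelihood at every support point (data/model mismatch).")
  }
  Ln <- L / row_max
  w <- w_init %||% rep(1 / ncol(L), ncol(L))
  w <- pmax(w, 0)
  w <- w / sum(w)
  obj <- function(w) sum(log(Ln %*% w)) + sum(log(row_max))
  cur <- obj(w)
  for (it in seq_len(max_iter)) {
    ybar <- drop(Ln %*% w)
    w <- w * colMeans(Ln / ybar)
    w <- w / sum(w)
    new <- obj(w)
    if (new - cur < tol) {
      cur <- new
      break
    }
    cur <- new
  }
  list(weights = w, objective = cur)
}

# Same problem from a log-likelihood matrix (stable for tiny densities).
solve_weights_log <- function(logL, w_init = NULL, tol = 1e-10,
                              max_iter = 2000) {
  row_max <- apply(logL, 1, max)
  if (any(!is.finite(row_max))) {
    abort("some subject has zero likelihood at every support point (data/model mismatch).")
  }
  Ln <- exp(logL - row_max)
  res <- solve_weights(Ln, w_init = w_init, tol = tol, max_iter = max_iter)
  res$objective <- res$objective + sum(row_max) - sum(log(apply(Ln, 1, max)))
  res
}

# Latin-hypercube initial grid over the bounds box.
initial_grid <- function(bounds, n_grid, free, seed) {
  with_seed_(seed, {
    u <- lhs::randomLHS(n_grid, length(free))
    grid <- tibble::tibble(
      intercept = 0, slope = 0, vc = 0, .rows = n_grid
    )
    for (j in seq_along(free)) {
      r <- bounds[[free[j]]]
      grid[[free[j]]] <- r[1] + u[, j] * (r[2] - r[1])
    }
    grid
  })
}

# Box-constrained individual ML estimate per subject; the population optimum
# concentrates near these points, so they make strong grid candidates.
individual_optima <- function(subjects, bounds, free, error) {
  lo <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  hi <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  starts <- list(
    (lo + hi) / 2,
    lo + 0.1 * (hi - lo),
    exp((log(pmax(lo, 1e-6)) + log(hi)) / 2) # geometric midpoint
  )
  purrr::map_dfr(subjects, function(s) {
    if (length(s$obs_times) == 0) return(NULL)
    f <- function(x) {
      p <- tibble::tibble(intercept = 0, slope = 0, vc = 1)
      p[free] <- as.list(x)
      -subject_loglik(s, p, error)
    }
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::nlminb(st, f, lower = lo, upper = hi),
        error = function(e) NULL
      )
      if (!is.null(opt) &&
          (is.null(best) || opt$objective < best$objective)) {
        best <- opt
      }
    }
    if (is.null(best)) return(NULL)
    p <- tibble::tibble(intercept = 0, slope = 0, vc = 1)
    p[free] <- as.list(best$par)
    p
  })
}

# Directional (gradient) screening: candidate j improves the current mixture
# iff d_j = mean_i L_ij / ybar_i > 1.
screen_candidates <- function(cand_parts, gamma, log_ybar) {
  logL <- loglik_from_parts(cand_parts, gamma)
  d <- colMeans(exp(logL - log_ybar)) # recycles log_ybar down columns
  d > 1 + 1e-9
}

perturb_grid <- function(points, bounds, free, delta) {
  cand <- list()
  for (nm in free) {
    r <- bounds[[nm]]
    step <- delta * (r[2] - r[1])
    for (sgn in c(-1, 1)) {
      p <- points
      p[[nm]] <- pmin(pmax(p[[nm]] + sgn * step, r[1]), r[2])
      cand[[length(cand) + 1]] <- p
    }
  }
  cand <- dplyr::distinct(dplyr::bind_rows(cand))
  dplyr::anti_join(cand, points, by = free)
}

#' Nonparametric adaptive-grid population fit
#'
#' Estimates the nonparametric maximum-likelihood population distribution of
#' `(intercept, slope, vc)` — a set of weighted support points — from sparse
#' concentration data, in the spirit of the nonparametric adaptive grid
#' (NPAG) algorithm. Starting from a Latin-hypercube grid over the search
#' box, the fit alternates (i) the convex weight sub-problem
#' ([solve_weights()]), (ii) pruning of negligible-weight points, (iii) local
#' refinement of each surviving point by per-dimension perturbations whose
#' size shrinks from 20% to 0.1% of the range, keeping only proposals that
#' raise the total log-likelihood, and (iv) one-dimensional re-estimation of
#' the assay noise multiplier `gamma`. The reported log-likelihood is
#' non-decreasing across cycles by construction.
#'
#' @param data Long-format dosing/observation data frame (see
#'   [read_dataset()] for the schema), at least two subjects.
#' @param bounds A [pk_bounds()] search box.
#' @param error An [assay_error()]; its `gamma` is the starting value when
#'   `control$estimate_gamma` is `TRUE`.
#' @param control An [npag_control()].
#' @param covariate_model `"crcl"` fits the renal covariate on clearance
#'   (`CL = intercept + slope * CrCl`); `"none"` fixes `slope = 0`
#'   (clearance independent of renal function), for covariate screening.
#' @return An object of class `npag_fit`: a list with `distribution`
#'   ([np_distribution()]), `gamma`, `log_likelihood`, `cycles`, `converged`,
#'   `trace` (per-cycle tibble), plus the inputs needed by the diagnostics.
#' @seealso [covariate_screen()], [posterior_estimates()], [predictions()]
#' @export
npag_fit <- function(data, bounds = pk_bounds(), error = assay_error(),
                     control = npag_control(),
                     covariate_model = c("crcl", "none")) {
  covariate_model <- match.arg(covariate_model)
  subjects <- as_subjects(data, control$lloq_policy, control$lloq)
  if (length(subjects) < 2) abort("need at least two subjects.")
  free <- if (covariate_model == "crcl") {
    c("intercept", "slope", "vc")
  } else {
    c("intercept", "vc")
  }

  with_seed_(control$seed, {
  grid <- initial_grid(bounds, control$n_grid, free, seed = NULL)
  if (isTRUE(control$seed_individual)) {
    grid <- dplyr::distinct(dplyr::bind_rows(
      grid, individual_optima(subjects, bounds, free, error)
    ))
  }
  gamma <- error$gamma
  parts <- likelihood_parts(subjects, grid, error)
  sw <- solve_weights_log(loglik_from_parts(parts, gamma),
                          tol = control$em_tol,
                          max_iter = control$em_max_iter)
  keep <- sw$weights >= control$prune_tol * max(sw$weights)
  grid <- grid[keep, , drop = FALSE]
  parts <- lapply(parts, function(x) if (is.matrix(x)) x[, keep, drop = FALSE] else x)
  w <- sw$weights[keep] / sum(sw$weights[keep])
  obj <- solve_weights_log(loglik_from_parts(parts, gamma), w_init = w,
                           tol = control$em_tol,
                           max_iter = control$em_max_iter)
  w <- obj$weights
  cur_obj <- obj$objective

  delta <- control$delta_init
  trace <- list()
  converged <- FALSE
  cycle <- 0
  while (cycle < control$max_cycles) {
    cycle <- cycle + 1
    prev_obj <- cur_obj

    # (iv) gamma re-estimation at fixed support/weights
    if (control$estimate_gamma) {
      f <- function(g) {
        logL <- loglik_from_parts(parts, g)
        rm_ <- apply(logL, 1, max)
        sum(log(exp(logL - rm_) %*% w)) + sum(rm_)
      }
      opt <- optimize(f, interval = control$gamma_bounds, maximum = TRUE,
                      tol = 1e-6)
      if (opt$objective > cur_obj) {
        gamma <- opt$maximum
        cur_obj <- opt$objective
      }
    }

    # (i) weights at current gamma
    sw <- solve_weights_log(loglik_from_parts(parts, gamma), w_init = w,
                            tol = control$em_tol,
                            max_iter = control$em_max_iter)
    if (sw$objective >= cur_obj) {
      w <- sw$weights
      cur_obj <- sw$objective
    }

    # (ii) prune
    keep <- w >= control$prune_tol * max(w)
    if (!all(keep)) {
      grid <- grid[keep, , drop = FALSE]
      parts <- lapply(parts, function(x) {
        if (is.matrix(x)) x[, keep, drop = FALSE] else x
      })
      w <- w[keep] / sum(w[keep])
    }

    # (iii) adaptive refinement: perturbed copies of surviving points, plus
    # fresh exploratory candidates passing the directional-derivative screen
    cand <- perturb_grid(grid, bounds, free, delta)
    cand_parts <- if (nrow(cand)) {
      likelihood_parts(subjects, cand, error)
    } else {
      NULL
    }
    if (control$n_explore > 0) {
      exp_grid <- initial_grid(bounds, control$n_explore, free, seed = NULL)
      exp_parts <- likelihood_parts(subjects, exp_grid, error)
      logL_cur <- loglik_from_parts(parts, gamma)
      rm_ <- apply(logL_cur, 1, max)
      log_ybar <- log(drop(exp(logL_cur - rm_) %*% w)) + rm_
      keep_c <- screen_candidates(exp_parts, gamma, log_ybar)
      if (any(keep_c)) {
        cand <- dplyr::bind_rows(cand, exp_grid[keep_c, , drop = FALSE])
        exp_kept <- lapply(exp_parts, function(x) {
          if (is.matrix(x)) x[, keep_c, drop = FALSE] else x
        })
        cand_parts <- if (is.null(cand_parts)) {
          exp_kept
        } else {
          list(
            sum_log_sd0 = cbind(cand_parts$sum_log_sd0,
                                exp_kept$sum_log_sd0),
            sse = cbind(cand_parts$sse, exp_kept$sse),
            nobs = cand_parts$nobs
          )
        }
      }
    }
    if (nrow(cand)) {
      all_parts <- list(
        sum_log_sd0 = cbind(parts$sum_log_sd0, cand_parts$sum_log_sd0),
        sse = cbind(parts$sse, cand_parts$sse),
        nobs = parts$nobs
      )
      eps <- 1e-3
      w_init <- c(w * (1 - eps), rep(eps / nrow(cand), nrow(cand)))
      sw <- solve_weights_log(loglik_from_parts(all_parts, gamma),
                              w_init = w_init, tol = control$em_tol,
                              max_iter = control$em_max_iter)
      if (sw$objective > cur_obj) {
        grid <- dplyr::bind_rows(grid, cand)
        parts <- all_parts
        w <- sw$weights
        cur_obj <- sw$objective
        keep <- w >= control$prune_tol * max(w)
        grid <- grid[keep, , drop = FALSE]
        parts <- lapply(parts, function(x) {
          if (is.matrix(x)) x[, keep, drop = FALSE] else x
        })
        w <- w[keep] / sum(w[keep])
      }
    }

    trace[[cycle]] <- tibble::tibble(
      cycle = cycle, log_likelihood = cur_obj, n_support = nrow(grid),
      gamma = gamma, delta = delta
    )

    if (cur_obj - prev_obj < control$ll_tol) {
      if (delta <= control$delta_min) {
        converged <- TRUE
        break
      }
      delta <- max(delta / 2, control$delta_min)
    }
  }
  if (!converged) {
    warn("npag_fit did not converge within `max_cycles` cycles.")
  }

  points <- grid
  points$weight <- w
  dist <- np_distribution(points)
  structure(list(
    distribution = dist,
    gamma = gamma,
    log_likelihood = cur_obj,
    cycles = cycle,
    converged = converged,
    trace = dplyr::bind_rows(trace),
    error = assay_error(error$c0, error$c1, gamma),
    bounds = bounds,
    control = control,
    covariate_model = covariate_model,
    subjects = subjects,
    n_subjects = length(subjects),
    n_obs = sum(vapply(subjects, function(s) length(s$obs_times), 1L))
  ), class = "npag_fit")
  }) # with_seed_
}

#' @export
print.npag_fit <- function(x, ...) {
  cat("Nonparametric population PK fit\n")
  cat("  subjects: ", x$n_subjects, ", observations: ", x$n_obs, "\n", sep = "")
  cat("  support points: ", nrow(x$distribution$points),
      ", gamma: ", signif(x$gamma, 4), "\n", sep = "")
  cat("  log-likelihood: ", signif(x$log_likelihood, 8),
      " (", x$cycles, " cycles, converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.npag_fit <- function(x, ...) x$distribution$points

#' @exportS3Method generics::glance
glance.npag_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    n_support = nrow(x$distribution$points),
    log_likelihood = x$log_likelihood,
    gamma = x$gamma,
    cycles = x$cycles,
    converged = x$converged
  )
}

#' @export
logLik.npag_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = 4 * nrow(object$distribution$points) - 1,
            class = "logLik")
}

#' Individual (posterior) parameter estimates
#'
#' Bayesian step of the nonparametric analysis: for each subject, the prior
#' support-point weights are multiplied by the subject's likelihood at each
#' point and renormalised; the posterior mean parameter vector is returned.
#'
#' @param fit An [npag_fit()] result.
#' @param data Optional long-format dataset; defaults to the fitting data.
#' @return A tibble with one row per subject: `subject_id`, posterior-mean
#'   `intercept`, `slope`, `vc`, and `cl` at the subject's own creatinine
#'   clearance.
#' @export
posterior_estimates <- function(fit, data = NULL) {
  subjects <- if (is.null(data)) {
    fit$subjects
  } else {
    as_subjects(data, fit$control$lloq_policy, fit$control$lloq)
  }
  pts <- fit$distribution$points
  grid <- pts[c("intercept", "slope", "vc")]
  purrr::map_dfr(subjects, function(s) {
    post <- posterior_weights(s, grid, pts$weight, fit$error)
    mu <- colSums(as.matrix(grid) * post)
    tibble::tibble(
      subject_id = s$subject_id,
      intercept = mu[["intercept"]], slope = mu[["slope"]], vc = mu[["vc"]],
      cl = mu[["intercept"]] + mu[["slope"]] * s$crcl_L_h
    )
  })
}

posterior_weights <- function(subject, grid, prior_w, error) {
  if (length(subject$obs_times) == 0) return(prior_w)
  parts <- likelihood_parts(list(subject), grid, error)
  logL <- drop(loglik_from_parts(parts, error$gamma))
  lw <- log(prior_w) + logL
  lw <- lw - max(lw)
  w <- exp(lw)
  if (sum(w) == 0 || !all(is.finite(w))) {
    abort("zero posterior mass: data/model mismatch.")
  }
  w / sum(w)
}

#' Covariate forward-inclusion screen for renal function on clearance
#'
#' Fits the population model twice — with clearance linear in creatinine
#' clearance and with clearance constant (`slope = 0`) — and returns twice
#' the difference in maximised log-likelihood. Large positive values favour
#' keeping the renal covariate; the accept/reject threshold is left to the
#' analyst.
#'
#' @inheritParams npag_fit
#' @return A list with `delta_ll` (2 * (LL_covariate - LL_reduced)), and the
#'   two fits (`fit_covariate`, `fit_reduced`).
#' @export
covariate_screen <- function(data, bounds = pk_bounds(),
                             error = assay_error(),
                             control = npag_control()) {
  fit_cov <- npag_fit(data, bounds, error, control, covariate_model = "crcl")
  fit_red <- npag_fit(data, bounds, error, control, covariate_model = "none")
  if (!fit_cov$converged || !fit_red$converged) {
    warn("covariate_screen: at least one fit did not converge.")
  }
  list(
    delta_ll = 2 * (fit_cov$log_likelihood - fit_red$log_likelihood),
    fit_covariate = fit_cov,
    fit_reduced = fit_red
  )
}
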