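#' Population and individual predictions
#'
#' For every observation, the population prediction is the prior-weighted
#' mean of the predictions at each support point, and the individual
#' prediction is the prediction at the subject's posterior-mean parameters
#' (the Bayesian step). The weighted residual divides the population
#' residual by the fitted assay SD at the population prediction.
#'
#' @param fit An [npag_fit()] result.
#' @param data Optional long-format dataset; defaults to the fitting data.
#' @return A tibble of class `pk_predictions`: `subject_id`, `time_h`,
#'   `observed`, `pred_pop`, `pred_ind`, `wres`.
#' @export
predictions <- function(fit, data = NULL) {
  subjects <- if (is.null(data)) {
    fit$subjects
  } else {
    as_subjects(data, fit$control$lloq_policy, fit$control$lloq)
  }
  pts <- fit$distribution$points
  grid <- pts[c("intercept", "slope", "vc")]
  post <- posterior_estimates_internal(subjects, fit)
  out <- purrr::map_dfr(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (length(s$obs_times) == 0) return(NULL)
    pred_mat <- conc_matrix(s$schedule, grid, s$crcl_L_h, s$obs_times)
    pred_pop <- drop(crossprod(pred_mat, pts$weight))
    p_ind <- post[i, c("intercept", "slope", "vc")]
    pred_ind <- drop(conc_matrix(s$schedule, p_ind, s$crcl_L_h, s$obs_times))
    tibble::tibble(
      subject_id = s$subject_id,
      time_h = s$obs_times,
      observed = s$obs_conc,
      pred_pop = pred_pop,
      pred_ind = pred_ind,
      wres = (s$obs_conc - pred_pop) / assay_sd(pred_pop, fit$error)
    )
  })
  class(out) <- c("pk_predictions", class(out))
  out
}

posterior_estimates_internal <- function(subjects, fit) {
  pts <- fit$distribution$points
  grid <- pts[c("intercept", "slope", "vc")]
  purrr::map_dfr(subjects, function(s) {
    pw <- posterior_weights(s, grid, pts$weight, fit$error)
    mu <- colSums(as.matrix(grid) * pw)
    tibble::tibble(intercept = mu[["intercept"]], slope = mu[["slope"]],
                   vc = mu[["vc"]])
  })
}

#' Goodness-of-fit metrics
#'
#' R-squared from least-squares regression of observed on predicted
#' concentrations (population and individual level), plus the bias (mean
#' weighted residual) and imprecision (variance of the weighted residuals,
#' i.e. mean squared weighted residual minus squared bias).
#'
#' @param preds A [predictions()] tibble.
#' @return A one-row tibble: `r2_pop`, `r2_ind`, `bias`, `imprecision`.
#' @export
fit_metrics <- function(preds) {
  if (nrow(preds) < 3) abort("need at least 3 observations.")
  r2 <- function(pred) {
    if (var(pred) == 0) abort("predictions have zero variance; R2 undefined.")
    # summary.lm warns on an exactly perfect fit, a legitimate case here
    suppressWarnings(summary(lm(preds$observed ~ pred))$r.squared)
  }
  bias <- mean(preds$wres)
  tibble::tibble(
    r2_pop = r2(preds$pred_pop),
    r2_ind = r2(preds$pred_ind),
    bias = bias,
    imprecision = mean(preds$wres^2) - bias^2
  )
}

# Simulate `nsim` replicate observation vectors for one subject under the
# fitted discrete population + assay noise. Returns an nsim x k matrix.
simulate_subject <- function(subject, fit, nsim) {
  pts <- fit$distribution$points
  grid <- pts[c("intercept", "slope", "vc")]
  k <- length(subject$obs_times)
  idx <- sample.int(nrow(pts), nsim, replace = TRUE, prob = pts$weight)
  pred <- conc_matrix(subject$schedule, grid[idx, , drop = FALSE],
                      subject$crcl_L_h, subject$obs_times)
  noise <- matrix(rnorm(nsim * k), nsim, k) * assay_sd(pmax(pred, 0), fit$error)
  pred + noise
}

#' Normalised prediction distribution errors
#'
#' Simulation-based residual diagnostic: for each subject, `nsim` replicate
#' observation vectors are simulated under the fitted model; observed and
#' simulated vectors are decorrelated with the inverse Cholesky factor of
#' the empirical simulation covariance; the prediction distribution error of
#' each observation is the fraction of decorrelated simulations below the
#' decorrelated observation (with a 1/(2 nsim) continuity correction at 0
#' and 1), and its standard-normal quantile is the NPDE. Under a correct
#' model the pooled NPDE are standard normal; a Shapiro-Wilk test summarises
#' normality.
#'
#' @inheritParams predictions
#' @param nsim Number of simulated replicates per subject (>= 200).
#' @param seed Optional integer seed.
#' @return A list of class `npde_result`: `npde` (per-observation tibble),
#'   `mean`, `variance`, `shapiro_statistic`, `shapiro_p`, `nsim`.
#' @export
npde <- function(fit, data = NULL, nsim = 1000, seed = NULL) {
  if (nsim < 200) abort("`nsim` must be >= 200.")
  subjects <- if (is.null(data)) {
    fit$subjects
  } else {
    as_subjects(data, fit$control$lloq_policy, fit$control$lloq)
  }
  with_seed_(seed, {
    rows <- purrr::map_dfr(subjects, function(s) {
      k <- length(s$obs_times)
      if (k == 0) return(NULL)
      sims <- simulate_subject(s, fit, nsim)
      mu <- colMeans(sims)
      sc <- sweep(sims, 2, mu)
      vcv <- crossprod(sc) / (nsim - 1)
      dec <- tryCatch({
        ch <- chol(vcv) # upper triangular, vcv = t(ch) %*% ch
        list(
          y = drop(backsolve(ch, s$obs_conc - mu, transpose = TRUE)),
          s = t(backsolve(ch, t(sc), transpose = TRUE))
        )
      }, error = function(e) {
        warn("singular simulated covariance; using marginal decorrelation.")
        sds <- sqrt(pmax(diag(vcv), .Machine$double.eps))
        list(
          y = (s$obs_conc - mu) / sds,
          s = sweep(sc, 2, sds, "/")
        )
      })
      pde <- vapply(seq_len(k), function(j) mean(dec$s[, j] < dec$y[j]),
                    numeric(1))
      pde <- pmin(pmax(pde, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
      tibble::tibble(
        subject_id = s$subject_id, time_h = s$obs_times,
        observed = s$obs_conc, pred_pop = mu,
        pde = pde, npde = qnorm(pde)
      )
    })
    sw <- if (nrow(rows) >= 3 && nrow(rows) <= 5000) {
      shapiro.test(rows$npde)
    } else {
      list(statistic = NA_real_, p.value = NA_real_)
    }
    structure(list(
      npde = rows,
      mean = mean(rows$npde),
      variance = var(rows$npde),
      shapiro_statistic = unname(sw$statistic),
      shapiro_p = sw$p.value,
      nsim = nsim
    ), class = "npde_result")
  })
}

#' @export
print.npde_result <- function(x, ...) {
  cat("NPDE over ", nrow(x$npde), " observations (nsim = ", x$nsim, ")\n",
      "  mean ", signif(x$mean, 3), ", variance ", signif(x$variance, 3),
      "\n  Shapiro-Wilk W = ", signif(x$shapiro_statistic, 4),
      ", p = ", signif(x$shapiro_p, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.npde_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$npde), mean = x$mean, variance = x$variance,
    shapiro_statistic = x$shapiro_statistic, shapiro_p = x$shapiro_p
  )
}

#' @exportS3Method generics::tidy
tidy.npde_result <- function(x, ...) x$npde

#' Visual predictive check bands
#'
#' Simulates `nsim` replicate datasets at the observed design and compares
#' observed concentration percentiles with simulation percentiles per
#' time-after-dose bin (default: one bin per design sampling time).
#'
#' @inheritParams npde
#' @param probs Percentiles to compare (default 5th, 50th, 95th).
#' @param bin_edges Optional numeric edges (h, time after last dose start)
#'   defining the bins; by default each distinct sampling time is its own
#'   bin. Empty bins are dropped with a warning.
#' @return A tibble of class `vpc_bands`: per bin, `time` (bin midpoint or
#'   design time), `n_obs`, observed and simulated percentile columns.
#' @export
vpc <- function(fit, data = NULL, nsim = 1000, probs = c(0.05, 0.5, 0.95),
                bin_edges = NULL, seed = NULL) {
  if (nsim < 200) abort("`nsim` must be >= 200.")
  subjects <- if (is.null(data)) {
    fit$subjects
  } else {
    as_subjects(data, fit$control$lloq_policy, fit$control$lloq)
  }
  with_seed_(seed, {
    per_obs <- purrr::map_dfr(subjects, function(s) {
      k <- length(s$obs_times)
      if (k == 0) return(NULL)
      sims <- simulate_subject(s, fit, nsim)
      tad <- vapply(s$obs_times, function(t) {
        starts <- s$schedule$start_time[s$schedule$start_time <= t]
        if (!length(starts)) t else t - max(starts)
      }, numeric(1))
      tibble::tibble(
        tad = tad, observed = s$obs_conc,
        sims = lapply(seq_len(k), function(j) sims[, j])
      )
    })
    if (is.null(bin_edges)) {
      per_obs$bin <- factor(round(per_obs$tad, 6))
    } else {
      per_obs$bin <- cut(per_obs$tad, breaks = bin_edges,
                         include.lowest = TRUE)
      if (anyNA(per_obs$bin)) {
        warn("observations outside `bin_edges` dropped.")
        per_obs <- per_obs[!is.na(per_obs$bin), ]
      }
      empty <- setdiff(levels(per_obs$bin), unique(as.character(per_obs$bin)))
      if (length(empty)) warn(paste0("empty bin(s) dropped: ",
                                     paste(empty, collapse = ", ")))
    }
    bands <- per_obs |>
      dplyr::group_by(.data$bin) |>
      dplyr::group_map(function(d, key) {
        simv <- unlist(d$sims)
        obs_q <- quantile(d$observed, probs, names = FALSE)
        sim_q <- quantile(simv, probs, names = FALSE)
        tibble::tibble(
          bin = as.character(key$bin),
          time = mean(d$tad),
          n_obs = nrow(d),
          obs_lo = obs_q[1], obs_med = obs_q[2], obs_hi = obs_q[3],
          sim_lo = sim_q[1], sim_med = sim_q[2], sim_hi = sim_q[3]
        )
      }) |>
      dplyr::bind_rows()
    class(bands) <- c("vpc_bands", class(bands))
    attr(bands, "probs") <- probs
    bands
  })
}

#' @exportS3Method ggplot2::autoplot
autoplot.vpc_bands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_med)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$obs_lo,
                                        ymax = .data$obs_hi), width = 0.1) +
    ggplot2::labs(x = "time after dose (h)", y = "concentration (mg/L)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.npde_result <- function(object, ...) {
  ggplot2::ggplot(object$npde, ggplot2::aes(sample = .data$npde)) +
    ggplot2::stat_qq() +
    ggplot2::stat_qq_line() +
    ggplot2::labs(x = "standard normal quantile", y = "NPDE") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot
#'
#' @param preds A [predictions()] tibble.
#' @param level `"individual"` (posterior, default) or `"population"`.
#' @return A ggplot object with the identity line and least-squares fit.
#' @export
plot_predictions <- function(preds, level = c("individual", "population")) {
  level <- match.arg(level)
  pred <- if (level == "individual") preds$pred_ind else preds$pred_pop
  d <- tibble::tibble(observed = preds$observed, predicted = pred)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste(level, "predicted (mg/L)"),
                  y = "observed (mg/L)") +
    ggplot2::theme_minimal()
}
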