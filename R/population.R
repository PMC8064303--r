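#' Nonparametric population model
#'
#' The population distribution estimated by [npag_fit()] is discrete: a set
#' of support points (parameter vectors with probability weights). For
#' semi-parametric simulation each point additionally serves as the mean of a
#' multivariate normal whose covariance is the full-model parameter
#' covariance divided by the number of points.
#'
#' @param points A data frame with columns `intercept`, `slope`, `vc`,
#'   `weight`; weights must be non-negative and sum to 1 (within 1e-9).
#' @param covariance 3x3 symmetric positive semi-definite matrix over
#'   `(intercept, slope, vc)`. Defaults to the weighted covariance of the
#'   support points themselves.
#' @return An object of class `np_distribution`.
#' @export
#' @examples
#' np_distribution(data.frame(
#'   intercept = c(3, 6), slope = c(1, 2), vc = c(20, 40),
#'   weight = c(0.4, 0.6)
#' ))
np_distribution <- function(points, covariance = NULL) {
  req <- c("intercept", "slope", "vc", "weight")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols)) {
    abort(paste0("`points` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  points <- tibble::as_tibble(points)[req]
  if (any(points$weight < 0)) abort("weights must be non-negative.")
  if (abs(sum(points$weight) - 1) > 1e-9) {
    abort("weights must sum to 1 (within 1e-9).")
  }
  if (any(points$vc <= 0) || any(points$intercept < 0) ||
      any(points$slope < 0)) {
    abort("support points must satisfy the parameter constraints.")
  }
  covariance <- covariance %||% weighted_cov(points)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(3, 3)) ||
      max(abs(covariance - t(covariance))) > 1e-8) {
    abort("`covariance` must be a symmetric 3x3 matrix.")
  }
  if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(1, max(abs(covariance)))) {
    abort("`covariance` must be positive semi-definite.")
  }
  dimnames(covariance) <- list(req[1:3], req[1:3])
  structure(
    list(points = points, covariance = covariance),
    class = "np_distribution"
  )
}

weighted_cov <- function(points) {
  x <- as.matrix(points[c("intercept", "slope", "vc")])
  w <- points$weight / sum(points$weight)
  mu <- colSums(x * w)
  xc <- sweep(x, 2, mu)
  cov <- t(xc) %*% (xc * w)
  (cov + t(cov)) / 2
}

#' @export
print.np_distribution <- function(x, ...) {
  cat("<np_distribution> ", nrow(x$points), " support point(s)\n", sep = "")
  print(x$points, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.np_distribution <- function(x, ...) x$points

#' Weighted parameter summary of a nonparametric distribution
#'
#' Weighted mean, SD and marginal median of each parameter over the support
#' points, the discrete analogue of the usual population-parameter table.
#'
#' @param dist An [np_distribution()].
#' @return A tibble with columns `parameter`, `mean`, `sd`, `median`.
#' @export
weighted_summary <- function(dist) {
  stopifnot(inherits(dist, "np_distribution"))
  pts <- dist$points
  w <- pts$weight / sum(pts$weight)
  purrr::map_dfr(c("intercept", "slope", "vc"), function(p) {
    x <- pts[[p]]
    m <- sum(w * x)
    tibble::tibble(
      parameter = p,
      mean = m,
      sd = sqrt(max(sum(w * (x - m)^2), 0)),
      median = weighted_median(x, w)
    )
  })
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= 0.5 - 1e-12)[1]]
}

#' Semi-parametric virtual-patient sampling
#'
#' Draws parameter vectors from the mixture in which each support point is
#' the mean of a multivariate normal with covariance `dist$covariance /
#' n_points`, weighted by the point's probability. Draws violating the
#' positivity constraints (`intercept >= 0`, `slope >= 0`, `vc > 0`) are
#' rejected and redrawn (at most 1000 attempts per draw).
#'
#' @param dist An [np_distribution()].
#' @param n Number of virtual patients.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of `n` rows with columns `intercept`, `slope`, `vc` and
#'   `component` (index of the originating support point).
#' @export
semiparametric_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "np_distribution"), n >= 1)
  with_seed_(seed, {
    pts <- dist$points
    sigma <- dist$covariance / nrow(pts)
    comp <- sample.int(nrow(pts), n, replace = TRUE, prob = pts$weight)
    draws <- matrix(NA_real_, n, 3)
    for (j in sort(unique(comp))) {
      idx <- which(comp == j)
      mu <- as.numeric(pts[j, c("intercept", "slope", "vc")])
      need <- idx
      attempts <- 0
      while (length(need)) {
        cand <- MASS::mvrnorm(length(need), mu = mu, Sigma = sigma)
        cand <- matrix(cand, ncol = 3)
        ok <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] > 0
        draws[need[ok], ] <- cand[ok, , drop = FALSE]
        need <- need[!ok]
        attempts <- attempts + 1
        if (attempts > 1000) {
          abort("rejection sampling failed: >1000 attempts per draw.")
        }
      }
    }
    tibble::tibble(
      intercept = draws[, 1], slope = draws[, 2], vc = draws[, 3],
      component = comp
    )
  })
}

#' Parametric virtual-patient sampling (log-normal fallback)
#'
#' When the fitted support points are not available, virtual patients are
#' drawn from independent log-normal distributions moment-matched to the
#' reported arithmetic mean and SD of each parameter. The log-normal places
#' no mass at or below zero, avoiding the near-zero clearances a truncated
#' normal would need rejection to remove; a truncated-normal alternative is
#' provided via `family = "truncnorm"`.
#'
#' @param means,sds Named numeric vectors with entries `intercept`, `slope`,
#'   `vc`: target arithmetic means and SDs.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param family `"lognormal"` (default, moment-matched) or `"truncnorm"`
#'   (normal truncated at zero; note truncation shifts the realised moments).
#' @return A tibble of `n` rows with columns `intercept`, `slope`, `vc`.
#' @export
#' @examples
#' parametric_sample(
#'   means = c(intercept = 4.556, slope = 1.353, vc = 30.68),
#'   sds = c(intercept = 5.035, slope = 1.032, vc = 23.349),
#'   n = 5, seed = 1
#' )
parametric_sample <- function(means, sds, n, seed = NULL,
                              family = c("lognormal", "truncnorm")) {
  family <- match.arg(family)
  par_names <- c("intercept", "slope", "vc")
  if (!all(par_names %in% names(means)) || !all(par_names %in% names(sds))) {
    abort("`means` and `sds` need entries intercept, slope, vc.")
  }
  if (any(means[par_names] <= 0)) abort("`means` must be positive.")
  if (any(sds[par_names] < 0)) abort("`sds` must be non-negative.")
  with_seed_(seed, {
    draw1 <- function(m, s) {
      if (s == 0) return(rep(m, n))
      if (family == "lognormal") {
        sdlog2 <- log(1 + (s / m)^2)
        rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
      } else {
        x <- rnorm(n, m, s)
        while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), m, s)
        x
      }
    }
    tibble::tibble(
      intercept = draw1(means[["intercept"]], sds[["intercept"]]),
      slope = draw1(means[["slope"]], sds[["slope"]]),
      vc = draw1(means[["vc"]], sds[["vc"]])
    )
  })
}

#' Published piperacillin population estimates
#'
#' Arithmetic means and SDs of the clearance intercept (L/h), clearance
#' slope on creatinine clearance (dimensionless) and central volume (L)
#' reported for non-critically ill patients with Enterobacteriaceae
#' bloodstream infection: intercept 4.556 +/- 5.035, slope 1.353 +/- 1.032,
#' vc 30.68 +/- 23.349. These parameterise the log-normal fallback population
#' used by the dosing simulations when a fitted support-point model is not
#' supplied.
#'
#' @return A list with elements `means`, `sds` and `medians` (named numeric
#'   vectors).
#' @export
piperacillin_population <- function() {
  list(
    means = c(intercept = 4.556, slope = 1.353, vc = 30.68),
    sds = c(intercept = 5.035, slope = 1.032, vc = 23.349),
    medians = c(intercept = 3.503, slope = 1.39, vc = 20.039)
  )
}
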