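#' Sweep presynaptic activity level against population spiking probability
#'
#' For each activity level `p`, activates `round(p * n_pre)` presynaptic
#' cells at random (fresh patterns per level) in the chosen pathway, runs the
#' population response, and records the probability of action-potential
#' initiation (API) as the mean output spiking fraction over `n_patterns`
#' patterns. This is the empirical input-output curve a sigmoid is fitted to.
#'
#' @param model A response model (e.g. [threshold_surrogate()]).
#' @param pathway Pathway name to drive; the other pathways stay silent.
#' @param levels Strictly increasing activity proportions in `[0, 1]`.
#' @param n_patterns Random patterns per level (default 200).
#' @param seed Optional integer seed.
#' @return Object of classes `activity_sweep` and `data.frame` with columns
#'   `level`, `k` (active presynaptic cells), `n_patterns`, `api_prob`, `se`
#'   (standard error of the mean over patterns).
#' @export
sweep_activity <- function(model, pathway, levels, n_patterns = 200,
                           seed = NULL) {
  stopifnot(inherits(model, "threshold_surrogate"),
            pathway %in% names(model$maps))
  if (length(levels) == 0) stop("levels must not be empty")
  stopifnot(is.numeric(levels), all(levels >= 0), all(levels <= 1))
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing")
  }
  n_pre <- model$maps[[pathway]]$spec$n_pre
  rows <- lapply(seq_along(levels), function(i) {
    k <- as.integer(round(levels[i] * n_pre))
    fr <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, pathway, i),
      vapply(seq_len(n_patterns), function(j) {
        inp <- random_pattern(n_pre, k)
        out <- population_response(model, stats::setNames(list(inp), pathway))
        out$k / model$n_post
      }, numeric(1))
    )
    data.frame(level = levels[i], k = k, n_patterns = n_patterns,
               api_prob = mean(fr),
               se = stats::sd(fr) / sqrt(n_patterns))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activity_sweep", "data.frame")
  attr(out, "pathway") <- pathway
  attr(out, "n_pre") <- n_pre
  out
}

#' Fit a Boltzmann (logistic sigmoid) input-output curve
#'
#' Fits the Boltzmann function
#' \deqn{f(x) = \frac{A}{1 + \exp((x_{1/2} - x)/s)}}
#' to API probability versus activity level by nonlinear least squares
#' (Levenberg-Marquardt). With `fix_amplitude = TRUE` (default) the amplitude
#' is fixed at `A = 1`, since the response is a probability that saturates at
#' 1; the free-amplitude variant is available for completeness. `x_half` is
#' the activity at half-maximal response and `slope > 0` the steepness, in
#' the same units as the activity axis (proportion of presynaptic cells).
#'
#' @param sweep An [sweep_activity()] result, or any data.frame with columns
#'   `level` and `api_prob`.
#' @param fix_amplitude Fix `A = 1` (default) or estimate it.
#' @return Object of class `boltzmann_fit` with methods `print`, `coef`,
#'   `predict`, `residuals`, `vcov` and `plot`. Fields include `amplitude`,
#'   the residual RMS `rms`, and the underlying `nls` fit.
#' @examples
#' x <- seq(0.01, 0.12, length.out = 12)
#' y <- 1 / (1 + exp((0.055 - x) / 0.004))
#' fit <- fit_boltzmann(data.frame(level = x, api_prob = y))
#' coef(fit)
#' @export
fit_boltzmann <- function(sweep, fix_amplitude = TRUE) {
  stopifnot(is.data.frame(sweep), all(c("level", "api_prob") %in% names(sweep)))
  x <- sweep$level
  y <- sweep$api_prob
  if (length(x) < 3) stop("need at least 3 sweep levels to fit")
  if (all(y <= 0) || all(y >= 1)) {
    stop("degenerate sweep: response is saturated at 0 or 1 everywhere; widen the level range")
  }
  # starts: x_half from the level closest to half-range, slope from the span
  amp0 <- if (fix_amplitude) 1 else max(y)
  x_half0 <- x[which.min(abs(y - amp0 / 2))]
  slope0 <- max(diff(range(x)) / 10, 1e-6)
  df <- data.frame(x = x, y = y)
  fit <- if (fix_amplitude) {
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp((x_half - x) / slope)), data = df,
      start = list(x_half = x_half0, slope = slope0),
      lower = c(x_half = -Inf, slope = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    )
  } else {
    minpack.lm::nlsLM(
      y ~ A / (1 + exp((x_half - x) / slope)), data = df,
      start = list(A = amp0, x_half = x_half0, slope = slope0),
      lower = c(A = 1e-12, x_half = -Inf, slope = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    )
  }
  cf <- stats::coef(fit)
  structure(
    list(
      x_half = unname(cf["x_half"]),
      slope = unname(cf["slope"]),
      amplitude = if (fix_amplitude) 1 else unname(cf["A"]),
      fix_amplitude = fix_amplitude,
      rms = sqrt(mean(stats::residuals(fit)^2)),
      vcov = stats::vcov(fit),
      nls = fit,
      data = df
    ),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> f(x) = %s / (1 + exp((x_half - x) / slope))\n",
    if (x$fix_amplitude) "1" else sprintf("%.4g", x$amplitude)))
  cat(sprintf("  x_half = %.6g   slope = %.6g   residual RMS = %.3g\n",
              x$x_half, x$slope, x$rms))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(x_half = object$x_half, slope = object$slope,
    amplitude = object$amplitude)
}

#' @export
vcov.boltzmann_fit <- function(object, ...) object$vcov

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  stats::residuals(object$nls)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    (newdata$level %||% newdata$x)
  } else {
    as.numeric(newdata)
  }
  object$amplitude / (1 + exp((object$x_half - x) / object$slope))
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = "activity level",
                 ylab = "API probability", pch = 19, ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Invert a fitted Boltzmann curve for a target response probability
#'
#' Closed-form inverse of the fitted sigmoid:
#' `x = x_half - slope * log(A / p_target - 1)`, so that
#' `f(invert_for_target(fit, p)) == p` to machine precision. Used to read
#' off the presynaptic activity level that yields a desired population
#' spiking probability (e.g. 14%).
#'
#' @param fit A [fit_boltzmann()] result.
#' @param p_target Target probability, strictly inside `(0, amplitude)`.
#' @return Activity level (proportion).
#' @export
invert_for_target <- function(fit, p_target) {
  stopifnot(inherits(fit, "boltzmann_fit"),
            is.numeric(p_target), length(p_target) == 1L)
  if (p_target <= 0 || p_target >= fit$amplitude) {
    stop(sprintf("p_target must lie strictly in (0, %g)", fit$amplitude))
  }
  fit$x_half - fit$slope * log(fit$amplitude / p_target - 1)
}

#' Calibrate the surrogate threshold to a target spiking probability
#'
#' Fixes the presynaptic activity level and finds the threshold `theta` at
#' which the mean output spiking fraction over a set of random input
#' patterns matches `p_target`. Because the spiking fraction is
#' non-increasing in `theta` (monotone spike rule), bisection is valid: the
#' drive of every cell for every calibration pattern is computed once, and
#' the bracket is bisected until the achieved fraction is within `tol` of
#' the target or the bracket collapses to the granularity of the empirical
#' drive distribution (in which case the closest attainable fraction is
#' returned, with `tol_met = FALSE`).
#'
#' If even the smallest positive threshold cannot reach `p_target`
#' (e.g. a near-1 target with so little input that many cells receive no
#' active synapse at all), calibration fails with an error rather than
#' looping.
#'
#' @param model A [threshold_surrogate()].
#' @param pathway Pathway to drive during calibration.
#' @param activity Presynaptic activity proportion.
#' @param p_target Target spiking probability in `(0, 1)`.
#' @param n_patterns Calibration patterns (default 50).
#' @param tol Tolerance on the achieved fraction (default 0.005).
#' @param seed Optional integer seed for the calibration patterns.
#' @return Object of class `threshold_calibration`: `theta`, `achieved`,
#'   `tol_met`, `p_target`, `activity`, `pathway`, `n_patterns`.
#' @export
calibrate_threshold <- function(model, pathway, activity, p_target,
                                n_patterns = 50, tol = 0.005, seed = NULL) {
  stopifnot(inherits(model, "threshold_surrogate"),
            pathway %in% names(model$maps),
            is.numeric(activity), length(activity) == 1L,
            activity > 0, activity <= 1,
            is.numeric(p_target), length(p_target) == 1L,
            p_target > 0, p_target < 1,
            n_patterns >= 1)
  n_pre <- model$maps[[pathway]]$spec$n_pre
  k <- as.integer(round(activity * n_pre))
  if (k < 1) stop("activity too low: no presynaptic cell active")
  drives <- with_seed(seed, {
    vapply(seq_len(n_patterns), function(j) {
      inp <- random_pattern(n_pre, k)
      .population_drive(model, stats::setNames(list(inp), pathway))
    }, numeric(model$n_post))
  })
  frac <- function(theta) mean(drives >= theta)
  eps <- 1e-12
  reachable <- frac(eps) # max fraction with a positive threshold
  if (reachable < p_target - tol) {
    stop(sprintf(
      "p_target = %.3f unreachable: at most %.3f of cells receive any positive drive at activity %.3g",
      p_target, reachable, activity))
  }
  lo <- eps
  hi <- max(drives) + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - p_target) <= tol) { lo <- hi <- mid; break }
    if (f > p_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  cand <- c(lo, hi, (lo + hi) / 2)
  ach <- vapply(cand, frac, numeric(1))
  best <- which.min(abs(ach - p_target))
  structure(
    list(theta = cand[best], achieved = ach[best],
         tol_met = abs(ach[best] - p_target) <= tol,
         p_target = p_target, activity = activity, pathway = pathway,
         n_patterns = n_patterns),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold_calibration> %s @ activity %.4g: theta = %.5g, achieved %.4f (target %.4f%s)\n",
    x$pathway, x$activity, x$theta, x$achieved, x$p_target,
    if (x$tol_met) "" else "; tolerance not met, closest attainable"))
  invisible(x)
}

#' Write an activity sweep to CSV
#'
#' Columns `level`, `k`, `n_patterns`, `api_prob`, `se`.
#'
#' @param sweep An [sweep_activity()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
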