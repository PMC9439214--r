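#' @title Nonlinear least-squares fits of the oviposition model components
#' @description Each `fit_*()` function estimates one model component by
#'   (nonlinear) least squares and returns an object of class `"ovifit"`
#'   carrying point estimates, standard errors from the Jacobian at the
#'   optimum, adjusted r-squared, residuals and the fitted parameter bundle.
#'   Iterative fits use Levenberg-Marquardt (via \pkg{minpack.lm}); the
#'   one-parameter constrained refits (`fit_fecundity_rm()`,
#'   `fit_aging_sigma()`) are closed-form linear least squares.
#' @name ovifit
NULL

new_ovifit <- function(component, estimates, se, residuals, fitted, n_obs,
                       params, data, converged = TRUE) {
  adj <- tryCatch(
    adjusted_r2(residuals, fitted + residuals, length(estimates)),
    error = function(e) NA_real_)
  structure(list(component = component, estimates = estimates, se = se,
                 adj_r2 = adj, residuals = residuals, fitted = fitted,
                 n_obs = n_obs, params = params, data = data,
                 converged = converged),
            class = c(paste0(component, "_fit"), "ovifit"))
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` with
#' `r2 = 1 - SS_res / SS_tot`, `SS_tot` about the mean of the observations.
#'
#' @param residuals Per-observation residuals (observed minus fitted).
#' @param observed Observed values.
#' @param n_params Number of fitted parameters `p`; requires
#'   `n > n_params + 1`.
#' @return Adjusted r-squared (at most 1; can be negative).
#' @export
adjusted_r2 <- function(residuals, observed, n_params) {
  n <- length(observed)
  stopifnot(length(residuals) == n)
  if (n <= n_params + 1)
    stop("adjusted r-squared needs n_obs > n_params + 1", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("zero total variance: adjusted r-squared undefined", call. = FALSE)
  r2 <- 1 - sum(residuals^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

lm_control <- function() minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                                    ptol = 1e-12, maxfev = 10000)

run_nlsLM <- function(formula, data, start, lower = NULL) {
  fit <- tryCatch(
    if (is.null(lower))
      minpack.lm::nlsLM(formula, data = data, start = start, control = lm_control())
    else
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        control = lm_control()),
    error = function(e)
      stop("least-squares fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  fit
}

#' Fit the Gaussian thermal fecundity curve
#'
#' Estimates all three parameters (`r_m`, `t_max`, `k`) of the thermal
#' fecundity curve from per-female (or per-condition-mean) total egg counts at
#' multiple temperatures. Starting values: `r_m` at the largest observed egg
#' count, `t_max` at the temperature with the largest mean egg count (smallest
#' such temperature on ties), `k` at half the observed temperature range.
#'
#' @param temp Temperature per observation (degrees C).
#' @param eggs Total eggs per female (>= 0), same length.
#' @param weights Optional nonnegative per-observation weights.
#' @return An `"ovifit"` with a `fecundity_params` bundle in `$params`.
#' @examples
#' sb <- fecundity_params(216.982, 30.558, 7.182)
#' tt <- rep(c(15, 20, 25, 30, 35, 40), each = 3)
#' fit <- fit_fecundity(tt, total_fecundity(tt, sb))
#' coef(fit)
#' @export
fit_fecundity <- function(temp, eggs, weights = NULL) {
  dat <- check_obs(temp = temp, eggs = eggs, weights = weights)
  if (nrow(dat) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (length(unique(dat$temp)) < 3L)
    stop("need at least 3 distinct temperatures (degenerate design)", call. = FALSE)
  if (any(dat$eggs < 0)) stop("'eggs' must be nonnegative", call. = FALSE)
  mu <- tapply(dat$eggs, dat$temp, mean)
  t_levels <- as.numeric(names(mu))
  start <- list(r_m = max(dat$eggs),
                t_max = min(t_levels[mu == max(mu)]),
                k = max(diff(range(dat$temp)) / 2, 0.5))
  # unconstrained fit; the curve is symmetric in the sign of k, so normalize
  fit <- if (is.null(weights)) {
    run_nlsLM(eggs ~ r_m * exp(-0.5 * ((temp - t_max) / k)^2), dat, start)
  } else {
    tryCatch(
      minpack.lm::nlsLM(eggs ~ r_m * exp(-0.5 * ((temp - t_max) / k)^2),
                        data = dat, start = start, weights = dat$weights,
                        control = lm_control()),
      error = function(e)
        stop("least-squares fit failed to converge: ", conditionMessage(e),
             call. = FALSE))
  }
  est <- stats::coef(fit)
  est["k"] <- abs(est["k"])
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (!is.finite(est["k"]) || est["k"] > 1e4)
    stop("fecundity fit unidentifiable: curve steepness diverged", call. = FALSE)
  if (est["r_m"] <= 0)
    stop("fecundity fit unidentifiable: nonpositive curve height", call. = FALSE)
  new_ovifit("fecundity", est, se,
             residuals = dat$eggs - stats::fitted(fit),
             fitted = as.numeric(stats::fitted(fit)), n_obs = nrow(dat),
             params = fecundity_params(est[["r_m"]], est[["t_max"]], est[["k"]]),
             data = dat)
}

#' Constrained refit of maximum total fecundity only
#'
#' Re-estimates `r_m` alone, holding `t_max` and `k` fixed (the host-plant
#' comparison refit: the curve shape is taken from the baseline host and only
#' its height is re-estimated per host). This is a one-parameter linear
#' least-squares problem with the closed form
#' `r_m = sum(w * g * y) / sum(w * g^2)`, where
#' `g = exp(-0.5 * ((t - t_max)/k)^2)`.
#'
#' @param temp Temperature per observation (degrees C).
#' @param eggs Total eggs per female or condition means.
#' @param t_max,k Fixed curve location and steepness.
#' @param weights Optional nonnegative weights (e.g. replicate counts when
#'   fitting condition means); default unweighted.
#' @return An `"ovifit"`; standard error from the residual variance (NA with a
#'   single observation).
#' @examples
#' # Kochia scoparia condition means at 30 and 35 C, baseline curve shape:
#' fit_fecundity_rm(c(30, 35), c(137.57, 102.17), t_max = 30.558, k = 7.182)
#' @export
fit_fecundity_rm <- function(temp, eggs, t_max, k, weights = NULL) {
  dat <- check_obs(temp = temp, eggs = eggs, weights = weights)
  if (any(dat$eggs < 0)) stop("'eggs' must be nonnegative", call. = FALSE)
  shape <- fecundity_params(1, t_max, k)
  g <- total_fecundity(dat$temp, shape)
  w <- if (is.null(weights)) rep(1, nrow(dat)) else dat$weights
  denom <- sum(w * g^2)
  if (denom < 1e-24)
    stop("all observations lie far outside the fecundity curve: r_m ",
         "unidentifiable", call. = FALSE)
  r_m <- sum(w * g * dat$eggs) / denom
  res <- dat$eggs - r_m * g
  n <- nrow(dat)
  se <- if (n > 1) sqrt(sum(w * res^2) / (n - 1) / denom) else NA_real_
  new_ovifit("fecundity_rm", c(r_m = r_m), c(r_m = se),
             residuals = res, fitted = r_m * g, n_obs = n,
             params = fecundity_params(r_m, t_max, k), data = dat)
}

#' Fit the temperature-dependent aging-rate curve
#'
#' Estimates `a`, `b`, `c` of the aging-rate curve (with `sigma` fixed at 1,
#' the baseline host) from adult longevities at several temperatures. Fitting
#' is done in rate space: observed rates are the reciprocals of individual
#' longevities in days, and squared rate error is minimized. Starting values
#' come from an exact linear regression of log rate on `T^2.5` and `T^3`.
#'
#' @param temp Temperature per observation (degrees C).
#' @param longevity Adult lifespan per observation, in `units`.
#' @param units `"days"` (default) or `"weeks"`; weekly records are converted
#'   to days (x 7) at this boundary.
#' @return An `"ovifit"` with an `aging_params` bundle (`sigma = 1`).
#' @export
fit_aging <- function(temp, longevity, units = c("days", "weeks")) {
  units <- match.arg(units)
  dat <- check_obs(temp = temp, longevity = longevity)
  if (any(dat$longevity <= 0)) stop("'longevity' must be positive", call. = FALSE)
  if (nrow(dat) < 4L || length(unique(dat$temp)) < 4L)
    stop("aging-rate fit needs >= 4 observations at >= 4 distinct temperatures ",
         "(under-determined otherwise)", call. = FALSE)
  days <- if (units == "weeks") dat$longevity * 7 else dat$longevity
  dat$rate <- 1 / days
  lin <- stats::lm(log(rate) ~ I(temp^2.5) + I(temp^3), data = dat)
  start <- list(a = unname(stats::coef(lin)[1]), b = unname(stats::coef(lin)[2]),
                c = unname(stats::coef(lin)[3]))
  fit <- run_nlsLM(rate ~ exp(a + b * temp^2.5 + c * temp^3), dat, start)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  new_ovifit("aging", est, se,
             residuals = dat$rate - stats::fitted(fit),
             fitted = as.numeric(stats::fitted(fit)), n_obs = nrow(dat),
             params = aging_params(est[["a"]], est[["b"]], est[["c"]], sigma = 1),
             data = dat)
}

#' Constrained refit of the host-specific aging multiplier only
#'
#' Estimates `sigma` alone, holding the baseline temperature response
#' (`a`, `b`, `c`) fixed: closed-form least squares of observed aging rates
#' (reciprocal longevities) on the baseline rates,
#' `sigma = sum(r_hat * y) / sum(r_hat^2)`.
#'
#' @param temp Temperature per observation (degrees C).
#' @param longevity Adult lifespan per observation, in `units`.
#' @param baseline An [aging_params()] bundle providing `a`, `b`, `c` (its
#'   `sigma` is ignored; rates are evaluated at `sigma = 1`).
#' @param units `"days"` or `"weeks"`.
#' @return An `"ovifit"` with the host's `aging_params` bundle.
#' @export
fit_aging_sigma <- function(temp, longevity, baseline, units = c("days", "weeks")) {
  units <- match.arg(units)
  stopifnot(inherits(baseline, "aging_params"))
  dat <- check_obs(temp = temp, longevity = longevity)
  if (any(dat$longevity <= 0)) stop("'longevity' must be positive", call. = FALSE)
  days <- if (units == "weeks") dat$longevity * 7 else dat$longevity
  y <- 1 / days
  base1 <- aging_params(baseline$a, baseline$b, baseline$c, sigma = 1)
  r_hat <- aging_rate(dat$temp, base1)
  sigma <- sum(r_hat * y) / sum(r_hat^2)
  res <- y - sigma * r_hat
  n <- nrow(dat)
  se <- if (n > 1) sqrt(sum(res^2) / (n - 1) / sum(r_hat^2)) else NA_real_
  new_ovifit("aging_sigma", c(sigma = sigma), c(sigma = se),
             residuals = res, fitted = sigma * r_hat, n_obs = n,
             params = aging_params(baseline$a, baseline$b, baseline$c, sigma),
             data = cbind(dat, rate = y))
}

#' Fit the Weibull oviposition schedule
#'
#' Estimates the Weibull scale and shape of the age-specific cumulative
#' oviposition curve from (normalized age, cumulative proportion) pairs.
#' Because age is normalized, observations from all temperatures and hosts
#' can be pooled. Starting values: scale at the age whose observed proportion
#' is nearest `1 - exp(-1)`, shape 2.
#'
#' @param px Normalized female age per observation (>= 0).
#' @param value Cumulative oviposition proportion in `[0, 1]`.
#' @return An `"ovifit"` with a `schedule_params` bundle.
#' @export
fit_schedule <- function(px, value) {
  dat <- check_schedule_obs(px, value)
  alpha0 <- dat$px[which.min(abs(dat$value - (1 - exp(-1))))]
  if (alpha0 <= 0) alpha0 <- max(dat$px) / 2
  fit <- run_nlsLM(value ~ 1 - exp(-(px / alpha)^beta), dat,
                   start = list(alpha = alpha0, beta = 2),
                   lower = c(alpha = 1e-8, beta = 1e-8))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  new_ovifit("schedule", est, se,
             residuals = dat$value - stats::fitted(fit),
             fitted = as.numeric(stats::fitted(fit)), n_obs = nrow(dat),
             params = schedule_params(est[["alpha"]], est[["beta"]]),
             data = dat)
}

#' Fit the sigmoid survival curve
#'
#' Estimates `gamma` (normalized age at 50% survival) and the slope of the
#' age-specific survival curve from (normalized age, surviving proportion)
#' pairs, under either parameterization of [survival_params()]. The fitted
#' `gamma` is exactly the age at which the fitted curve crosses 0.5.
#'
#' @param px Normalized female age per observation (>= 0).
#' @param value Surviving proportion in `[0, 1]`.
#' @param parameterization Passed to [survival_params()]; default
#'   `"slope_multiplier"`.
#' @return An `"ovifit"` with a `survival_params` bundle. In the
#'   `"slope_multiplier"` form the reported `delta` is the positive slope
#'   magnitude; in `"literal"` it is the (negative) literal slope.
#' @export
fit_survival <- function(px, value,
                         parameterization = c("slope_multiplier", "literal")) {
  parameterization <- match.arg(parameterization)
  dat <- check_schedule_obs(px, value)
  gamma0 <- dat$px[which.min(abs(dat$value - 0.5))]
  if (gamma0 <= 0) gamma0 <- stats::median(dat$px)
  v <- pmin(pmax(dat$value, 0.01), 0.99)
  slope0 <- tryCatch(
    abs(unname(stats::coef(stats::lm(log((1 - v) / v) ~ dat$px))[2])),
    error = function(e) 5)
  if (!is.finite(slope0) || slope0 < 0.1) slope0 <- 5
  if (parameterization == "slope_multiplier") {
    fit <- run_nlsLM(value ~ 1 / (1 + exp((px - gamma) * m)), dat,
                     start = list(gamma = gamma0, m = slope0),
                     lower = c(gamma = 1e-8, m = 1e-8))
    est <- stats::coef(fit)
    estimates <- c(gamma = unname(est["gamma"]), delta = unname(est["m"]))
    params <- survival_params(est[["gamma"]], est[["m"]], "slope_multiplier")
  } else {
    fit <- run_nlsLM(value ~ 1 / (1 + exp((gamma - px) / delta)), dat,
                     start = list(gamma = gamma0, delta = -1 / slope0))
    est <- stats::coef(fit)
    if (est[["delta"]] >= 0)
      stop("survival fit produced a nondecreasing curve (delta >= 0)",
           call. = FALSE)
    estimates <- c(gamma = unname(est["gamma"]), delta = unname(est["delta"]))
    params <- survival_params(est[["gamma"]], est[["delta"]], "literal")
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  names(se) <- names(estimates)
  new_ovifit("survival", estimates, se,
             residuals = dat$value - stats::fitted(fit),
             fitted = as.numeric(stats::fitted(fit)), n_obs = nrow(dat),
             params = params, data = dat)
}

# -- shared input checks ------------------------------------------------------

check_obs <- function(...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, logical(1))]
  n <- unique(lengths(args))
  if (length(n) != 1L)
    stop("observation vectors must have equal length", call. = FALSE)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || any(!is.finite(args[[nm]])))
      stop("'", nm, "' must be finite and numeric", call. = FALSE)
  }
  if (!is.null(args$weights) && any(args$weights < 0))
    stop("'weights' must be nonnegative", call. = FALSE)
  as.data.frame(args)
}

check_schedule_obs <- function(px, value) {
  dat <- check_obs(px = px, value = value)
  if (any(dat$px < 0)) stop("'px' must be nonnegative", call. = FALSE)
  if (any(dat$value < 0 | dat$value > 1))
    stop("'value' must lie in [0, 1]", call. = FALSE)
  if (nrow(dat) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!any(dat$value > 0 & dat$value < 1))
    stop("need at least one proportion strictly inside (0, 1): curve ",
         "unidentifiable from all-0/all-1 data", call. = FALSE)
  if (all(dat$px == 0)) stop("'px' values are all zero", call. = FALSE)
  dat
}

# -- methods ------------------------------------------------------------------

#' @export
print.ovifit <- function(x, ...) {
  cat(sprintf("Oviposition-model component fit: %s (n = %d)\n", x$component, x$n_obs))
  tab <- cbind(Estimate = x$estimates, `Std. Error` = x$se)
  print(round(tab, 4))
  if (is.finite(x$adj_r2)) cat(sprintf("Adjusted r-squared: %.3f\n", x$adj_r2))
  invisible(x)
}

#' @export
summary.ovifit <- function(object, ...) {
  structure(list(component = object$component, estimates = object$estimates,
                 se = object$se, adj_r2 = object$adj_r2, n_obs = object$n_obs,
                 converged = object$converged,
                 rss = sum(object$residuals^2)),
            class = "summary.ovifit")
}

#' @export
print.summary.ovifit <- function(x, ...) {
  cat(sprintf("Component: %s\nObservations: %d\nConverged: %s\nRSS: %.6g\n",
              x$component, x$n_obs, x$converged, x$rss))
  print(cbind(Estimate = x$estimates, `Std. Error` = x$se))
  if (is.finite(x$adj_r2)) cat(sprintf("Adjusted r-squared: %.4f\n", x$adj_r2))
  invisible(x)
}

#' @export
coef.ovifit <- function(object, ...) object$estimates

#' @export
residuals.ovifit <- function(object, ...) object$residuals

#' Evaluate a fitted component on new inputs
#'
#' @param object An `"ovifit"`.
#' @param newdata Numeric vector of temperatures (fecundity/aging components)
#'   or normalized ages (schedule/survival components). Defaults to the
#'   fitting inputs.
#' @param ... Unused.
#' @return Fitted curve values.
#' @export
predict.ovifit <- function(object, newdata = NULL, ...) {
  p <- object$params
  x <- newdata
  switch(object$component,
    fecundity    = total_fecundity(if (is.null(x)) object$data$temp else x, p),
    fecundity_rm = total_fecundity(if (is.null(x)) object$data$temp else x, p),
    aging        = aging_rate(if (is.null(x)) object$data$temp else x, p),
    aging_sigma  = aging_rate(if (is.null(x)) object$data$temp else x, p),
    schedule     = cum_oviposition(if (is.null(x)) object$data$px else x, p),
    survival     = surv_prop(if (is.null(x)) object$data$px else x, p),
    stop("unknown component"))
}
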