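#' Total fecundity as a function of temperature
#'
#' Evaluates the Gaussian thermal fecundity curve
#' \eqn{f(T) = R_m \exp[-\tfrac{1}{2}((T - T_{max})/k)^2]}, the expected total
#' number of eggs laid per female over her whole adult life at constant
#' temperature \eqn{T}.
#'
#' @param t Temperature(s), degrees C. Values outside \[0, 50\] are evaluated
#'   as-is (the curve is an extrapolation there) with a warning.
#' @param params A [fecundity_params()] object.
#' @return Eggs per female, same length as `t`; always in `(0, r_m]`.
#' @examples
#' sb <- default_host_models()$sugar_beet
#' total_fecundity(30.558, sb$fecundity)  # the maximum, R_m
#' @export
total_fecundity <- function(t, params) {
  stopifnot(inherits(params, "fecundity_params"))
  check_temperature(t, allow_negative = TRUE)
  params$r_m * exp(-0.5 * ((t - params$t_max) / params$k)^2)
}

#' Female aging rate as a function of temperature
#'
#' Evaluates \eqn{r(T) = \sigma \exp(a + b T^{2.5} + c T^3)}, the daily
#' physiological aging rate (1/day) of adult females at temperature \eqn{T}.
#' One unit of accumulated rate corresponds to roughly a full adult lifespan.
#'
#' @param t Temperature(s), degrees C; must be nonnegative (the \eqn{T^{2.5}}
#'   term is undefined for negative temperatures). Values above 50 warn.
#' @param params An [aging_params()] object.
#' @return Aging rate (1/day), strictly positive, same length as `t`.
#' @export
aging_rate <- function(t, params) {
  stopifnot(inherits(params, "aging_params"))
  check_temperature(t, allow_negative = FALSE)
  params$sigma * exp(params$a + params$b * t^2.5 + params$c * t^3)
}

#' Normalized female age under a daily temperature series
#'
#' Accumulates the daily aging rate over a temperature series to produce the
#' normalized (physiological) age trajectory: `px[1] = 0` on the emergence
#' day, and `px[i + 1] = px[i] + r(T_i)` where `T_i` is the mean temperature
#' of the i-th day of adult life. Each daily mean drives the whole day.
#'
#' @param temps Daily mean temperatures: a numeric vector or a
#'   [temperature_series()].
#' @param params An [aging_params()] object.
#' @return Numeric vector of length `length(temps) + 1`: normalized age at the
#'   start of each day plus the end of the final day. Strictly increasing,
#'   starting at 0.
#' @examples
#' ag <- default_host_models()$sugar_beet$aging
#' normalized_age(rep(30, 5), ag)
#' @export
normalized_age <- function(temps, params) {
  temps <- as_daily_temps(temps)
  if (length(temps) < 1L) stop("temperature series must have length >= 1", call. = FALSE)
  cumsum(c(0, aging_rate(temps, params)))
}

#' Age-specific cumulative oviposition rate
#'
#' Weibull schedule \eqn{p(Px) = 1 - \exp[-(Px/\alpha)^\beta]}: the fraction
#' of a female's lifetime egg total laid by normalized age \eqn{Px}.
#'
#' @param px Normalized female age(s), nonnegative.
#' @param params A [schedule_params()] object.
#' @return Proportion(s) in `[0, 1)`, nondecreasing in `px`, 0 at `px = 0`.
#' @export
cum_oviposition <- function(px, params) {
  stopifnot(inherits(params, "schedule_params"))
  if (any(!is.finite(px)) || any(px < 0))
    stop("'px' must be finite and nonnegative", call. = FALSE)
  1 - exp(-(px / params$alpha)^params$beta)
}

#' Age-specific survival of adult females
#'
#' Proportion of females still alive at normalized age \eqn{Px}, under either
#' survival parameterization (see [survival_params()]). In both forms the
#' curve equals exactly 0.5 at \eqn{Px = \gamma} and is monotone
#' nonincreasing.
#'
#' @param px Normalized female age(s), nonnegative.
#' @param params A [survival_params()] object.
#' @return Proportion(s) in `(0, 1)`.
#' @export
surv_prop <- function(px, params) {
  stopifnot(inherits(params, "survival_params"))
  if (any(!is.finite(px)) || any(px < 0))
    stop("'px' must be finite and nonnegative", call. = FALSE)
  if (params$parameterization == "slope_multiplier") {
    1 / (1 + exp((px - params$gamma) * abs(params$delta)))
  } else {
    1 / (1 + exp((params$gamma - px) / params$delta))
  }
}

#' Normalized age at a given survival level (inverse survival function)
#'
#' Solves \eqn{s(Px) = q} for \eqn{Px}. Used to sample individual lifetimes
#' on the normalized-age scale (death age at uniform `1 - q`) and to locate
#' the median lifespan.
#'
#' @param q Survival proportion(s) in (0, 1).
#' @param params A [survival_params()] object.
#' @return Normalized age(s); negative solutions (survival below its age-0
#'   value) are truncated to 0.
#' @export
survival_quantile <- function(q, params) {
  stopifnot(inherits(params, "survival_params"))
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly within (0, 1)", call. = FALSE)
  px <- if (params$parameterization == "slope_multiplier") {
    params$gamma + log((1 - q) / q) / abs(params$delta)
  } else {
    # s = 1/(1 + e^{(gamma - px)/delta}), delta < 0
    params$gamma - params$delta * log((1 - q) / q)
  }
  pmax(px, 0)
}

#' Expected fraction of the oviposition schedule completed before death
#'
#' A female dying at normalized age `px_d` has completed fraction `p(px_d)` of
#' the Weibull oviposition schedule. Averaging over the lifetime distribution
#' implied by the survival curve (death-age CDF `1 - s(px)`) gives the
#' expected completed fraction — the factor linking a female's *potential*
#' laying intensity to her expected *realized* lifetime total. With the fitted
#' beet-leafhopper schedule and survival parameters this is about 0.92.
#'
#' Computed by midpoint quadrature over the uniform death quantile.
#'
#' @param schedule A [schedule_params()] object.
#' @param survival A [survival_params()] object.
#' @param n Number of quadrature nodes.
#' @return A scalar in (0, 1).
#' @export
schedule_completion <- function(schedule, survival, n = 20000L) {
  u <- (seq_len(n) - 0.5) / n
  px_d <- survival_quantile(1 - u, survival)
  mean(cum_oviposition(px_d, schedule))
}

# -- internal helpers ---------------------------------------------------------

check_temperature <- function(t, allow_negative) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("temperatures must be finite numbers", call. = FALSE)
  if (!allow_negative && any(t < 0))
    stop("negative temperatures are not admissible here (T^2.5 undefined)",
         call. = FALSE)
  if (any(t < 0 | t > 50))
    warning("temperature outside [0, 50] C: the model is an extrapolation there",
            call. = FALSE)
  invisible(t)
}

as_daily_temps <- function(temps) {
  if (inherits(temps, "temperature_series")) return(temps$temp)
  if (!is.numeric(temps))
    stop("'temps' must be a numeric vector or a temperature_series", call. = FALSE)
  temps
}
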