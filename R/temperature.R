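#' Daily mean temperature series
#'
#' An ordered sequence of daily mean temperatures, the driving input of the
#' oviposition simulator. Days must be consecutive calendar days: the model is
#' day-indexed from female emergence and needs a complete series.
#'
#' @param temp Daily mean temperatures (degrees C), finite, one per day.
#' @param dates Calendar dates (`Date` or ISO-8601 strings), strictly
#'   increasing by one day. Defaults to consecutive days from `start`.
#' @param start Start date used when `dates` is missing.
#' @return A data frame of class `"temperature_series"` with columns `date`
#'   and `temp`.
#' @examples
#' temperature_series(rep(30, 7), start = as.Date("2021-06-01"))
#' @export
temperature_series <- function(temp, dates = NULL, start = as.Date("2021-01-01")) {
  if (!is.numeric(temp) || length(temp) < 1L || any(!is.finite(temp)))
    stop("'temp' must be a nonempty vector of finite temperatures", call. = FALSE)
  if (is.null(dates)) {
    dates <- seq(as.Date(start), by = "day", length.out = length(temp))
  } else {
    dates <- as.Date(dates)
    if (length(dates) != length(temp))
      stop("'dates' and 'temp' must have equal length", call. = FALSE)
    if (anyNA(dates)) stop("'dates' contains unparseable dates", call. = FALSE)
    d <- diff(as.integer(dates))
    if (any(d == 0))
      stop("duplicate dates in temperature series (first at position ",
           which(d == 0)[1] + 1L, ")", call. = FALSE)
    if (any(d != 1L))
      stop("gap or disorder in temperature series dates (first at position ",
           which(d != 1L)[1] + 1L, "): the daily model needs a complete series",
           call. = FALSE)
  }
  structure(data.frame(date = dates, temp = temp),
            class = c("temperature_series", "data.frame"))
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Daily temperature series: %d days, %s to %s, mean %.1f C [%.1f, %.1f]\n",
              nrow(x), format(x$date[1]), format(x$date[nrow(x)]),
              mean(x$temp), min(x$temp), max(x$temp)))
  invisible(x)
}

#' Generate a daily temperature regime
#'
#' Builds synthetic daily mean temperature series of the kinds used to drive
#' the model: constant growth-chamber regimes, a winter semi-field regime
#' (cool, variable; used for the winter/spring host plants), a summer
#' greenhouse regime (warm; used for the summer host), or a fully custom
#' sinusoid. Non-constant profiles are
#' `mean + amplitude * sin(2*pi*(day - 1)/period) + N(0, noise_sd)`,
#' truncated below at 0 degrees C. The default `period` equals the series
#' length, so the seasonal component averages to zero over the window and the
#' sample mean tracks `mean`.
#'
#' The winter and summer defaults are this package's assumptions about
#' plausible logger records (no published daily series exists to copy); see
#' the methods vignette.
#'
#' @param profile One of `"constant"`, `"winter_semifield"`,
#'   `"summer_greenhouse"`, `"custom_sinusoid"`.
#' @param days Series length in days. Defaults: 70 (constant), 105 (winter,
#'   15 weeks), 84 (summer, 12 weeks).
#' @param mean Mean temperature, degrees C. Defaults: 30 (constant), 12
#'   (winter), 28 (summer).
#' @param amplitude Seasonal sinusoid amplitude, degrees C (0 for constant).
#' @param period Sinusoid period in days; default `days`.
#' @param noise_sd Day-to-day Gaussian noise SD, degrees C.
#' @param start Start date of the series.
#' @param seed Optional RNG seed; the series is reproducible under it and the
#'   caller's RNG state is left untouched.
#' @return A [temperature_series()].
#' @examples
#' generate_regime("constant", days = 14, mean = 35)
#' generate_regime("winter_semifield", seed = 1)
#' @export
generate_regime <- function(profile = c("constant", "winter_semifield",
                                        "summer_greenhouse", "custom_sinusoid"),
                            days = NULL, mean = NULL, amplitude = NULL,
                            period = NULL, noise_sd = NULL,
                            start = as.Date("2021-01-01"), seed = NULL) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    constant          = list(days = 70L,  mean = 30, amplitude = 0, noise_sd = 0),
    winter_semifield  = list(days = 105L, mean = 12, amplitude = 4, noise_sd = 2),
    summer_greenhouse = list(days = 84L,  mean = 28, amplitude = 3, noise_sd = 1.5),
    custom_sinusoid   = list(days = 70L,  mean = 20, amplitude = 5, noise_sd = 1))
  days <- if (is.null(days)) defaults$days else days
  mean <- if (is.null(mean)) defaults$mean else mean
  amplitude <- if (is.null(amplitude)) defaults$amplitude else amplitude
  noise_sd <- if (is.null(noise_sd)) defaults$noise_sd else noise_sd
  if (!is.numeric(days) || length(days) != 1L || days < 1)
    stop("'days' must be a positive count", call. = FALSE)
  days <- as.integer(days)
  if (is.null(period)) period <- days
  temp <- if (profile == "constant") {
    rep(mean, days)
  } else {
    with_seed(seed, {
      i <- seq_len(days) - 1
      mean + amplitude * sin(2 * pi * i / period) + stats::rnorm(days, 0, noise_sd)
    })
  }
  temperature_series(pmax(temp, 0), start = start)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
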