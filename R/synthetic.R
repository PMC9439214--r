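#' Generate a synthetic cage bioassay
#'
#' Emulates the weekly cage bioassay that the model components are fitted to:
#' individual females caged on one host plant under a temperature regime,
#' with eggs counted and alive/dead status recorded every week until death.
#' No raw per-female data were ever published for this system, so synthetic
#' bioassays generated from a parameter bundle are the test bed for every
#' fitting and validation stage.
#'
#' Per female, a death age is drawn on the normalized-age scale by
#' inverse-CDF sampling of the survival curve (lifetime CDF `1 - s(px)`) and
#' converted to a death day via the aging trajectory. Expected eggs accrue
#' daily as `f(T) * dp` up to the moment of death (including the partial
#' death day), are summed within weeks, and observed counts are drawn from
#' the chosen count-noise law around the weekly expectation.
#'
#' `fecundity_basis` controls what the bundle's fecundity curve `f(T)` means
#' for the generator:
#' \describe{
#'   \item{`"realized"` (default)}{`f(T)` is the *expected realized lifetime
#'     total* — what cage totals actually measure, since every caged female
#'     eventually dies mid-schedule. The per-female laying intensity is
#'     scaled by `1 / schedule_completion(...)` (about 1/0.92) so that the
#'     mean observed total equals `f(T)`. Use this basis when the generated
#'     data will be re-fitted: fecundity refits are then unbiased for the
#'     generating `r_m`.}
#'   \item{`"potential"`}{the literal forward model: intensity `f(T) * dp`,
#'     so a female dying at age `px_d` realizes only `f(T) * p(px_d)` and
#'     long-lived females approach `f(T)`. This matches the survival-weighted
#'     simulator exactly (closed-loop validation is unbiased) but realized
#'     totals average about 8% below `f(T)`.}
#' }
#' The two bases cannot be reconciled in one generator because the model
#' multiplies a fecundity curve fitted to realized totals by survival again;
#' see the methods vignette.
#'
#' @param model A [host_plant_model()] (the generating truth).
#' @param regime A [temperature_series()], a numeric vector of daily
#'   temperatures, or a single constant temperature (horizon then extends
#'   automatically until the schedule and survival curves are exhausted).
#' @param n_females Number of caged females (>= 1).
#' @param egg_noise `"negative_binomial"` (default; weekly count SDs in this
#'   system exceed Poisson expectation), `"poisson"`, or `"none"`
#'   (deterministic expectations).
#' @param dispersion Negative-binomial size parameter (> 0); default 5.
#' @param fecundity_basis `"realized"` or `"potential"`; see Details.
#' @param regime_name Label recorded with the dataset.
#' @param seed Optional RNG seed (caller's RNG state is preserved).
#' @return A data frame of class `"bioassay_data"` with columns `female_id`,
#'   `week`, `eggs`, `alive`, `host`, `regime_name`; attribute `"females"`
#'   holds per-female death day/age (NA when censored by the regime end).
#' @examples
#' ks <- default_host_models()$kochia_scoparia
#' ba <- generate_bioassay(ks, regime = 30, n_females = 14, seed = 1)
#' summarize_bioassay(ba)
#' @export
generate_bioassay <- function(model, regime, n_females = 12,
                              egg_noise = c("negative_binomial", "poisson", "none"),
                              dispersion = 5,
                              fecundity_basis = c("realized", "potential"),
                              regime_name = NULL, seed = NULL) {
  stopifnot(inherits(model, "host_model"))
  egg_noise <- match.arg(egg_noise)
  fecundity_basis <- match.arg(fecundity_basis)
  if (!is.numeric(n_females) || length(n_females) != 1L || n_females < 1)
    stop("'n_females' must be >= 1", call. = FALSE)
  n_females <- as.integer(n_females)
  if (egg_noise == "negative_binomial" &&
      (!is.numeric(dispersion) || dispersion <= 0))
    stop("'dispersion' must be positive for negative_binomial noise", call. = FALSE)

  if (is.numeric(regime) && length(regime) == 1L) {
    if (is.null(regime_name)) regime_name <- sprintf("constant_%g", regime)
    r <- aging_rate(regime, model$aging)
    px_hi <- max(survival_quantile(1e-3, model$survival),
                 model$schedule$alpha * (-log(1 - 0.9999))^(1 / model$schedule$beta))
    tv <- rep(regime, ceiling(px_hi / r) + 7L)
  } else {
    tv <- as_daily_temps(regime)
    if (is.null(regime_name)) regime_name <- "custom"
  }
  n_days <- length(tv)
  px <- normalized_age(tv, model$aging)
  p <- cum_oviposition(px, model$schedule)
  f <- total_fecundity(tv, model$fecundity)
  scale <- if (fecundity_basis == "realized")
    1 / schedule_completion(model$schedule, model$survival) else 1
  n_weeks <- as.integer(ceiling(n_days / 7))
  wk_of_day <- (seq_len(n_days) - 1L) %/% 7L + 1L

  with_seed(seed, {
    u <- stats::runif(n_females)
    px_d <- survival_quantile(1 - u, model$survival)
    death_day <- rep(NA_integer_, n_females)
    rows <- vector("list", n_females)
    for (j in seq_len(n_females)) {
      # laying truncated at the death age, partial death day included
      pj <- cum_oviposition(pmin(px, px_d[j]), model$schedule)
      daily <- f * diff(pj) * scale
      mu_wk <- as.numeric(rowsum(daily, wk_of_day))
      obs <- switch(egg_noise,
        none = mu_wk,
        poisson = stats::rpois(n_weeks, mu_wk),
        negative_binomial = ifelse(mu_wk > 0,
          stats::rnbinom(n_weeks, size = dispersion, mu = mu_wk), 0))
      if (px_d[j] <= px[n_days + 1L]) {
        death_day[j] <- if (px_d[j] <= 0) 1L else
          min(which(px[-1] >= px_d[j]))
      }
      alive <- if (is.na(death_day[j])) rep(TRUE, n_weeks) else
        seq_len(n_weeks) < ceiling(death_day[j] / 7)
      rows[[j]] <- data.frame(female_id = j, week = seq_len(n_weeks),
                              eggs = obs, alive = alive)
    }
    out <- do.call(rbind, rows)
    out$host <- model$host
    out$regime_name <- regime_name
    structure(out,
              females = data.frame(female_id = seq_len(n_females),
                                   death_px = px_d, death_day = death_day,
                                   death_week = ceiling(death_day / 7)),
              n_females = n_females, fecundity_basis = fecundity_basis,
              class = c("bioassay_data", "data.frame"))
  })
}

#' Simulate bioassay datasets from a host model
#'
#' `simulate()` method for [host_plant_model()] objects: draws `nsim`
#' independent synthetic cage bioassays via [generate_bioassay()].
#'
#' @param object A [host_plant_model()].
#' @param nsim Number of datasets.
#' @param seed Optional seed governing all `nsim` draws.
#' @param ... Passed to [generate_bioassay()] (`regime`, `n_females`, ...).
#' @return A `"bioassay_data"` frame if `nsim = 1`, else a list of them.
#' @export
simulate.host_model <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed,
    lapply(seq_len(nsim), function(i) generate_bioassay(object, ..., seed = NULL)))
  if (nsim == 1) out[[1]] else out
}

#' Condition summary of a bioassay dataset
#'
#' Per host x regime condition: sample size, mean and SD of per-female total
#' eggs, and mean and SD of longevity in weeks (the week in which death was
#' recorded; females still alive at the end of the regime are counted at
#' their last observed week and reported in `n_censored`).
#'
#' @param data A `"bioassay_data"` frame (generated or read from CSV).
#' @return A data frame, one row per host x regime.
#' @export
summarize_bioassay <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  req <- c("female_id", "week", "eggs", "alive", "host", "regime_name")
  if (!all(req %in% names(data)))
    stop("bioassay data must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  split_by <- interaction(data$host, data$regime_name, drop = TRUE)
  out <- lapply(split(data, split_by), function(d) {
    per_f <- split(d, d$female_id)
    totals <- vapply(per_f, function(x) sum(x$eggs), numeric(1))
    lw <- vapply(per_f, function(x) {
      dead <- which(!x$alive)
      if (length(dead)) x$week[min(dead)] else NA_integer_
    }, numeric(1))
    censored <- is.na(lw)
    lw[censored] <- vapply(per_f[censored], function(x) max(x$week), numeric(1))
    data.frame(host = d$host[1], regime_name = d$regime_name[1],
               n = length(per_f),
               mean_eggs = mean(totals), sd_eggs = stats::sd(totals),
               mean_longevity_weeks = mean(lw), sd_longevity_weeks = stats::sd(lw),
               n_censored = sum(censored))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# -- synthetic observation tables for the component fits ----------------------

#' Synthetic observation tables for the component fits
#'
#' Generate per-observation tables directly from a model component plus
#' noise, in the shapes the `fit_*()` functions consume. These are the
#' designs used for parameter-recovery checks.
#'
#' `synth_fecundity_obs()`: total eggs at each temperature with multiplicative
#' Gaussian noise of coefficient of variation `cv`, truncated at 0.
#' `synth_longevity_obs()`: longevities whose reciprocals scatter (CV `cv`)
#' around the aging-rate curve.
#' `synth_schedule_obs()` / `synth_survival_obs()`: proportions on a
#' normalized-age grid with additive Gaussian noise of SD `sd`, clamped to
#' `[0, 1]`.
#'
#' @param params The generating component parameter object.
#' @param temps Temperatures (degrees C).
#' @param n_per_temp Observations per temperature.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param px Normalized-age grid.
#' @param sd Additive noise SD.
#' @param seed Optional RNG seed.
#' @return A data frame shaped for the corresponding `fit_*()` function.
#' @name synth_obs
NULL

#' @rdname synth_obs
#' @export
synth_fecundity_obs <- function(params, temps = c(15, 20, 25, 30, 35, 40),
                                n_per_temp = 30, cv = 0.10, seed = NULL) {
  stopifnot(inherits(params, "fecundity_params"))
  with_seed(seed, {
    tt <- rep(temps, each = n_per_temp)
    mu <- total_fecundity(tt, params)
    data.frame(temp = tt, eggs = pmax(mu * (1 + stats::rnorm(length(tt), 0, cv)), 0))
  })
}

#' @rdname synth_obs
#' @export
synth_longevity_obs <- function(params, temps = c(15, 20, 25, 30, 35, 40),
                                n_per_temp = 20, cv = 0.05, seed = NULL) {
  stopifnot(inherits(params, "aging_params"))
  with_seed(seed, {
    tt <- rep(temps, each = n_per_temp)
    rate <- aging_rate(tt, params) *
      pmax(1 + stats::rnorm(length(tt), 0, cv), 0.05)
    data.frame(temp = tt, longevity = 1 / rate)
  })
}

#' @rdname synth_obs
#' @export
synth_schedule_obs <- function(params, px = seq(0, 1.5, length.out = 60),
                               sd = 0.03, seed = NULL) {
  stopifnot(inherits(params, "schedule_params"))
  with_seed(seed, data.frame(
    px = px,
    value = pmin(pmax(cum_oviposition(px, params) +
                        stats::rnorm(length(px), 0, sd), 0), 1)))
}

#' @rdname synth_obs
#' @export
synth_survival_obs <- function(params, px = seq(0, 2.5, length.out = 60),
                               sd = 0.05, seed = NULL) {
  stopifnot(inherits(params, "survival_params"))
  with_seed(seed, data.frame(
    px = px,
    value = pmin(pmax(surv_prop(px, params) +
                        stats::rnorm(length(px), 0, sd), 0), 1)))
}
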