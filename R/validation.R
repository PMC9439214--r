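#' Compare predicted and observed weekly oviposition
#'
#' Pairs model-predicted weekly eggs per original female with observed weekly
#' means from a cage bioassay and computes the validation statistics: RMSE,
#' r-squared (squared Pearson correlation of the paired weekly values) and
#' mean bias (predicted minus observed). Observed weekly means are on the
#' cohort basis — dead females contribute zero — which is the basis the
#' survival-weighted prediction is on.
#'
#' @param observed A `"bioassay_data"` frame, or a data frame with columns
#'   `week` and `eggs` already holding weekly means per original female.
#' @param predicted A data frame with columns `week` and `eggs` (e.g. from
#'   [predict.host_model()] with `weekly = TRUE`).
#' @return An object of class `"ovi_validation"`: list with `per_week`
#'   (paired observed/predicted), `rmse`, `r2`, `mean_bias`, `n_weeks`,
#'   `host`.
#' @examples
#' ks <- default_host_models()$kochia_scoparia
#' reg <- generate_regime("summer_greenhouse", seed = 4)
#' obs <- generate_bioassay(ks, reg, n_females = 30, seed = 5,
#'                          fecundity_basis = "potential")
#' compare_weekly(obs, predict(ks, reg))
#' @export
compare_weekly <- function(observed, predicted) {
  stopifnot(is.data.frame(predicted), all(c("week", "eggs") %in% names(predicted)))
  host <- NA_character_
  if (inherits(observed, "bioassay_data") ||
      all(c("female_id", "eggs", "week") %in% names(observed))) {
    n_f <- length(unique(observed$female_id))
    obs_wk <- data.frame(
      week = sort(unique(observed$week)),
      eggs = as.numeric(rowsum(observed$eggs, observed$week)[, 1]) / n_f)
    if ("host" %in% names(observed)) host <- observed$host[1]
  } else {
    stopifnot(all(c("week", "eggs") %in% names(observed)))
    obs_wk <- observed[, c("week", "eggs")]
  }
  weeks <- intersect(obs_wk$week, predicted$week)
  if (length(weeks) == 0)
    stop("no overlapping weeks between observed and predicted series", call. = FALSE)
  per_week <- data.frame(
    week = weeks,
    observed = obs_wk$eggs[match(weeks, obs_wk$week)],
    predicted = predicted$eggs[match(weeks, predicted$week)])
  d <- per_week$predicted - per_week$observed
  r2 <- if (stats::sd(per_week$observed) > 0 && stats::sd(per_week$predicted) > 0)
    stats::cor(per_week$observed, per_week$predicted)^2 else NA_real_
  structure(list(per_week = per_week,
                 rmse = sqrt(mean(d^2)), r2 = r2, mean_bias = mean(d),
                 n_weeks = length(weeks), host = host),
            class = "ovi_validation")
}

#' Validate a host model against bioassay observations under a regime
#'
#' Predicts weekly oviposition for the regime (survival weighting on, the
#' form appropriate for cohort observations) and compares it with the
#' observed weekly egg counts.
#'
#' @param model A [host_plant_model()].
#' @param observed A `"bioassay_data"` frame covering the regime's weeks.
#' @param regime The driving [temperature_series()] (or numeric daily
#'   temperatures); must cover the observation window.
#' @param survival_weighting Default `TRUE`.
#' @return An `"ovi_validation"` object; see [compare_weekly()].
#' @export
validate_model <- function(model, observed, regime, survival_weighting = TRUE) {
  tv <- as_daily_temps(regime)
  max_wk <- max(observed$week)
  if (length(tv) < (max_wk - 1) * 7 + 1)
    stop("temperature regime (", length(tv), " days) is shorter than the ",
         "observation window (", max_wk, " weeks)", call. = FALSE)
  pred <- predict(model, tv, weekly = TRUE,
                  survival_weighting = survival_weighting)
  compare_weekly(observed, pred)
}

#' @export
print.ovi_validation <- function(x, ...) {
  cat(sprintf("Oviposition model validation%s: %d weeks\n",
              if (!is.na(x$host)) paste0(" (", x$host, ")") else "", x$n_weeks))
  cat(sprintf("  RMSE: %.3f eggs/week   r2: %.3f   mean bias (pred - obs): %.3f\n",
              x$rmse, x$r2, x$mean_bias))
  invisible(x)
}
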