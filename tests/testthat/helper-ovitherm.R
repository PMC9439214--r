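# Shared fixtures: the fitted beet-leafhopper parameter sets, built in code so
# every test can construct them without touching the shipped bundle.

sb_fecundity <- function() fecundity_params(216.982, 30.558, 7.182)
sb_aging <- function(sigma = 1) aging_params(-4.700, 4.506e-04, -3.837e-05, sigma)
sb_schedule <- function() schedule_params(0.501, 1.957)
sb_survival <- function(parameterization = "slope_multiplier")
  survival_params(1.042, -5.083, parameterization)

sb_model <- function() host_plant_model("Sugar beet", sb_fecundity(), sb_aging(),
                                        sb_schedule(), sb_survival())

ks_model <- function() host_plant_model(
  "Kochia scoparia",
  fecundity_params(133.050, 30.558, 7.182),
  sb_aging(sigma = 0.700),
  sb_schedule(), sb_survival())

# Per-female total eggs from a bioassay frame.
female_totals <- function(ba) as.numeric(tapply(ba$eggs, ba$female_id, sum))
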