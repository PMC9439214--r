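Package: ovitherm
Title: Temperature- and Host-Dependent Oviposition Models for the Beet Leafhopper
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits, simulates and validates age- and temperature-structured
    oviposition models for the beet leafhopper (Circulifer tenellus) on sugar
    beet and four non-agricultural host plants. The model combines a Gaussian
    temperature-dependent total fecundity curve, a temperature-dependent female
    aging rate with a host-specific multiplier, physiological-age normalization
    by accumulated aging rate, a Weibull age-specific cumulative oviposition
    schedule, and a sigmoid age-specific survival curve. Includes constrained
    one-parameter refits for host comparisons, daily and weekly oviposition
    prediction under fluctuating temperature regimes, constant-temperature
    sweeps, a synthetic cage-bioassay generator, and tools to validate
    predictions against weekly egg-count observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
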