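test_that("temperature regimes honor their profile and seed contracts", {
  r <- generate_regime("constant", days = 70, mean = 30)
  expect_s3_class(r, "temperature_series")
  expect_identical(r$temp, rep(30, 70))
  a <- generate_regime("winter_semifield", seed = 42)
  b <- generate_regime("winter_semifield", seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 105L)
  # seasonal component integrates to ~0 over the window; noise SE ~0.2 C
  expect_lt(abs(mean(a$temp) - 12), 0.5)
  expect_true(all(a$temp >= 0))
  g <- generate_regime("summer_greenhouse", seed = 1)
  expect_equal(nrow(g), 84L)
  expect_lt(abs(mean(g$temp) - 28), 0.6)
  expect_error(generate_regime("constant", days = -3), "positive")
})

test_that("bioassay generation is seed-deterministic with monotone alive flags", {
  m <- ks_model()
  a <- generate_bioassay(m, 30, n_females = 8, seed = 7)
  b <- generate_bioassay(m, 30, n_females = 8, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$eggs >= 0))
  for (d in split(a, a$female_id)) {
    expect_identical(d$week, seq_len(nrow(d)))
    expect_true(all(diff(d$alive) <= 0))  # no resurrection
  }
  one <- generate_bioassay(m, 30, n_females = 1, seed = 3)
  expect_identical(one, generate_bioassay(m, 30, n_females = 1, seed = 3))
  # simulate() method draws nsim independent datasets reproducibly
  sims <- simulate(m, nsim = 3, seed = 5, regime = 30, n_females = 4)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]]$eggs, sims[[2]]$eggs))
  expect_identical(sims,
                   simulate(m, nsim = 3, seed = 5, regime = 30, n_females = 4))
})

test_that("deterministic potential-basis totals approach f(T) for long-lived females", {
  m <- sb_model()
  ba <- generate_bioassay(m, 30.558, n_females = 60, egg_noise = "none",
                          fecundity_basis = "potential", seed = 11)
  fem <- attr(ba, "females")
  tot <- female_totals(ba)
  long_lived <- !is.na(fem$death_px) &
    cum_oviposition(fem$death_px, m$schedule) > 0.999
  expect_gt(sum(long_lived), 3)
  expect_equal(tot[long_lived], rep(216.982, sum(long_lived)), tolerance = 1e-3)
  # every total is bounded by the schedule completed at death
  expect_true(all(tot <= 216.982 + 1e-9))
})

test_that("deterministic realized-basis totals vary only through death times", {
  m <- ks_model()
  ba <- generate_bioassay(m, 30, n_females = 40, egg_noise = "none", seed = 2)
  fem <- attr(ba, "females")
  tot <- female_totals(ba)
  cfac <- schedule_completion(m$schedule, m$survival)
  dead <- !is.na(fem$death_day)
  expect_gt(sum(dead), 30)
  expect_equal(tot[dead],
               total_fecundity(30, m$fecundity) / cfac *
                 cum_oviposition(fem$death_px[dead], m$schedule),
               tolerance = 1e-6)
  s <- summarize_bioassay(ba)
  expect_gt(s$sd_eggs, 0)
  expect_equal(s$n, 40L)
})

test_that("count-noise laws have the right dispersion", {
  m <- ks_model()
  # week-1 counts of females alive through week 1 have a fixed expectation:
  # across seeds their variance/mean ratio identifies the noise law
  grab <- function(noise, seeds) {
    unlist(lapply(seeds, function(s) {
      ba <- generate_bioassay(m, 30, n_females = 25, egg_noise = noise,
                              dispersion = 5, seed = s)
      wk1 <- ba[ba$week == 1 & ba$alive, ]
      wk1$eggs
    }))
  }
  pois <- grab("poisson", 1:40)
  expect_gt(length(pois), 900)
  expect_lt(abs(var(pois) / mean(pois) - 1), 0.1)
  nb <- grab("negative_binomial", 1:40)
  expect_gt(var(nb) / mean(nb), 1.5)
})

test_that("condition summaries match their construction", {
  m <- ks_model()
  ba <- generate_bioassay(m, 30, n_females = 10, seed = 4)
  s <- summarize_bioassay(ba)
  expect_equal(s$mean_eggs, mean(female_totals(ba)))
  fem <- attr(ba, "females")
  expect_equal(s$mean_longevity_weeks, mean(fem$death_week))
  # 200-replicate average of mean totals matches f(30) under the truth
  set.seed(77)
  mm <- replicate(200, {
    b <- generate_bioassay(m, 30, n_females = 12, seed = NULL)
    mean(female_totals(b))
  })
  expect_lt(abs(mean(mm) / total_fecundity(30, m$fecundity) - 1), 0.03)
})

test_that("pipeline closure: R_m refit on simulated bioassays is unbiased", {
  m <- ks_model()
  set.seed(99)
  est <- replicate(300, {
    b30 <- generate_bioassay(m, 30, n_females = 15)
    b35 <- generate_bioassay(m, 35, n_females = 15)
    coef(fit_fecundity_rm(c(30, 35),
                          c(mean(female_totals(b30)), mean(female_totals(b35))),
                          30.558, 7.182))[["r_m"]]
  })
  expect_lt(abs(mean(est) / 133.050 - 1), 0.03)
})

test_that("large synthetic designs let every fit recover its generating parameters", {
  fp <- sb_fecundity(); ap <- sb_aging(); sp <- sb_schedule(); sv <- sb_survival()
  obs <- synth_fecundity_obs(fp, n_per_temp = 200, cv = 0.10, seed = 61)
  expect_equal(unname(coef(fit_fecundity(obs$temp, obs$eggs))),
               c(fp$r_m, fp$t_max, fp$k), tolerance = 0.02)
  expect_equal(coef(fit_fecundity_rm(obs$temp, obs$eggs, fp$t_max, fp$k))[["r_m"]],
               fp$r_m, tolerance = 0.02)
  lobs <- synth_longevity_obs(ap, n_per_temp = 200, cv = 0.05, seed = 62)
  expect_equal(unname(coef(fit_aging(lobs$temp, lobs$longevity))[1]), ap$a,
               tolerance = 0.02)
  lobs2 <- synth_longevity_obs(sb_aging(sigma = 0.904), temps = c(30, 35),
                               n_per_temp = 100, cv = 0.05, seed = 63)
  expect_equal(coef(fit_aging_sigma(lobs2$temp, lobs2$longevity, ap))[["sigma"]],
               0.904, tolerance = 0.02)
  sobs <- synth_schedule_obs(sp, px = seq(0, 1.5, length.out = 200), sd = 0.03,
                             seed = 64)
  expect_equal(unname(coef(fit_schedule(sobs$px, sobs$value))),
               c(sp$alpha, sp$beta), tolerance = 0.02)
  vobs <- synth_survival_obs(sv, px = seq(0, 2.5, length.out = 200), sd = 0.05,
                             seed = 65)
  expect_equal(coef(fit_survival(vobs$px, vobs$value))[["gamma"]], sv$gamma,
               tolerance = 0.02)
})
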