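test_that("noise-free data recover generating parameters to high precision", {
  # property over randomized true parameters, every component
  set.seed(101)
  for (i in 1:5) {
    fp <- fecundity_params(runif(1, 20, 300), runif(1, 22, 38), runif(1, 4, 10))
    tt <- rep(seq(10, 45, length.out = 8), each = 2)
    fit <- fit_fecundity(tt, total_fecundity(tt, fp))
    expect_equal(unname(coef(fit)), c(fp$r_m, fp$t_max, fp$k), tolerance = 1e-7)

    ap <- aging_params(runif(1, -5.5, -4), runif(1, 2e-4, 6e-4),
                       runif(1, -5e-5, -2e-5))
    tt <- seq(12, 40, length.out = 7)
    fit <- fit_aging(tt, 1 / aging_rate(tt, ap))
    expect_equal(unname(coef(fit)), c(ap$a, ap$b, ap$c), tolerance = 1e-6)

    sp <- schedule_params(runif(1, 0.3, 0.8), runif(1, 1.2, 3))
    px <- seq(0.05, 1.8, length.out = 20)
    fit <- fit_schedule(px, cum_oviposition(px, sp))
    expect_equal(unname(coef(fit)), c(sp$alpha, sp$beta), tolerance = 1e-7)

    sv <- survival_params(runif(1, 0.7, 1.4), runif(1, 3, 8))
    px <- seq(0, 2.5, length.out = 20)
    fit <- fit_survival(px, surv_prop(px, sv))
    expect_equal(unname(coef(fit)), c(sv$gamma, sv$delta), tolerance = 1e-7)
  }
})

test_that("full Gaussian fit reports sensible SEs and adjusted r2", {
  obs <- synth_fecundity_obs(sb_fecundity(), n_per_temp = 30, cv = 0.10, seed = 2)
  fit <- fit_fecundity(obs$temp, obs$eggs)
  expect_true(all(fit$se > 0))
  expect_gt(fit$adj_r2, 0.9)
  expect_lte(fit$adj_r2, 1)
  expect_equal(coef(fit)[["t_max"]], 30.558, tolerance = 0.02)
})

test_that("degenerate fecundity designs are rejected or flagged", {
  expect_error(fit_fecundity(c(30, 30, 30, 30), c(10, 12, 11, 9)), "distinct")
  expect_error(fit_fecundity(c(30, 35), c(10, 12)), "at least 4")
  # constant response: curve height/steepness unidentifiable
  expect_error(fit_fecundity(rep(c(20, 30, 40), 2), rep(50, 6)))
})

test_that("constrained R_m refit has the closed form and matches the host refits", {
  # single on-curve observation recovers r_m exactly
  fp <- sb_fecundity()
  fit1 <- fit_fecundity_rm(33, total_fecundity(33, fp), fp$t_max, fp$k)
  expect_equal(coef(fit1)[["r_m"]], fp$r_m, tolerance = 1e-12)
  expect_true(is.na(fit1$se[["r_m"]]))

  # condition means at the two bioassay temperatures -> hand-oracle values
  refit <- function(y) coef(fit_fecundity_rm(c(30, 35), y, 30.558, 7.182))[["r_m"]]
  expect_equal(refit(c(137.57, 102.17)), 133.050, tolerance = 0.02) # K. scoparia
  expect_equal(refit(c(106.60, 79.27)), 103.146, tolerance = 0.02)  # P. ovata
  expect_equal(refit(c(27.15, 17.33)), 24.872, tolerance = 0.02)    # E. cicutarium
  expect_equal(refit(c(30.07, 20.64)), 28.610, tolerance = 0.02)    # S. tragus

  # observations far outside the curve are unidentifiable
  suppressWarnings(
    expect_error(fit_fecundity_rm(c(300, 400), c(5, 5), 30.558, 7.182),
                 "unidentifiable"))
})

test_that("closed-form refits agree with a generic 1-D minimizer", {
  set.seed(31)
  tt <- runif(12, 15, 42)
  yy <- total_fecundity(tt, sb_fecundity()) * (1 + rnorm(12, 0, 0.1))
  rm_closed <- coef(fit_fecundity_rm(tt, yy, 30.558, 7.182))[["r_m"]]
  g <- exp(-0.5 * ((tt - 30.558) / 7.182)^2)
  rm_opt <- optimize(function(r) sum((yy - r * g)^2), c(0, 1000),
                     tol = 1e-12)$minimum
  expect_equal(rm_closed, rm_opt, tolerance = 1e-8)

  lt <- 1 / (aging_rate(tt, sb_aging()) * (1 + rnorm(12, 0, 0.05)))
  sig_closed <- coef(fit_aging_sigma(tt, lt, sb_aging()))[["sigma"]]
  rh <- aging_rate(tt, sb_aging())
  sig_opt <- optimize(function(s) sum((1 / lt - s * rh)^2), c(0, 10),
                      tol = 1e-12)$minimum
  expect_equal(sig_closed, sig_opt, tolerance = 1e-8)
})

test_that("aging-rate fits work in rate space and handle weekly units", {
  # weekly longevities are converted at the fitting boundary (x 7)
  tt <- seq(15, 40, 5)
  days <- 1 / aging_rate(tt, sb_aging())
  fit_wk <- fit_aging(tt, days / 7, units = "weeks")
  expect_equal(unname(coef(fit_wk)), c(-4.700, 4.506e-4, -3.837e-5),
               tolerance = 1e-6)
  expect_error(fit_aging(c(30, 30, 35, 35), c(40, 42, 30, 31)), "distinct|determined")
})

test_that("sigma refit is an identity on proportional rates", {
  base <- sb_aging()
  tt <- c(25, 30, 35)
  expect_equal(coef(fit_aging_sigma(tt, 1 / aging_rate(tt, base), base))[["sigma"]],
               1, tolerance = 1e-12)
  lt_07 <- 1 / (0.7 * aging_rate(tt, base))
  expect_equal(coef(fit_aging_sigma(tt, lt_07, base))[["sigma"]], 0.700,
               tolerance = 1e-12)
  # mixed-temperature noisy recovery is unbiased (bias < 2% over replicates)
  sig <- sapply(1:200, function(s) {
    obs <- synth_longevity_obs(aging_params(-4.700, 4.506e-4, -3.837e-5,
                                            sigma = 1.108),
                               temps = c(25, 30, 35), n_per_temp = 10,
                               cv = 0.10, seed = 500 + s)
    coef(fit_aging_sigma(obs$temp, obs$longevity, base))[["sigma"]]
  })
  expect_lt(abs(mean(sig) / 1.108 - 1), 0.02)
})

test_that("schedule and survival fits recover from noisy curves", {
  al <- sapply(1:10, function(s) {
    obs <- synth_schedule_obs(sb_schedule(), sd = 0.03, seed = s)
    coef(fit_schedule(obs$px, obs$value))[["alpha"]]
  })
  expect_true(all(abs(al - 0.501) < 3 * 0.012))

  obs <- synth_survival_obs(sb_survival(), sd = 0.05, seed = 3)
  fit <- fit_survival(obs$px, obs$value)
  expect_equal(coef(fit)[["gamma"]], 1.042, tolerance = 0.05)
  # fitted gamma is where the fitted curve crosses 0.5
  root <- uniroot(function(x) surv_prop(x, fit$params) - 0.5, c(0.1, 3),
                  tol = 1e-12)$root
  expect_equal(root, coef(fit)[["gamma"]], tolerance = 1e-9)
  # gamma recovery is unbiased across replicates
  ga <- sapply(1:200, function(s) {
    o <- synth_survival_obs(sb_survival(), sd = 0.05, seed = 1000 + s)
    coef(fit_survival(o$px, o$value))[["gamma"]]
  })
  expect_lt(abs(mean(ga) / 1.042 - 1), 0.01)
})

test_that("schedule/survival observation validation rejects uninformative data", {
  expect_error(fit_schedule(c(0, 0, 0), c(0, 0.5, 1)), "all zero")
  expect_error(fit_schedule(c(0.1, 0.5, 1), c(0, 1, 1)), "unidentifiable")
  expect_error(fit_schedule(c(0.1, -0.5, 1), c(0, 0.5, 1)), "nonnegative")
  expect_error(fit_survival(c(0.1, 0.5), c(0.9, 0.4)), "at least 3")
})

test_that("adjusted r-squared follows its definition", {
  set.seed(7)
  y <- rnorm(20, 10, 2)
  # perfect fit
  expect_equal(adjusted_r2(rep(0, 20), y, 2), 1)
  # fit no better than the mean, one parameter: penalty drives it below 0
  expect_lte(adjusted_r2(y - mean(y), y, 1), 0)
  # adjusted never exceeds unadjusted
  res <- rnorm(20, 0, 1)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_lte(adjusted_r2(res, y, 3), r2)
  expect_error(adjusted_r2(rep(0, 3), c(1, 2, 3), 2), "n_obs")
  expect_error(adjusted_r2(rep(0, 5), rep(4, 5), 1), "variance")
})

test_that("ovifit methods print, summarize and predict", {
  obs <- synth_fecundity_obs(sb_fecundity(), n_per_temp = 5, cv = 0.05, seed = 9)
  fit <- fit_fecundity(obs$temp, obs$eggs)
  expect_output(print(fit), "fecundity")
  expect_output(print(summary(fit)), "Adjusted r-squared")
  expect_length(residuals(fit), nrow(obs))
  expect_equal(predict(fit, 30.558), coef(fit)[["r_m"]] *
                 exp(-0.5 * ((30.558 - coef(fit)[["t_max"]]) / coef(fit)[["k"]])^2))
})
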