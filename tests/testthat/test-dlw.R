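# Noise-free synthetic decay series with known kinetics.
make_series <- function(k_h = 0.09, k_o = 0.11, e0_h = 1.2e-4, e0_o = 3e-4,
                        days = 1:10, dose = 108, noise_sd = 0,
                        weight = 62) {
  set.seed(99)
  noise <- function(n) 1 + rnorm(n, 0, noise_sd)
  urine_series("P1", data.frame(
    day = days,
    delta2h = e0_h * exp(-k_h * days) * noise(length(days)),
    delta18o = e0_o * exp(-k_o * days) * noise(length(days))),
    dose_g = dose, weight_kg = weight)
}

test_that("assign_dose follows the two-standard-dose rule", {
  expect_equal(assign_dose(60), 108)
  expect_equal(assign_dose(75), 141)   # boundary is inclusive on the high side
  expect_equal(assign_dose(90), 141)
  expect_equal(assign_dose(c(74.9, 75.0)), c(108, 141))
  expect_error(assign_dose(0), "domain error")
})

test_that("fit_elimination recovers noise-free kinetics exactly", {
  kin <- fit_elimination(make_series())
  expect_equal(kin$k_h, 0.09, tolerance = 1e-10)
  expect_equal(kin$k_o, 0.11, tolerance = 1e-10)
  expect_equal(kin$intercept_h, 1.2e-4, tolerance = 1e-10)
  expect_equal(kin$intercept_o, 3e-4, tolerance = 1e-10)
  # dilution space = dose tracer moles / intercept enrichment
  k <- dlw_constants()
  expect_equal(kin$n_h, 108 * k$mol_2h2o_per_g / 1.2e-4, tolerance = 1e-10)
  expect_equal(kin$n_o, 108 * k$mol_h218o_per_g / 3e-4, tolerance = 1e-10)
  # the two-point window variant agrees on exactly log-linear data
  kin2 <- fit_elimination(make_series(), method = "twopoint")
  expect_equal(kin2$k_h, kin$k_h, tolerance = 1e-10)
  expect_equal(kin2$k_o, kin$k_o, tolerance = 1e-10)
})

test_that("only samples inside the fit windows are used", {
  s <- make_series()
  # corrupt the unused mid-protocol days; the fit must not change
  s$samples$delta2h[s$samples$day %in% 4:7] <- 9e9
  s$samples$delta18o[s$samples$day %in% 4:7] <- 9e9
  kin <- fit_elimination(s)
  expect_equal(kin$k_h, 0.09, tolerance = 1e-10)
  expect_equal(kin$k_o, 0.11, tolerance = 1e-10)
})

test_that("fitted rates under noise match a Monte-Carlo derived tolerance", {
  # oracle: the empirical sampling distribution of the OLS slope over 1000
  # replicates of 1% multiplicative noise on the 6 window samples
  reps <- 1000
  set.seed(31)
  days <- c(1:3, 8:10)
  k_true <- 0.09
  sim_k <- replicate(reps, {
    y <- log(1.2e-4 * exp(-k_true * days) * (1 + rnorm(6, 0, 0.01)))
    xc <- days - mean(days)
    -sum(xc * (y - mean(y))) / sum(xc^2)
  })
  tol <- 4 * sd(sim_k)
  for (i in 1:20) {
    s <- urine_series("P1", data.frame(
      day = days,
      delta2h = 1.2e-4 * exp(-k_true * days) * (1 + rnorm(6, 0, 0.01)),
      delta18o = 3e-4 * exp(-0.11 * days) * (1 + rnorm(6, 0, 0.01))),
      dose_g = 108, weight_kg = 62)
    expect_lt(abs(fit_elimination(s)$k_h - k_true), tol)
  }
})

test_that("fit_elimination rejects unusable data", {
  s <- make_series(days = c(1, 5))  # one sample inside the windows
  expect_error(fit_elimination(s), "fewer than 2 usable samples")
  s2 <- make_series()
  s2$samples$delta18o[2] <- -1e-6
  expect_error(fit_elimination(s2), "data error.*18O.*day 2")
})

test_that("slopes are invariant to uniform enrichment rescaling", {
  s <- make_series()
  s10 <- s
  s10$samples$delta2h <- s$samples$delta2h * 10
  s10$samples$delta18o <- s$samples$delta18o * 10
  a <- fit_elimination(s)
  b <- fit_elimination(s10)
  expect_equal(b$k_h, a$k_h, tolerance = 1e-12)
  expect_equal(b$k_o, a$k_o, tolerance = 1e-12)
  expect_equal(b$intercept_h, 10 * a$intercept_h, tolerance = 1e-10)
  expect_equal(b$n_h, a$n_h / 10, tolerance = 1e-10)
})

test_that("compute_rco2 implements the two-pool slope-intercept equation", {
  k <- dlw_constants()
  kin <- structure(list(k_h = 0.09, k_o = 0.11, intercept_h = 1e-4,
                        intercept_o = 2.5e-4, n_h = 1800, n_o = 1740),
                   class = "aq_kinetics")
  # spreadsheet-style hand computation of the configured equation
  flux <- 1.007 * 0.11 * 1740 - 1.041 * 0.09 * 1800
  expected <- flux / 2.078 - 0.0246 * 1.05 * flux
  expect_equal(compute_rco2(kin, k), expected, tolerance = 1e-12)
  # linearity: doubling both dilution spaces doubles CO2 production
  kin2 <- kin; kin2$n_h <- 2 * kin$n_h; kin2$n_o <- 2 * kin$n_o
  expect_equal(compute_rco2(kin2, k), 2 * compute_rco2(kin, k),
               tolerance = 1e-12)
  # degenerate flux: 1.007 k_o n_o == 1.041 k_h n_h
  kin0 <- kin
  kin0$n_o <- 1.041 * kin$k_h * kin$n_h / (1.007 * kin$k_o)
  expect_error(compute_rco2(kin0, k), "unphysiological")
})

test_that("tee_from_rco2 applies the Weir relation", {
  expect_equal(tee_from_rco2(0), 0)
  # hand evaluation: 20 mol/d at RQ 0.85
  vco2 <- 20 * 22.414
  expect_equal(tee_from_rco2(20, 0.85),
               (3.941 * vco2 / 0.85 + 1.106 * vco2) * 4.184,
               tolerance = 1e-12)
  # strictly decreasing in RQ
  expect_gt(tee_from_rco2(20, 0.75), tee_from_rco2(20, 0.85))
  expect_gt(tee_from_rco2(20, 0.85), tee_from_rco2(20, 0.95))
  expect_error(tee_from_rco2(20, 0.5), "physiological bounds")
  expect_error(tee_from_rco2(-1), "non-negative")
})

test_that("urine series constructor enforces the sampling protocol", {
  expect_error(urine_series("P1", data.frame(day = c(2, 1),
                                             delta2h = 1:2, delta18o = 1:2),
                            108, 60), "strictly increasing")
  expect_error(urine_series("P1", data.frame(day = c(0.5, 2),
                                             delta2h = 1:2, delta18o = 1:2),
                            108, 60), "post-dose")
})

test_that("urine series round-trip through the delimited table format", {
  series <- list(make_series(), make_series(k_h = 0.08))
  series[[2]]$participant_id <- "P2"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_urine_series(series, path)
  back <- read_urine_series(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$samples, series[[1]]$samples)
  expect_equal(back[[2]]$dose_g, 108)
  expect_equal(dlw_tee(back[[1]])$tee_kj_day, dlw_tee(series[[1]])$tee_kj_day)
})
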